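# Lazily computed, memoized fixtures shared across test files. Everything is
# generated in code at test time; the simulator is deterministic, so sharing
# a trajectory between tests cannot couple them.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

base_50y <- function() {
  fixture("base_50y", function() {
    run_simulation("normal_aging", years = 50, record_stride = 365)
  })
}

scenario_50y <- function(name) {
  fixture(paste0(name, "_50y"), function() {
    run_simulation(name, years = 50, record_stride = 365)
  })
}

calibrated_v0 <- function() {
  fixture("cal_v0", function() calibrate_v0(anchor = 5.929e9))
}

calibrated_k_exit <- function() {
  fixture("cal_k_exit", function() {
    p <- update_params(default_params(), v0 = calibrated_v0()$fitted_value)
    calibrate_k_exit(p, anchor_ratio = 1.96)
  })
}

calibrated_params <- function() {
  update_params(default_params(),
                v0 = calibrated_v0()$fitted_value,
                k_exit = calibrated_k_exit()$fitted_value)
}

calibrated_run <- function(scenario_name, ...) {
  fixture(paste0("calrun_", scenario_name), function() {
    run_simulation(scenario_name, years = 50, record_stride = 50 * 365,
                   params = calibrated_params(), ...)
  })
}

reference_50y <- function() {
  fixture("reference_50y", function() {
    reference_integrate("normal_aging", years = 50, fine_dt = 0.25)
  })
}

# a random but invariant-respecting parameter set for property tests;
# caller is responsible for seeding
random_valid_params <- function() {
  jit <- function(x, lo = 0.5, hi = 1.5) x * stats::runif(1, lo, hi)
  p <- default_params()
  update_params(p,
    d = min(jit(p$d), 0.5), k1 = min(jit(p$k1), 0.5),
    k2 = min(jit(p$k2), 0.5),
    k3 = jit(p$k3), k8 = jit(p$k8), k4 = jit(p$k4),
    k5 = jit(p$k5), k11 = jit(p$k11),
    k6 = jit(p$k6), k7 = jit(p$k7), k9a = jit(p$k9a),
    k7a = jit(p$k7a), k9 = jit(p$k9), k12 = jit(p$k12),
    C1_0 = jit(p$C1_0), C4_0 = jit(p$C4_0),
    pvs_init_fraction = stats::runif(1, 0.05, 0.5),
    v0 = stats::runif(1, 0.144, 0.43),
    k_exit = jit(p$k_exit))
}
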