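test_that("per-day fluxes match their defining rate laws", {
  p <- default_params()

  gen <- generation_flux(5275, p)
  expect_equal(gen[["gen40"]], 16000 * 1.5 * 5275) # 1.266e8/day
  expect_equal(gen[["gen42"]], 3000 * 1.5 * 5275)
  expect_equal(generation_flux(0, p), c(gen40 = 0, gen42 = 0))
  gen2 <- generation_flux(5275, update_params(p, k4 = 2))
  expect_equal(gen2[["gen40"]] / gen[["gen40"]], 4 / 3)

  upt <- uptake_flux(4500, 1e9, 1e9, p)
  expect_equal(upt[["upt40"]], 1400 * 4500) # 6.3e6/day
  expect_equal(upt[["upt42"]], 200 * 4500)
  expect_equal(uptake_flux(4500, 1e3, 1e9, p)[["upt40"]], 1e3) # clamp
  expect_equal(uptake_flux(0, 1e9, 1e9, p), c(upt40 = 0, upt42 = 0))

  expect_equal(glymphatic_flux(6.258576e7, 0.29, 1), 0.29 * 6.258576e7)
  expect_equal(glymphatic_flux(5e8, 0, 1), 0)
  expect_equal(glymphatic_flux(2 * 7e7, 0.2, 1), 2 * glymphatic_flux(7e7, 0.2, 1))

  expect_equal(lrp_flux(1e8, 1, 0.4), 4e7)
  expect_equal(lrp_flux(1e8, 0, 0.4), 0)
  expect_equal(lrp_flux(1e8, 1, 0.12), 1.2e7) # ApoE4 preset rate

  s <- initial_state(p)
  s[["C1"]] <- 1e9; s[["C2"]] <- 1e8; s[["C4"]] <- 0; s[["C5"]] <- 0
  dep <- deposition_fluxes(s, p)
  expect_equal(dep[["dep_brain40"]], 1e6)
  expect_equal(dep[["dep_vessel40"]], 4e5)
  expect_equal(dep[["dep_brain42"]], 0)
  zero <- s; zero[c("C1", "C2", "C4", "C5")] <- 0
  expect_true(all(deposition_fluxes(zero, p) == 0))
})

test_that("neuron loss switches from natural to stimulated above the amyloid trigger", {
  p <- default_params()
  C1_init <- pgml_to_molecules(p$C1_0, p$mw40)
  expect_equal(neuron_loss_rate(0, C1_init, p), 0.01)
  expect_equal(neuron_loss_rate(10 * C1_init, C1_init, p), 0.01)
  expect_equal(neuron_loss_rate(21 * C1_init, C1_init, p), 0.044)
})

test_that("a single daily step from initial conditions raises parenchymal amyloid", {
  p <- default_params()
  s0 <- initial_state(p)
  res <- step_state(s0, p, physiology())
  # generation 1.266e8/day dwarfs initial uptake + convection + deposition
  expect_gt(res$state[["C1"]], s0[["C1"]])
  expect_equal(res$fluxes[["gen40"]], 16000 * 1.5 * 5275)
  expect_true(all(res$fluxes >= 0))
  expect_equal(res$state[["t"]], 1)
  # cell pools decay by their daily fractions
  expect_equal(res$state[["N"]], p$N0 * (1 - annual_to_daily(p$d)))
  expect_equal(res$state[["M"]], p$M0 * (1 - p$k12))
})

test_that("zero generation with zero initial amyloid is an absorbing state", {
  p <- update_params(default_params(), k3 = 0, k8 = 0, C1_0 = 0, C4_0 = 0)
  traj <- run_simulation("normal_aging", years = 1, params = p)
  ab <- as.matrix(traj[, c("C1", "C4", "C2", "C5", "C3", "C6", "C9", "C10")])
  expect_true(all(ab == 0))
  # cell pools still follow closed-form geometric decay
  expect_equal(traj$N[366], p$N0 * (1 - annual_to_daily(p$d))^365)
  expect_equal(traj$M[366], p$M0 * (1 - p$k12)^365)
})

test_that("69 years of daily neuron decay at 1 %/yr gives exactly half the pool", {
  traj <- run_simulation("normal_aging", years = 69, record_stride = 69 * 365)
  n_frac <- endpoints(traj)[["N"]] / default_params()$N0
  expect_equal(n_frac, 0.5, tolerance = 1e-3)
  expect_equal(n_frac, 0.99^69, tolerance = 1e-12) # compounding is exact
})

test_that("perivascular pool decays geometrically and its deposit converges to the closed form", {
  # no generation, no uptake, no inflow (flow_off), receptors frozen at full
  p <- update_params(default_params(), k3 = 0, k8 = 0, k5 = 0, k11 = 0,
                     k2 = 0, k10 = 0)
  scen <- scenario("pvs_decay",
                   stiffness = stiffness_profile(2, 18250, "flow_off"))
  traj <- run_simulation(scen, years = 0.2, params = p)
  r <- p$k6 + p$k_exit + p$k7
  C2_0 <- traj$C2[1]
  expect_equal(traj$C2[traj$t_days == 10], C2_0 * (1 - r)^10, tolerance = 1e-12)
  # geometric series: C3(infinity) = C2(0) * k7 / (k6 + k_exit + k7)
  expect_equal(traj$C3[nrow(traj)], C2_0 * p$k7 / r, tolerance = 1e-10)
  # generation is zero, so the ledger residual is pure float roundoff on
  # an absolute (molecules) scale
  expect_lt(mass_balance_residual(traj), 1e-6)
})

test_that("the amyloid subsystem is linear in the generation rates", {
  # trigger made irrelevant (k1 = 0) and uptake off; zero initial amyloid
  base <- update_params(default_params(), k1 = 0, k5 = 0, k11 = 0,
                        C1_0 = 0, C4_0 = 0)
  doubled <- update_params(base, k3 = 2 * base$k3, k8 = 2 * base$k8)
  t1 <- run_simulation("normal_aging", years = 2, params = base,
                       record_stride = 2 * 365)
  t2 <- run_simulation("normal_aging", years = 2, params = doubled,
                       record_stride = 2 * 365)
  e1 <- endpoints(t1); e2 <- endpoints(t2)
  pools <- c("C1", "C4", "C2", "C5", "C3", "C6", "C9", "C10")
  expect_equal(e2[pools], 2 * e1[pools], tolerance = 1e-12)
})

test_that("random valid parameter sets keep pools non-negative, deposits monotone and the ledger closed", {
  withr::local_seed(424242)
  for (i in 1:8) {
    p <- random_valid_params()
    hr <- sample(c(45, 60, 90), 1)
    traj <- run_simulation(scenario(paste0("rand", i), heart_rate = hr),
                           years = 2, params = p, record_stride = 30)
    m <- as.matrix(traj[, setdiff(names(traj), "t_days")])
    expect_true(all(m >= 0))
    for (dep in c("C3", "C6", "C9", "C10")) {
      expect_true(all(diff(traj[[dep]]) >= 0))
    }
    expect_lt(mass_balance_residual(traj), 1e-9)
  }
})

test_that("oversized steps are rejected rather than silently clipped", {
  p <- default_params()
  s <- initial_state(p)
  # with no parenchymal feed, dt = 10 days puts the PVS outflow fraction
  # above 1 and drives the pool negative
  s[["C1"]] <- 0; s[["C4"]] <- 0
  expect_error(step_state(s, p, physiology(), dt = 10),
               class = "glymphsim_internal_consistency")
  expect_error(step_state(s, p, physiology(), dt = 0),
               class = "glymphsim_invalid_parameter")
})
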