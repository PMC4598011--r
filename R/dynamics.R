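# State vector layout. Pools, all per model volume:
#   N neurons, M microglia, EC endothelial cells, LRP receptors;
#   C1/C4 Abeta40/42 in parenchymal ISF, C2/C5 in perivascular space,
#   C3/C6 deposited in vessel wall, C9/C10 deposited in parenchyma.
STATE_FIELDS <- c("t", "N", "M", "EC", "LRP",
                  "C1", "C4", "C2", "C5", "C3", "C6", "C9", "C10")

FLUX_FIELDS <- c("gen40", "gen42", "upt40", "upt42", "glym40", "glym42",
                 "lrp40", "lrp42", "exit40", "exit42",
                 "dep_brain40", "dep_brain42", "dep_vessel40", "dep_vessel42")

#' Initial model state
#'
#' Builds the day-0 state from a parameter set: full cell pools, parenchymal
#' amyloid converted from pg/mL to molecules, perivascular amyloid at
#' `pvs_init_fraction` of the parenchymal amount, and empty deposits.
#'
#' @param params A parameter set from [default_params()].
#' @param pvs_init_scale Extra multiplier on the initial perivascular amyloid
#'   (used by the sensitivity sweep; default 1).
#' @return Named numeric vector with elements
#'   `t, N, M, EC, LRP, C1, C4, C2, C5, C3, C6, C9, C10`.
#' @export
#' @examples
#' initial_state(default_params())
initial_state <- function(params, pvs_init_scale = 1) {
  if (pvs_init_scale <= 0) {
    rlang::abort("pvs_init_scale must be positive",
                 class = "glymphsim_invalid_parameter")
  }
  C1 <- pgml_to_molecules(params$C1_0, params$mw40, params$model_volume)
  C4 <- pgml_to_molecules(params$C4_0, params$mw42, params$model_volume)
  c(t = 0, N = params$N0, M = params$M0, EC = params$EC0, LRP = params$LRP0,
    C1 = C1, C4 = C4,
    C2 = params$pvs_init_fraction * pvs_init_scale * C1,
    C5 = params$pvs_init_fraction * pvs_init_scale * C4,
    C3 = 0, C6 = 0, C9 = 0, C10 = 0)
}

#' Amyloid generation flux
#'
#' Neurons generate Abeta40 at `k3` and Abeta42 at `k8` molecules per neuron
#' per day, always multiplied by the stimulated-generation factor `k4`
#' (applied unconditionally) and by an optional sweep `multiplier`.
#'
#' @param N Neuron count.
#' @param params Parameter set.
#' @param multiplier Extra generation multiplier (default 1).
#' @return Named vector `c(gen40, gen42)` in molecules/day.
#' @export
#' @examples
#' generation_flux(5275, default_params()) # gen40 = 16000 * 1.5 * 5275
generation_flux <- function(N, params, multiplier = 1) {
  if (N < 0 || multiplier <= 0) {
    rlang::abort("N must be >= 0 and multiplier > 0",
                 class = "glymphsim_invalid_parameter")
  }
  c(gen40 = params$k3 * params$k4 * multiplier * N,
    gen42 = params$k8 * params$k4 * multiplier * N)
}

#' Microglial uptake flux
#'
#' Uptake is a zeroth-order demand (`k5` and `k11` molecules per surviving
#' microglia per day) clamped to what is actually available, so a small pool
#' cannot be driven negative.
#'
#' @param M Microglia count.
#' @param available40,available42 Molecules available for uptake this day.
#' @param params Parameter set.
#' @return Named vector `c(upt40, upt42)` in molecules/day.
#' @export
#' @examples
#' uptake_flux(4500, 1e9, 1e9, default_params()) # demand 1400 * 4500
uptake_flux <- function(M, available40, available42, params) {
  if (M < 0 || available40 < 0 || available42 < 0) {
    rlang::abort("M and availabilities must be non-negative",
                 class = "glymphsim_invalid_parameter")
  }
  c(upt40 = min(params$k5 * M, available40),
    upt42 = min(params$k11 * M, available42))
}

#' Glymphatic (convective) transfer flux
#'
#' Advection of parenchymal amyloid into the perivascular space reduces, in
#' the well-mixed limit, to a first-order transfer at rate `v / L`: the bulk
#' interstitial-fluid velocity over the convective path length.
#'
#' @param C Parenchymal pool, molecules.
#' @param v Bulk ISF velocity, mm/day.
#' @param L Convective path length, mm (the capillary segment length).
#' @return Transfer flux in molecules/day.
#' @export
#' @examples
#' glymphatic_flux(6.26e7, 0.29, 1)
glymphatic_flux <- function(C, v, L) {
  if (C < 0 || v < 0 || L <= 0) {
    rlang::abort("need C >= 0, v >= 0, L > 0",
                 class = "glymphsim_invalid_parameter")
  }
  (v / L) * C
}

#' LRP-1 transport flux out of the perivascular space
#'
#' Receptor-mediated transport into blood (a perfect sink) at rate
#' `k6 * (LRP/LRP0)`: the transport constant scaled by the surviving
#' receptor fraction.
#'
#' @param C_pvs Perivascular pool, molecules.
#' @param lrp_frac Surviving receptor fraction in `[0, 1]`
#'   (see [lrp_fraction()]).
#' @param k6 Transport rate constant, fraction/day.
#' @return Flux in molecules/day.
#' @export
#' @examples
#' lrp_flux(1e8, 1, 0.4)
lrp_flux <- function(C_pvs, lrp_frac, k6) {
  if (C_pvs < 0 || lrp_frac < 0 || lrp_frac > 1 || k6 < 0) {
    rlang::abort("invalid lrp_flux arguments",
                 class = "glymphsim_invalid_parameter")
  }
  k6 * lrp_frac * C_pvs
}

#' Deposition fluxes
#'
#' First-order deposition out of the soluble pools: parenchymal at `k7a`
#' (Abeta40) and `k9` (Abeta42) per day, vessel-wall at `k7` (Abeta40) and
#' `k9a` (Abeta42) per day.
#'
#' @param state Model state vector (see [initial_state()]).
#' @param params Parameter set.
#' @return Named vector `c(dep_brain40, dep_brain42, dep_vessel40,
#'   dep_vessel42)` in molecules/day.
#' @export
deposition_fluxes <- function(state, params) {
  c(dep_brain40 = params$k7a * state[["C1"]],
    dep_brain42 = params$k9 * state[["C4"]],
    dep_vessel40 = params$k7 * state[["C2"]],
    dep_vessel42 = params$k9a * state[["C5"]])
}

#' Effective annual neuron loss rate
#'
#' Natural loss `d` always applies; once soluble parenchymal Abeta40 exceeds
#' `theta_k1` times its initial value, amyloid toxicity adds the stimulated
#' loss `k1`. The threshold is high enough that heart-rate and ApoE arms
#' never trigger it, while flow-collapse (stiffness) arms do.
#'
#' @param C1 Current parenchymal Abeta40, molecules.
#' @param C1_init Initial parenchymal Abeta40, molecules.
#' @param params Parameter set.
#' @return Annual loss fraction (`d` or `d + k1`).
#' @export
neuron_loss_rate <- function(C1, C1_init, params) {
  if (C1 < 0 || C1_init < 0) {
    rlang::abort("C1 and C1_init must be non-negative",
                 class = "glymphsim_invalid_parameter")
  }
  if (C1 > params$theta_k1 * C1_init) params$d + params$k1 else params$d
}

#' Advance the model state by one step
#'
#' The daily update map. All fluxes are evaluated on the start-of-step state
#' and applied simultaneously, so the cumulative ledger closes exactly. Cell
#' pools decay multiplicatively (annual fractions compounded to daily); the
#' eight amyloid pools advance by explicit forward differences:
#'
#' parenchyma gains generation and loses microglial uptake, glymphatic
#' transfer and parenchymal deposition; the perivascular space gains the
#' transfer and loses LRP-1 transport (to blood, a sink), glymphatic exit
#' toward cervical lymph (`k_exit`) and vessel-wall deposition; deposits
#' only accumulate.
#'
#' The caller must keep the per-step first-order outflow fraction of each
#' soluble pool below 1 (the engine sub-steps at 0.9); the only clamp is the
#' documented availability clamp on microglial uptake.
#'
#' @param state State vector from [initial_state()].
#' @param params Parameter set.
#' @param phys An [physiology()] object.
#' @param dt Step size in days (1 by default).
#' @param C1_init Initial parenchymal Abeta40 (molecules), the neuron-loss
#'   trigger reference; defaults to the value implied by `params`.
#' @param gen_multiplier Extra generation multiplier (default 1).
#' @return List with elements `state` (the advanced state vector) and
#'   `fluxes` (named per-step molecule totals:
#'   `gen40, gen42, upt40, upt42, glym40, glym42, lrp40, lrp42, exit40,
#'   exit42, dep_brain40, dep_brain42, dep_vessel40, dep_vessel42`).
#' @export
#' @examples
#' s0 <- initial_state(default_params())
#' step_state(s0, default_params(), physiology())$state
step_state <- function(state, params, phys, dt = 1,
                       C1_init = pgml_to_molecules(params$C1_0, params$mw40,
                                                   params$model_volume),
                       gen_multiplier = 1) {
  if (dt <= 0) {
    rlang::abort("dt must be positive", class = "glymphsim_invalid_parameter")
  }
  t <- state[["t"]]
  v <- isf_velocity(t, phys, params)
  lfrac <- lrp_fraction(state[["LRP"]], params$LRP0)
  L <- params$segment_length

  gen <- generation_flux(state[["N"]], params, gen_multiplier)
  glym40 <- glymphatic_flux(state[["C1"]], v, L)
  glym42 <- glymphatic_flux(state[["C4"]], v, L)
  dep <- deposition_fluxes(state, params)
  # availability for uptake: what first-order outflows leave behind this step
  avail40 <- max(0, state[["C1"]] - dt * (glym40 + dep[["dep_brain40"]])) / dt
  avail42 <- max(0, state[["C4"]] - dt * (glym42 + dep[["dep_brain42"]])) / dt
  upt <- uptake_flux(state[["M"]], avail40, avail42, params)
  lrp40 <- lrp_flux(state[["C2"]], lfrac, params$k6)
  lrp42 <- lrp_flux(state[["C5"]], lfrac, params$k6)
  exit40 <- params$k_exit * state[["C2"]]
  exit42 <- params$k_exit * state[["C5"]]

  r_neuron <- neuron_loss_rate(state[["C1"]], C1_init, params)
  f_n <- annual_to_daily(r_neuron)
  f_ec <- annual_to_daily(params$k2)
  f_lrp <- annual_to_daily(params$k10)

  new <- state
  new[["t"]] <- t + dt
  new[["N"]] <- state[["N"]] * (1 - f_n)^dt
  new[["M"]] <- state[["M"]] * (1 - params$k12)^dt
  new[["EC"]] <- state[["EC"]] * (1 - f_ec)^dt
  new[["LRP"]] <- state[["LRP"]] * (1 - f_lrp)^dt
  new[["C1"]] <- state[["C1"]] + dt * (gen[["gen40"]] - upt[["upt40"]] -
                                         glym40 - dep[["dep_brain40"]])
  new[["C4"]] <- state[["C4"]] + dt * (gen[["gen42"]] - upt[["upt42"]] -
                                         glym42 - dep[["dep_brain42"]])
  new[["C2"]] <- state[["C2"]] + dt * (glym40 - lrp40 - exit40 -
                                         dep[["dep_vessel40"]])
  new[["C5"]] <- state[["C5"]] + dt * (glym42 - lrp42 - exit42 -
                                         dep[["dep_vessel42"]])
  new[["C3"]] <- state[["C3"]] + dt * dep[["dep_vessel40"]]
  new[["C6"]] <- state[["C6"]] + dt * dep[["dep_vessel42"]]
  new[["C9"]] <- state[["C9"]] + dt * dep[["dep_brain40"]]
  new[["C10"]] <- state[["C10"]] + dt * dep[["dep_brain42"]]

  if (any(new[c("C1", "C4", "C2", "C5")] < -1e-6)) {
    rlang::abort(
      "soluble amyloid pool driven negative: step size too large for the outflow rates",
      class = "glymphsim_internal_consistency")
  }
  # forward-difference roundoff can leave a pool at -1e-16 molecules
  new[c("C1", "C4", "C2", "C5")] <- pmax(new[c("C1", "C4", "C2", "C5")], 0)

  fluxes <- c(gen[["gen40"]], gen[["gen42"]], upt[["upt40"]], upt[["upt42"]],
              glym40, glym42, lrp40, lrp42, exit40, exit42,
              dep[["dep_brain40"]], dep[["dep_brain42"]],
              dep[["dep_vessel40"]], dep[["dep_vessel42"]]) * dt
  names(fluxes) <- FLUX_FIELDS
  list(state = new, fluxes = fluxes)
}
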