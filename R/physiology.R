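#' Vessel stiffness profile
#'
#' Vessel wall stiffness S rises exponentially from 1 at the start of the run
#' to `fold_change` at `duration` days and stays there. Stiffer walls transmit
#' arterial pulsations less effectively, which lowers the interstitial-fluid
#' bulk velocity via the chosen compliance law:
#'
#' * `inverse`: compliance = 1/S;
#' * `linear_floor`: compliance falls linearly from 1 at S = 1 to 0 at
#'   S = `fold_change`;
#' * `flow_off`: convective inflow to the perivascular space is shut off for
#'   the whole run (the limiting case of a wall that transmits no pulsation).
#'
#' @param fold_change Stiffness multiple at the end of the ramp, >= 1.
#' @param duration Ramp length in days (default 18250, i.e. 50 years).
#' @param law Compliance law, one of "inverse", "linear_floor", "flow_off".
#' @return An object of class `ab_stiffness`.
#' @export
#' @examples
#' stiffness_profile(fold_change = 2)
stiffness_profile <- function(fold_change = 1, duration = 18250,
                              law = c("inverse", "linear_floor", "flow_off")) {
  law <- match.arg(law)
  if (!is.numeric(fold_change) || length(fold_change) != 1 || fold_change < 1) {
    rlang::abort("fold_change must be a single number >= 1",
                 class = "glymphsim_invalid_parameter")
  }
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    rlang::abort("duration must be a single positive number of days",
                 class = "glymphsim_invalid_parameter")
  }
  structure(list(fold_change = fold_change, duration = duration,
                 shape = "exponential", law = law),
            class = "ab_stiffness")
}

#' Physiological setting of a simulation arm
#'
#' Bundles heart rate, the vessel stiffness profile and the ApoE allele.
#' Interstitial-fluid flow is driven by arterial pulsations, so mean bulk
#' velocity scales linearly with heart rate relative to the 60 bpm reference;
#' the allele selects the LRP-1 transport efficiency.
#'
#' @param heart_rate Beats per minute, within `[30, 200]`.
#' @param stiffness An [stiffness_profile()] (default: no stiffening).
#' @param apoe ApoE allele, "E2", "E3" or "E4".
#' @param hr_ref Reference heart rate, beats/min (default 60).
#' @return An object of class `ab_physiology`.
#' @export
#' @examples
#' physiology(heart_rate = 50)
physiology <- function(heart_rate = 60, stiffness = stiffness_profile(),
                       apoe = c("E3", "E2", "E4"), hr_ref = 60) {
  apoe <- match.arg(apoe)
  if (!is.numeric(heart_rate) || length(heart_rate) != 1 ||
      heart_rate < 30 || heart_rate > 200) {
    rlang::abort("heart_rate must lie in [30, 200] beats/min",
                 class = "glymphsim_invalid_parameter")
  }
  if (!inherits(stiffness, "ab_stiffness")) {
    rlang::abort("stiffness must be built with stiffness_profile()",
                 class = "glymphsim_invalid_parameter")
  }
  if (!is.numeric(hr_ref) || length(hr_ref) != 1 || hr_ref <= 0) {
    rlang::abort("hr_ref must be positive", class = "glymphsim_invalid_parameter")
  }
  structure(list(heart_rate = heart_rate, hr_ref = hr_ref,
                 stiffness = stiffness, apoe = apoe),
            class = "ab_physiology")
}

#' Wall stiffness at a given time
#'
#' Exponential ramp: `S(t) = exp(log(fold_change) * min(t, duration) /
#' duration)`, so S(0) = 1 and S(duration) = fold_change.
#'
#' @param t Time in days (vectorized), >= 0.
#' @param profile An [stiffness_profile()].
#' @return Stiffness multiple S(t) >= 1.
#' @export
#' @examples
#' stiffness_at(9125, stiffness_profile(2)) # sqrt(2) at mid-ramp
stiffness_at <- function(t, profile) {
  if (any(t < 0)) {
    rlang::abort("t must be non-negative", class = "glymphsim_invalid_parameter")
  }
  exp(log(profile$fold_change) * pmin(t, profile$duration) / profile$duration)
}

#' Wall compliance factor from stiffness
#'
#' Maps stiffness S >= 1 to the fraction of the baseline pulsation-driven
#' velocity that survives, per the selected law (see [stiffness_profile()]).
#'
#' @param S Stiffness multiple, >= 1 (vectorized).
#' @param law "inverse", "linear_floor" or "flow_off".
#' @param fold_change Endpoint stiffness of the profile (used by
#'   `linear_floor`).
#' @return Compliance factor in `[0, 1]`.
#' @export
#' @examples
#' compliance_factor(2, "inverse", 2) # 0.5
compliance_factor <- function(S, law, fold_change = 2) {
  if (any(S < 1)) {
    rlang::abort("S must be >= 1", class = "glymphsim_invalid_parameter")
  }
  switch(law,
    inverse = 1 / S,
    linear_floor = if (fold_change > 1) {
      pmax(0, (fold_change - S) / (fold_change - 1))
    } else {
      rep(1, length(S))
    },
    flow_off = rep(0, length(S)),
    rlang::abort(paste0("unknown compliance law: ", law),
                 class = "glymphsim_invalid_parameter")
  )
}

#' Interstitial-fluid bulk velocity
#'
#' `v(t) = v0 * (heart_rate / hr_ref) * compliance(S(t))`: linear in heart
#' rate (pulsations drive the flow) and attenuated by wall stiffening. With
#' the defaults (60 bpm, no stiffening) this is the calibrated baseline
#' velocity `v0` = 0.2946 mm/day, i.e. ~0.2 um/min, inside the literature
#' range of 0.1-0.3 um/min.
#'
#' @param t Time in days (vectorized), >= 0.
#' @param phys An [physiology()] object.
#' @param params An [default_params()] parameter set (supplies `v0`).
#' @return Velocity in mm/day, >= 0.
#' @export
#' @examples
#' isf_velocity(0, physiology(), default_params())
isf_velocity <- function(t, phys, params) {
  S <- stiffness_at(t, phys$stiffness)
  cf <- compliance_factor(S, phys$stiffness$law, phys$stiffness$fold_change)
  params$v0 * (phys$heart_rate / phys$hr_ref) * cf
}

#' Surviving LRP-1 receptor fraction
#'
#' LRP-1 transport capacity scales with the surviving receptor pool; the
#' fraction multiplies the transport rate constant `k6` in the perivascular
#' clearance flux.
#'
#' @param LRP Current receptor count, in `[0, LRP0]`.
#' @param LRP0 Initial receptor count, > 0.
#' @return `LRP / LRP0`, in `[0, 1]`.
#' @export
#' @examples
#' lrp_fraction(0.99^50 * 9.3e11, 9.3e11) # ~0.605 after 50 years at 1 %/yr
lrp_fraction <- function(LRP, LRP0) {
  if (any(LRP0 <= 0)) {
    rlang::abort("LRP0 must be positive", class = "glymphsim_invalid_parameter")
  }
  if (any(LRP < 0)) {
    rlang::abort("LRP must be non-negative", class = "glymphsim_invalid_parameter")
  }
  if (any(LRP > LRP0 * (1 + 1e-12))) {
    rlang::abort("LRP exceeds LRP0", class = "glymphsim_invariant_violation")
  }
  pmin(LRP / LRP0, 1)
}
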