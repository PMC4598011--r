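TRAJ_COLS <- c("t_days", "N", "M", "EC", "LRP", "C1", "C4", "C2", "C5",
               "C3", "C6", "C9", "C10",
               "cum_gen40", "cum_gen42", "cum_upt40", "cum_upt42",
               "cum_lrp40", "cum_lrp42", "cum_exit40", "cum_exit42")

resolve_scenario <- function(scenario) {
  if (is.character(scenario) && length(scenario) == 1) {
    reg <- builtin_scenarios()
    if (!scenario %in% names(reg)) {
      rlang::abort(paste0("unknown scenario \"", scenario, "\"; valid: ",
                          paste(names(reg), collapse = ", ")),
                   class = "glymphsim_invalid_parameter")
    }
    return(reg[[scenario]])
  }
  if (!inherits(scenario, "ab_scenario")) {
    rlang::abort("scenario must be a name or an object from scenario()",
                 class = "glymphsim_invalid_parameter")
  }
  scenario
}

scenario_params <- function(scen, params = NULL) {
  if (is.null(params)) {
    params <- default_params(apoe = scen$apoe)
  } else {
    validate_params(params)
    params <- update_params(params,
                            k6 = if (scen$apoe == "E4") 0.12 else 0.4)
  }
  if (!is.null(scen$k4_override)) {
    params <- update_params(params, k4 = scen$k4_override)
  }
  if (length(scen$param_overrides) > 0) {
    params <- do.call(update_params, c(list(params), scen$param_overrides))
  }
  params
}

scenario_physiology <- function(scen) {
  stiff <- if (is.null(scen$stiffness)) stiffness_profile() else scen$stiffness
  physiology(heart_rate = scen$heart_rate, stiffness = stiff, apoe = scen$apoe)
}

#' Run a simulation
#'
#' Advances the 12-pool model through `years` of daily steps under a named
#' or custom scenario, recording every `record_stride` days together with
#' the cumulative flux ledger. The run is fully deterministic: there is no
#' random number generator anywhere in the simulator.
#'
#' Any day whose worst-case first-order outflow fraction would exceed 0.9 is
#' automatically split into sub-steps to preserve positivity of the explicit
#' scheme (never needed with the default rates).
#'
#' @param scenario Scenario name from [builtin_scenarios()] or an
#'   [scenario()] object. Default `"normal_aging"`.
#' @param years Horizon in years (default 50, i.e. 18,250 daily steps).
#' @param dt Step size in days (default 1).
#' @param record_stride Record every this many days (default 1; day 0 and
#'   the final day are always recorded).
#' @param params Optional base parameter set (default: the scenario's
#'   allele-specific [default_params()]). Scenario overrides still apply.
#' @param pvs_init_scale Multiplier on the initial perivascular amyloid
#'   (sensitivity sweeps; default 1).
#' @return A tibble of class `ab_trajectory` with columns `t_days`, the 12
#'   pools and 8 cumulative ledger columns; attributes `scenario_name`,
#'   `params_used`, `physiology`, `years`, `dt`.
#' @export
#' @examples
#' traj <- run_simulation("normal_aging", years = 2)
#' tail(traj)
run_simulation <- function(scenario = "normal_aging", years = 50, dt = 1,
                           record_stride = 1, params = NULL,
                           pvs_init_scale = 1) {
  scen <- resolve_scenario(scenario)
  if (years <= 0 || dt <= 0 || record_stride < dt) {
    rlang::abort("need years > 0, dt > 0, record_stride >= dt",
                 class = "glymphsim_invalid_parameter")
  }
  params <- scenario_params(scen, params)
  phys <- scenario_physiology(scen)

  n_days <- round(years * 365)
  n_steps <- round(n_days / dt)
  if (abs(n_steps * dt - n_days) > 1e-9) {
    rlang::abort("dt must divide the horizon evenly",
                 class = "glymphsim_invalid_parameter")
  }

  # worst-case per-day first-order outflow fractions (compliance <= 1, lrp <= 1)
  v_max <- params$v0 * phys$heart_rate / phys$hr_ref
  frac_par <- (v_max / params$segment_length + max(params$k7a, params$k9)) * dt
  frac_pvs <- (params$k6 + params$k_exit + max(params$k7, params$k9a)) * dt
  n_sub <- max(1, ceiling(max(frac_par, frac_pvs) / 0.9))
  dt_sub <- dt / n_sub

  state <- initial_state(params, pvs_init_scale = pvs_init_scale)
  C1_init <- pgml_to_molecules(params$C1_0, params$mw40, params$model_volume)
  cum <- stats::setNames(numeric(length(FLUX_FIELDS)), FLUX_FIELDS)

  rec_every <- max(1L, as.integer(round(record_stride / dt)))
  rec_idx <- unique(c(0L, seq(rec_every, n_steps, by = rec_every), n_steps))
  out <- matrix(NA_real_, nrow = length(rec_idx), ncol = length(TRAJ_COLS),
                dimnames = list(NULL, TRAJ_COLS))
  record <- function(row, state, cum) {
    out[row, ] <<- c(state[STATE_FIELDS],
                     cum[c("gen40", "gen42", "upt40", "upt42",
                           "lrp40", "lrp42", "exit40", "exit42")])
  }
  row <- 1L
  record(row, state, cum)
  next_rec <- 2L
  for (i in seq_len(n_steps)) {
    if (n_sub == 1L) {
      res <- step_state(state, params, phys, dt = dt, C1_init = C1_init)
      state <- res$state
      cum <- cum + res$fluxes
    } else {
      for (j in seq_len(n_sub)) {
        res <- step_state(state, params, phys, dt = dt_sub, C1_init = C1_init)
        state <- res$state
        cum <- cum + res$fluxes
      }
    }
    if (next_rec <= length(rec_idx) && i == rec_idx[next_rec]) {
      record(next_rec, state, cum)
      next_rec <- next_rec + 1L
    }
  }

  traj <- tibble::as_tibble(as.data.frame(out))
  attr(traj, "scenario_name") <- scen$name
  attr(traj, "params_used") <- params
  attr(traj, "physiology") <- phys
  attr(traj, "years") <- years
  attr(traj, "dt") <- dt
  class(traj) <- c("ab_trajectory", class(traj))
  traj
}

#' Final-state endpoints of a trajectory
#'
#' @param traj An `ab_trajectory`.
#' @return Named numeric vector of the final row's pools.
#' @export
endpoints <- function(traj) {
  last <- traj[nrow(traj), ]
  stats::setNames(as.numeric(last[1, STATE_FIELDS_OUT]), STATE_FIELDS_OUT)
}

STATE_FIELDS_OUT <- c("t_days", "N", "M", "EC", "LRP", "C1", "C4", "C2", "C5",
                      "C3", "C6", "C9", "C10")

#' Mass-balance residual of a trajectory
#'
#' The ledger identity: for each species, cumulative generation must equal
#' the change in soluble stocks plus accumulated deposits plus cumulative
#' uptake, LRP-1 clearance and glymphatic exit. Returns the maximum relative
#' residual over all recorded rows and both species; a correctly wired run
#' stays below 1e-9 (the bookkeeping is exact up to float roundoff).
#'
#' @param traj An `ab_trajectory`.
#' @return Maximum relative residual (dimensionless).
#' @export
#' @examples
#' mass_balance_residual(run_simulation(years = 1))
mass_balance_residual <- function(traj) {
  if (nrow(traj) < 1) {
    rlang::abort("empty trajectory", class = "glymphsim_invalid_parameter")
  }
  d40 <- (traj$C1 - traj$C1[1]) + (traj$C2 - traj$C2[1]) +
    (traj$C3 - traj$C3[1]) + (traj$C9 - traj$C9[1]) +
    traj$cum_upt40 + traj$cum_lrp40 + traj$cum_exit40
  d42 <- (traj$C4 - traj$C4[1]) + (traj$C5 - traj$C5[1]) +
    (traj$C6 - traj$C6[1]) + (traj$C10 - traj$C10[1]) +
    traj$cum_upt42 + traj$cum_lrp42 + traj$cum_exit42
  r40 <- abs(traj$cum_gen40 - d40) / pmax(1, traj$cum_gen40)
  r42 <- abs(traj$cum_gen42 - d42) / pmax(1, traj$cum_gen42)
  max(r40, r42)
}

#' Fine-step reference integration
#'
#' Independent oracle for the daily map: classical fixed-step 4th-order
#' Runge-Kutta integration of the continuous-rate counterpart of the model
#' (annual loss fractions converted to continuous hazards
#' `-log(1 - r)/365`, daily fractions to `-log(1 - f)`), so cell pools have
#' identical closed forms in both schemes and the amyloid quasi-steady
#' levels agree. Intended for tests; records daily.
#'
#' @param scenario Scenario name or object.
#' @param years Horizon in years.
#' @param fine_dt Step in days, must be <= 0.25.
#' @param params Optional base parameter set.
#' @return A tibble with the 13 state columns (no ledger).
#' @export
reference_integrate <- function(scenario = "normal_aging", years = 50,
                                fine_dt = 0.25, params = NULL) {
  if (fine_dt > 0.25) {
    rlang::abort("fine_dt must be <= 0.25 days",
                 class = "glymphsim_invalid_parameter")
  }
  scen <- resolve_scenario(scenario)
  params <- scenario_params(scen, params)
  phys <- scenario_physiology(scen)
  C1_init <- pgml_to_molecules(params$C1_0, params$mw40, params$model_volume)

  hz <- function(annual) -log(1 - annual) / 365
  h_m <- -log(1 - params$k12)
  h_ec <- hz(params$k2)
  h_lrp <- hz(params$k10)
  L <- params$segment_length

  deriv <- function(t, y) {
    v <- isf_velocity(t, phys, params)
    lfrac <- min(y[["LRP"]] / params$LRP0, 1)
    r_n <- if (y[["C1"]] > params$theta_k1 * C1_init) params$d + params$k1 else params$d
    gen40 <- params$k3 * params$k4 * y[["N"]]
    gen42 <- params$k8 * params$k4 * y[["N"]]
    upt40 <- min(params$k5 * y[["M"]], y[["C1"]] / fine_dt)
    upt42 <- min(params$k11 * y[["M"]], y[["C4"]] / fine_dt)
    g40 <- (v / L) * y[["C1"]]
    g42 <- (v / L) * y[["C4"]]
    db40 <- params$k7a * y[["C1"]]
    db42 <- params$k9 * y[["C4"]]
    dv40 <- params$k7 * y[["C2"]]
    dv42 <- params$k9a * y[["C5"]]
    l40 <- params$k6 * lfrac * y[["C2"]]
    l42 <- params$k6 * lfrac * y[["C5"]]
    e40 <- params$k_exit * y[["C2"]]
    e42 <- params$k_exit * y[["C5"]]
    c(N = -hz(r_n) * y[["N"]],
      M = -h_m * y[["M"]],
      EC = -h_ec * y[["EC"]],
      LRP = -h_lrp * y[["LRP"]],
      C1 = gen40 - upt40 - g40 - db40,
      C4 = gen42 - upt42 - g42 - db42,
      C2 = g40 - l40 - e40 - dv40,
      C5 = g42 - l42 - e42 - dv42,
      C3 = dv40, C6 = dv42, C9 = db40, C10 = db42)
  }

  n_days <- round(years * 365)
  per_day <- round(1 / fine_dt)
  if (abs(per_day * fine_dt - 1) > 1e-12) {
    rlang::abort("fine_dt must divide one day evenly",
                 class = "glymphsim_invalid_parameter")
  }
  y <- initial_state(params)[-1] # drop t
  out <- matrix(NA_real_, nrow = n_days + 1, ncol = 13,
                dimnames = list(NULL, STATE_FIELDS_OUT))
  out[1, ] <- c(0, y)
  t <- 0
  h <- fine_dt
  for (day in seq_len(n_days)) {
    for (s in seq_len(per_day)) {
      k1v <- deriv(t, y)
      k2v <- deriv(t + h / 2, y + h / 2 * k1v)
      k3v <- deriv(t + h / 2, y + h / 2 * k2v)
      k4v <- deriv(t + h, y + h * k3v)
      y <- y + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
      y <- pmax(y, 0)
      t <- t + h
    }
    out[day + 1, ] <- c(day, y)
  }
  tibble::as_tibble(as.data.frame(out))
}

new_calibration <- function(parameter, fitted_value, anchor, achieved,
                            at_bound, extra = list()) {
  structure(c(list(parameter = parameter,
                   fitted_value = fitted_value,
                   anchor = anchor,
                   achieved = achieved,
                   residual = abs(achieved - anchor) / abs(anchor),
                   at_bound = at_bound),
              extra),
            class = "ab_calibration")
}

#' @export
print.ab_calibration <- function(x, ...) {
  cat(sprintf("<ab_calibration> %s = %.6g (anchor %.6g, achieved %.6g, relative residual %.3g%s)\n",
              x$parameter, x$fitted_value, x$anchor, x$achieved, x$residual,
              if (x$at_bound) ", AT BOUND" else ""))
  invisible(x)
}

#' Tidy a calibration result
#' @param x An `ab_calibration`.
#' @param ... Unused.
#' @return One-row tibble with parameter, fitted value, anchor, achieved
#'   value, relative residual and bound flag.
#' @method tidy ab_calibration
#' @export
tidy.ab_calibration <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, fitted_value = x$fitted_value,
                 anchor = x$anchor, achieved = x$achieved,
                 residual = x$residual, at_bound = x$at_bound)
}

#' Calibrate the baseline interstitial-fluid velocity
#'
#' Fits `v0` (mm/day) so that the 50-year normal-aging parenchymal Abeta40
#' deposit hits `anchor`. The deposit is strictly decreasing in `v0` (faster
#' flow sweeps soluble amyloid out of the parenchyma before it can deposit),
#' so bisection over the literature range has a unique solution; if the
#' anchor is unreachable the nearer bound is returned with `at_bound = TRUE`
#' and the residual reported.
#'
#' @param params Base parameter set (default [default_params()]).
#' @param anchor Target parenchymal Abeta40 deposit after `years`, molecules.
#' @param years Horizon in years (default 50).
#' @param bounds Search range for `v0`, mm/day (default the literature range
#'   `c(0.144, 0.43)`).
#' @param tol Relative tolerance on `v0` (default 1e-5).
#' @return An `ab_calibration` (see [tidy.ab_calibration()]).
#' @export
calibrate_v0 <- function(params = default_params(), anchor = 5.929e9,
                         years = 50, bounds = c(0.144, 0.43), tol = 1e-5) {
  if (anchor <= 0) {
    rlang::abort("anchor must be positive", class = "glymphsim_invalid_parameter")
  }
  dep_at <- function(v0) {
    p <- update_params(params, v0 = v0)
    traj <- run_simulation("normal_aging", years = years,
                           record_stride = years * 365, params = p)
    endpoints(traj)[["C9"]]
  }
  f_lo <- dep_at(bounds[1]) - anchor
  f_hi <- dep_at(bounds[2]) - anchor
  if (f_lo < 0) { # even slowest flow deposits too little
    return(new_calibration("v0", bounds[1], anchor, f_lo + anchor, TRUE))
  }
  if (f_hi > 0) { # even fastest flow deposits too much
    return(new_calibration("v0", bounds[2], anchor, f_hi + anchor, TRUE))
  }
  root <- stats::uniroot(function(v) dep_at(v) - anchor,
                         interval = bounds, f.lower = f_lo, f.upper = f_hi,
                         tol = tol * diff(bounds))
  new_calibration("v0", root$root, anchor, dep_at(root$root), FALSE)
}

#' Calibrate the perivascular glymphatic exit rate
#'
#' Fits `k_exit` (fraction/day) so that the ratio of the 50-year vessel-wall
#' Abeta40 deposit under the ApoE4 allele (k6 = 0.12/day) to the normal-aging
#' value (k6 = 0.4/day) equals `anchor_ratio`. A larger exit rate dilutes the
#' difference the two transport constants make, so the ratio is strictly
#' decreasing in `k_exit` and bisection has a unique solution within bounds.
#'
#' The result also reports `lrp_share`: the realized fraction of all Abeta40
#' leaving the perivascular space that went through LRP-1 in the baseline
#' run (a diagnostic, not an enforced constraint).
#'
#' @param params Base parameter set.
#' @param anchor_ratio Target vessel deposit ratio, > 1 (default 1.96).
#' @param years Horizon in years.
#' @param bounds Search range for `k_exit`, fraction/day (default `c(0, 2)`).
#' @param tol Relative tolerance (default 1e-5).
#' @return An `ab_calibration` with extra element `lrp_share`.
#' @export
calibrate_k_exit <- function(params = default_params(), anchor_ratio = 1.96,
                             years = 50, bounds = c(0, 2), tol = 1e-5) {
  if (anchor_ratio <= 1) {
    rlang::abort("anchor_ratio must exceed 1", class = "glymphsim_invalid_parameter")
  }
  run_pair <- function(k_exit) {
    p <- update_params(params, k_exit = k_exit)
    base <- run_simulation("normal_aging", years = years,
                           record_stride = years * 365, params = p)
    apo <- run_simulation("apoe4", years = years,
                          record_stride = years * 365, params = p)
    list(base = base, apo = apo,
         ratio = endpoints(apo)[["C3"]] / endpoints(base)[["C3"]])
  }
  r_lo <- run_pair(bounds[1])
  if (r_lo$ratio < anchor_ratio) {
    return(new_calibration("k_exit", bounds[1], anchor_ratio, r_lo$ratio, TRUE,
                           extra = list(lrp_share = lrp_share(r_lo$base))))
  }
  r_hi <- run_pair(bounds[2])
  if (r_hi$ratio > anchor_ratio) {
    return(new_calibration("k_exit", bounds[2], anchor_ratio, r_hi$ratio, TRUE,
                           extra = list(lrp_share = lrp_share(r_hi$base))))
  }
  root <- stats::uniroot(function(k) run_pair(k)$ratio - anchor_ratio,
                         interval = bounds,
                         f.lower = r_lo$ratio - anchor_ratio,
                         f.upper = r_hi$ratio - anchor_ratio,
                         tol = tol * diff(bounds))
  fit <- run_pair(root$root)
  new_calibration("k_exit", root$root, anchor_ratio, fit$ratio, FALSE,
                  extra = list(lrp_share = lrp_share(fit$base)))
}

# fraction of Abeta40 leaving the PVS that went through LRP-1
lrp_share <- function(traj) {
  e <- endpoints(traj)
  last <- traj[nrow(traj), ]
  out <- last$cum_lrp40 + last$cum_exit40 + e[["C3"]]
  if (out <= 0) return(NA_real_)
  last$cum_lrp40 / out
}

#' Write a trajectory to CSV
#'
#' Fixed header (`t_days, N, M, EC, LRP, C1, C4, C2, C5, C3, C6, C9, C10,
#' cum_gen40, ... cum_exit42`), full double precision, period decimal
#' separator, no grouping.
#'
#' @param traj An `ab_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(all(TRAJ_COLS %in% names(traj)))
  cols <- lapply(traj[TRAJ_COLS], function(x) sprintf("%.17g", x))
  lines <- c(paste(TRAJ_COLS, collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}
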