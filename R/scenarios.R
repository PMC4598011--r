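#' Define a simulation scenario
#'
#' A scenario is a named bundle of physiology settings (heart rate, vessel
#' stiffness profile, ApoE allele) plus optional parameter overrides that
#' defines one simulation arm.
#'
#' @param name Scenario label (unique within a registry).
#' @param heart_rate Beats per minute (default 60).
#' @param stiffness An [stiffness_profile()] or `NULL` for no stiffening.
#' @param apoe ApoE allele ("E3" default).
#' @param k4_override Replacement value for the stimulated-generation
#'   multiplier `k4`, or `NULL`.
#' @param param_overrides Named list of further parameter overrides.
#' @param notes Free-text description.
#' @return An object of class `ab_scenario`.
#' @export
#' @examples
#' scenario("tachycardia", heart_rate = 120)
scenario <- function(name, heart_rate = 60, stiffness = NULL,
                     apoe = c("E3", "E2", "E4"), k4_override = NULL,
                     param_overrides = list(), notes = "") {
  apoe <- match.arg(apoe)
  if (!is.character(name) || length(name) != 1 || nchar(name) == 0) {
    rlang::abort("name must be a non-empty string",
                 class = "glymphsim_invalid_parameter")
  }
  if (!is.null(stiffness) && !inherits(stiffness, "ab_stiffness")) {
    rlang::abort("stiffness must be NULL or from stiffness_profile()",
                 class = "glymphsim_invalid_parameter")
  }
  structure(list(name = name, heart_rate = heart_rate, stiffness = stiffness,
                 apoe = apoe, k4_override = k4_override,
                 param_overrides = param_overrides, notes = notes),
            class = "ab_scenario")
}

#' @export
print.ab_scenario <- function(x, ...) {
  cat(sprintf("<ab_scenario> %s: HR %g bpm, ApoE %s%s%s\n", x$name,
              x$heart_rate, x$apoe,
              if (is.null(x$stiffness)) "" else
                sprintf(", stiffness x%g (%s)", x$stiffness$fold_change,
                        x$stiffness$law),
              if (is.null(x$k4_override)) "" else
                sprintf(", k4 = %g", x$k4_override)))
  invisible(x)
}

#' Built-in scenario registry
#'
#' The nine standard simulation arms: normal aging (the baseline all reports
#' normalize to), bradycardia (HR 50), elevated heart rate (HR 90), two-fold
#' vessel stiffening, the ApoE4 allele, the three pairwise combinations, and
#' doubled stimulated amyloid generation (`k4` 1.5 to 2).
#'
#' Stiffness arms default to the `flow_off` compliance law, under which
#' convective inflow to the perivascular space is shut down for the whole
#' run; this reproduces the qualitative signature of vessel stiffening
#' (parenchymal deposits explode, vessel deposits collapse, extra neuron
#' loss). The `inverse` law remains selectable via [scenario()].
#'
#' @return Named list of nine [scenario()] objects.
#' @export
#' @examples
#' names(builtin_scenarios())
builtin_scenarios <- function() {
  stiff <- stiffness_profile(fold_change = 2, duration = 18250,
                             law = "flow_off")
  scens <- list(
    scenario("normal_aging", notes = "baseline: HR 60, ApoE3, no stiffening"),
    scenario("bradycardia", heart_rate = 50, notes = "HR 60 -> 50"),
    scenario("elevated_hr", heart_rate = 90, notes = "HR 60 -> 90 (exercise)"),
    scenario("stiffness_2x", stiffness = stiff,
             notes = "two-fold exponential wall stiffening"),
    scenario("apoe4", apoe = "E4", notes = "LRP-1 transport 0.4 -> 0.12/day"),
    scenario("apoe4_bradycardia", heart_rate = 50, apoe = "E4"),
    scenario("apoe4_stiffness", stiffness = stiff, apoe = "E4"),
    scenario("bradycardia_stiffness", heart_rate = 50, stiffness = stiff),
    scenario("generation_2x", k4_override = 2,
             notes = "stimulated generation multiplier 1.5 -> 2")
  )
  stats::setNames(scens, vapply(scens, `[[`, character(1), "name"))
}

#' Run several scenarios
#'
#' @param scenarios A named list of scenarios (default the full registry) or
#'   a character vector of registry names.
#' @param years,dt,record_stride,params Passed to [run_simulation()].
#' @return Named list of `ab_trajectory` objects.
#' @export
run_scenarios <- function(scenarios = builtin_scenarios(), years = 50,
                          dt = 1, record_stride = 1, params = NULL) {
  if (is.character(scenarios)) {
    scenarios <- builtin_scenarios()[scenarios]
  }
  purrr::map(scenarios, run_simulation, years = years, dt = dt,
             record_stride = record_stride, params = params)
}

#' Normalized endpoint report
#'
#' For each scenario trajectory, extracts the four 50-year deposit endpoints
#' (parenchymal and vessel-wall, Abeta40 and Abeta42) and normalizes them to
#' the baseline run, giving the ratio-to-baseline and percent-of-baseline
#' representations. A zero baseline endpoint yields an `NA` ratio (flagged
#' in `ratio_defined`), never an error.
#'
#' @param trajectories Named list of `ab_trajectory` objects (names become
#'   the scenario column).
#' @param baseline The baseline `ab_trajectory` (same horizon and grid).
#' @return A tibble with columns `scenario`, `compartment`
#'   (parenchyma/vessel), `species` (Abeta40/Abeta42), `endpoint_molecules`,
#'   `ratio_to_baseline`, `percent_of_baseline`, `ratio_defined`.
#' @export
#' @examples
#' trajs <- run_scenarios(c("normal_aging", "bradycardia"), years = 2)
#' normalized_report(trajs, trajs$normal_aging)
normalized_report <- function(trajectories, baseline) {
  stopifnot(is.list(trajectories), length(trajectories) > 0)
  horizon <- function(tr) tr$t_days[nrow(tr)]
  h0 <- horizon(baseline)
  bad <- names(trajectories)[vapply(trajectories, horizon, numeric(1)) != h0]
  if (length(bad) > 0) {
    rlang::abort(paste0("horizon mismatch with baseline: ",
                        paste(bad, collapse = ", ")),
                 class = "glymphsim_invalid_input")
  }
  pool_map <- tibble::tibble(
    pool = c("C9", "C10", "C3", "C6"),
    compartment = c("parenchyma", "parenchyma", "vessel", "vessel"),
    species = c("Abeta40", "Abeta42", "Abeta40", "Abeta42")
  )
  base_end <- endpoints(baseline)
  rows <- purrr::imap(trajectories, function(tr, nm) {
    e <- endpoints(tr)
    dplyr::mutate(pool_map,
                  scenario = nm,
                  endpoint_molecules = as.numeric(e[.data$pool]),
                  baseline_molecules = as.numeric(base_end[.data$pool]))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
    ratio_defined = .data$baseline_molecules > 0,
    ratio_to_baseline = dplyr::if_else(.data$ratio_defined,
                                       .data$endpoint_molecules / .data$baseline_molecules,
                                       NA_real_),
    percent_of_baseline = 100 * .data$ratio_to_baseline
  )
  dplyr::select(out, "scenario", "compartment", "species",
                "endpoint_molecules", "ratio_to_baseline",
                "percent_of_baseline", "ratio_defined")
}

#' Run the full scenario table
#'
#' Convenience wrapper: runs all nine built-in scenarios and returns the
#' normalized endpoint report (the baseline row has all ratios exactly 1).
#'
#' @param years,dt,params Passed to [run_simulation()].
#' @return A [normalized_report()] tibble (36 rows).
#' @export
run_report <- function(years = 50, dt = 1, params = NULL) {
  trajs <- run_scenarios(builtin_scenarios(), years = years, dt = dt,
                         record_stride = years * 365, params = params)
  normalized_report(trajs, trajs$normal_aging)
}

#' One-at-a-time sensitivity sweep
#'
#' Re-runs a scenario with one estimated parameter swept over a list of
#' values, returning the four deposit endpoints and their relative change
#' against the scenario's default run. Sweepable parameters:
#' `pvs_init_fraction_scale` (multiplier on the initial perivascular
#' amyloid) and `k4` (the stimulated-generation multiplier).
#'
#' @param param_name `"pvs_init_fraction_scale"` or `"k4"`.
#' @param values Positive finite sweep values (may be empty).
#' @param scenario Scenario name or object (default baseline).
#' @param years,dt,params Passed to [run_simulation()].
#' @return A tibble with columns `param`, `value`, `pool`, `compartment`,
#'   `species`, `endpoint_molecules`, `rel_change_vs_default`.
#' @export
#' @examples
#' sensitivity_sweep("k4", c(1.5, 2), years = 2)
sensitivity_sweep <- function(param_name, values, scenario = "normal_aging",
                              years = 50, dt = 1, params = NULL) {
  if (!param_name %in% c("pvs_init_fraction_scale", "k4")) {
    rlang::abort("param_name must be \"pvs_init_fraction_scale\" or \"k4\"",
                 class = "glymphsim_invalid_parameter")
  }
  cols <- c("param", "value", "pool", "compartment", "species",
            "endpoint_molecules", "rel_change_vs_default")
  pool_map <- tibble::tibble(
    pool = c("C9", "C10", "C3", "C6"),
    compartment = c("parenchyma", "parenchyma", "vessel", "vessel"),
    species = c("Abeta40", "Abeta42", "Abeta40", "Abeta42")
  )
  if (length(values) == 0) {
    return(tibble::tibble(param = character(0), value = numeric(0),
                          pool = character(0), compartment = character(0),
                          species = character(0),
                          endpoint_molecules = numeric(0),
                          rel_change_vs_default = numeric(0)))
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    rlang::abort("sweep values must be positive and finite",
                 class = "glymphsim_invalid_parameter")
  }
  run_value <- function(v) {
    stride <- years * 365
    if (param_name == "pvs_init_fraction_scale") {
      run_simulation(scenario, years = years, dt = dt, params = params,
                     record_stride = stride, pvs_init_scale = v)
    } else {
      scen <- resolve_scenario(scenario)
      scen$k4_override <- v
      run_simulation(scen, years = years, dt = dt, params = params,
                     record_stride = stride)
    }
  }
  default_end <- endpoints(run_value(if (param_name == "k4") {
    p <- scenario_params(resolve_scenario(scenario), params)
    p$k4
  } else 1))
  rows <- purrr::map(values, function(v) {
    e <- endpoints(run_value(v))
    dplyr::mutate(pool_map,
                  param = param_name, value = v,
                  endpoint_molecules = as.numeric(e[.data$pool]),
                  rel_change_vs_default =
                    as.numeric(e[.data$pool]) / as.numeric(default_end[.data$pool]) - 1)
  })
  dplyr::select(dplyr::bind_rows(rows), dplyr::all_of(cols))
}

#' Write a normalized report to CSV
#'
#' @param report A [normalized_report()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pretty text rendering of a normalized report
#'
#' @param report A [normalized_report()] tibble.
#' @return Character vector of lines (also printed is left to the caller).
#' @export
format_report <- function(report) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(report,
                  cell = sprintf("%.4g", .data$ratio_to_baseline),
                  col = paste(.data$compartment, .data$species, sep = "_")),
    id_cols = "scenario", names_from = "col", values_from = "cell")
  header <- sprintf("%-24s %18s %18s %18s %18s", "scenario",
                    "parench_Ab40", "parench_Ab42", "vessel_Ab40", "vessel_Ab42")
  body <- sprintf("%-24s %18s %18s %18s %18s", wide$scenario,
                  wide$parenchyma_Abeta40, wide$parenchyma_Abeta42,
                  wide$vessel_Abeta40, wide$vessel_Abeta42)
  c(header, body)
}
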