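#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

AVOGADRO <- 6.02214076e23

# nearest integer, ties away from zero (round() would go to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Geometric constants of the modeled tissue volume
#'
#' The simulator describes a 1 mm^3 volume of CA1 hippocampal tissue threaded
#' by parallel capillaries. Capillaries are ~8 um in diameter, separated by
#' 40 um, with 1 mm linear segments; a single polygonal endothelial cell wraps
#' the full ~25 um circumference and is ~20 um wide, giving 5 endothelial
#' cells per 100 um of capillary length.
#'
#' @param model_volume Tissue volume modeled, mm^3.
#' @param capillary_diameter Capillary diameter, um.
#' @param capillary_separation Distance between neighbouring capillaries, um.
#' @param segment_length Linear capillary segment length, mm.
#' @param ec_width Endothelial cell width along the capillary axis, um.
#' @param ec_circumference Wrapped endothelial cell circumference, um.
#'
#' @return A named list of validated geometric constants.
#' @export
#' @examples
#' geometry_constants()
geometry_constants <- function(model_volume = 1,
                               capillary_diameter = 8,
                               capillary_separation = 40,
                               segment_length = 1,
                               ec_width = 20,
                               ec_circumference = 25) {
  g <- list(
    model_volume = model_volume,
    capillary_diameter = capillary_diameter,
    capillary_separation = capillary_separation,
    segment_length = segment_length,
    ec_width = ec_width,
    ec_circumference = ec_circumference
  )
  bad <- names(g)[!vapply(g, function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("geometry constants must be single positive numbers; offending: ",
                 paste(bad, collapse = ", ")), class = "glymphsim_invalid_parameter")
  }
  if (capillary_separation <= capillary_diameter) {
    abort("capillary_separation must exceed capillary_diameter",
          class = "glymphsim_invalid_parameter")
  }
  g
}

#' Convert a pg/mL concentration to a molecule count in the model volume
#'
#' Table-style amyloid concentrations are reported in pg/mL while generation
#' and uptake rates are in molecules/day, so initial conditions are converted
#' to molecules at load time using the monomer molar mass.
#'
#' @param conc Concentration in pg/mL (1 pg/mL = 1e-3 pg/mm^3).
#' @param molar_mass Molar mass in Da (g/mol); Abeta40 = 4330, Abeta42 = 4514.
#' @param volume Tissue volume in mm^3 (default 1).
#'
#' @return Number of molecules in `volume` (double, not rounded).
#' @export
#' @examples
#' pgml_to_molecules(450, 4330) # ~6.26e7 molecules of Abeta40 per mm^3
pgml_to_molecules <- function(conc, molar_mass, volume = 1) {
  if (any(!is.finite(molar_mass)) || any(molar_mass <= 0)) {
    abort("molar_mass must be positive", class = "glymphsim_invalid_parameter")
  }
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    abort("volume must be positive", class = "glymphsim_invalid_parameter")
  }
  if (any(conc < 0)) {
    abort("conc must be non-negative", class = "glymphsim_invalid_parameter")
  }
  # pg/mL -> pg/mm^3 (1e-3), x volume -> pg, -> grams (1e-12), -> mol -> molecules
  conc * 1e-3 * volume * 1e-12 / molar_mass * AVOGADRO
}

#' Convert an annual loss fraction to the equivalent daily fraction
#'
#' Geometric compounding: 365 applications of the daily fraction reproduce the
#' annual fraction exactly, so e.g. 1 %/yr natural neuron loss yields exactly
#' 50% loss over 69 years of daily steps.
#'
#' @param rate Annual loss fraction in `[0, 1)`.
#' @return Daily loss fraction `1 - (1 - rate)^(1/365)`.
#' @export
#' @examples
#' annual_to_daily(0.01)
annual_to_daily <- function(rate) {
  if (any(!is.finite(rate)) || any(rate < 0) || any(rate >= 1)) {
    abort("annual rate must satisfy 0 <= rate < 1",
          class = "glymphsim_invalid_parameter")
  }
  1 - (1 - rate)^(1 / 365)
}

#' Endothelial cells per capillary segment
#'
#' One polygonal endothelial cell wraps the full capillary circumference, so
#' the count along a segment is length over cell width, rounded to the
#' nearest integer (ties away from zero).
#'
#' @param diameter Capillary diameter, um (not used by the count itself but
#'   validated as part of the geometry).
#' @param ec_width Endothelial cell width, um.
#' @param length Segment length, um.
#' @return Integer cell count.
#' @export
#' @examples
#' ec_per_capillary_length(8, 20, 100) # 5 cells per 100 um
ec_per_capillary_length <- function(diameter = 8, ec_width = 20, length = 100) {
  if (any(c(diameter, ec_width, length) <= 0)) {
    abort("all geometry arguments must be positive",
          class = "glymphsim_invalid_parameter")
  }
  as.integer(round_half_away(length / ec_width))
}

#' Capillaries across one edge of the model volume
#'
#' Capillaries are laid out on a square lattice with pitch
#' `diameter + separation`; a 1 mm edge holds a 21-by-21 array.
#'
#' @param edge Edge length, um.
#' @param diameter Capillary diameter, um.
#' @param separation Capillary separation, um.
#' @return Integer capillary count per edge.
#' @export
#' @examples
#' capillaries_per_edge(1000, 8, 40) # 21
capillaries_per_edge <- function(edge = 1000, diameter = 8, separation = 40) {
  if (any(c(edge, diameter, separation) <= 0)) {
    abort("all geometry arguments must be positive",
          class = "glymphsim_invalid_parameter")
  }
  as.integer(round_half_away(edge / (diameter + separation)))
}

#' MRI-derived hippocampal volumes by cohort
#'
#' Baseline whole-hippocampus volume and annual volume loss for healthy,
#' mild-cognitive-impairment and Alzheimer's cohorts, as measured by
#' longitudinal MRI.
#'
#' @return A tibble with columns `cohort`, `baseline_volume` (mm^3) and
#'   `loss_rate` (mm^3/year, negative = shrinkage).
#' @export
#' @examples
#' hippocampal_volumes()
hippocampal_volumes <- function() {
  tibble(
    cohort = c("healthy", "MCI", "AD"),
    baseline_volume = c(2133, 1846, 1631),
    loss_rate = c(-17.3, -47.5, -72.0)
  )
}

#' Annual percent volume loss
#'
#' Adds a `percent_per_year` column (signed, % of baseline volume lost per
#' year) to a volume table such as [hippocampal_volumes()].
#'
#' @param volumes Data frame with columns `baseline_volume` (mm^3, > 0) and
#'   `loss_rate` (mm^3/year).
#' @return The input as a tibble with `percent_per_year` appended.
#' @export
#' @examples
#' percent_loss_per_year(hippocampal_volumes())
percent_loss_per_year <- function(volumes) {
  stopifnot(is.data.frame(volumes))
  if (!all(c("baseline_volume", "loss_rate") %in% names(volumes))) {
    abort("volumes needs columns baseline_volume and loss_rate",
          class = "glymphsim_invalid_parameter")
  }
  if (any(volumes$baseline_volume <= 0)) {
    abort("baseline_volume must be positive",
          class = "glymphsim_invalid_parameter")
  }
  dplyr::mutate(as_tibble(volumes),
                percent_per_year = 100 * .data$loss_rate / .data$baseline_volume)
}

#' Endothelial senescence rate presets
#'
#' The default simulation uses 1 %/yr endothelial senescence, which carries
#' the LRP-1 receptor pool to ~60% of its initial value over 50 years
#' (0.99^50 = 0.605). The unstimulated and stimulated literature rates are
#' kept as named presets.
#'
#' @return A tibble with columns `preset` and `k2` (fraction/year).
#' @export
ec_senescence_rates <- function() {
  tibble(
    preset = c("default", "no_stimulus", "stimulus"),
    k2 = c(0.01, 0.001, 0.017)
  )
}

# every legal ModelParams field, in canonical order
PARAM_FIELDS <- c(
  "d", "k1", "k2", "k3", "k8", "k4", "k5", "k11", "k6", "k7", "k9a",
  "k7a", "k9", "k10", "k12", "N0", "M0", "EC0", "LRP0", "C1_0", "C4_0",
  "pvs_init_fraction", "v0", "k_exit", "theta_k1", "mw40", "mw42",
  "model_volume", "segment_length"
)

#' Default model parameters
#'
#' Returns the full validated parameter set for a given ApoE allele. Units:
#' `d`, `k1`, `k2`, `k10` are fractions/year; `k12`, `k6`, `k7`, `k9a`,
#' `k7a`, `k9`, `k_exit` are fractions/day; `k3`, `k8` molecules/neuron/day;
#' `k5`, `k11` molecules/microglia/day; `k4` a dimensionless generation
#' multiplier; `C1_0`, `C4_0` pg/mL; `v0` mm/day; `mw40`, `mw42` Da;
#' `N0`, `M0`, `EC0`, `LRP0` counts per model volume.
#'
#' ApoE4 slows effective LRP-1 transport: `k6` is 0.4/day for the E2/E3
#' alleles and 0.12/day for E4. The endothelial pool `EC0` is derived from
#' the capillary lattice geometry (21 x 21 capillaries x 50 cells each).
#' `v0` (baseline interstitial-fluid velocity) and `k_exit` (perivascular
#' glymphatic exit rate toward cervical lymph) default to their calibrated
#' values 0.2946 mm/day and 0.1304/day; see [calibrate_v0()] and
#' [calibrate_k_exit()].
#'
#' @param apoe ApoE allele, one of "E2", "E3", "E4".
#' @return A validated named list of class `ab_params`.
#' @export
#' @examples
#' p <- default_params("E4")
#' p$k6
default_params <- function(apoe = c("E3", "E2", "E4")) {
  if (!is.character(apoe) || !all(apoe %in% c("E2", "E3", "E4"))) {
    abort("apoe must be one of \"E2\", \"E3\", \"E4\"",
          class = "glymphsim_invalid_parameter")
  }
  apoe <- apoe[1]
  geom <- geometry_constants()
  n_edge <- capillaries_per_edge(1000 * geom$model_volume^(1 / 3),
                                 geom$capillary_diameter,
                                 geom$capillary_separation)
  ec_per_cap <- ec_per_capillary_length(geom$capillary_diameter,
                                        geom$ec_width,
                                        1000 * geom$segment_length)
  params <- list(
    d = 0.01,          # natural neuron loss, fraction/yr
    k1 = 0.034,        # amyloid-stimulated extra neuron loss, fraction/yr
    k2 = 0.01,         # endothelial senescence, fraction/yr (see ec_senescence_rates)
    k3 = 16000,        # Abeta40 generation, molecules/neuron/day
    k8 = 3000,         # Abeta42 generation, molecules/neuron/day
    k4 = 1.5,          # stimulated-generation multiplier, dimensionless
    k5 = 1400,         # microglial Abeta40 uptake, molecules/microglia/day
    k11 = 200,         # microglial Abeta42 uptake, molecules/microglia/day
    k6 = if (apoe == "E4") 0.12 else 0.4, # LRP-1 transport, fraction/day
    k7 = 0.004,        # Abeta40 vessel-wall deposition, fraction/day
    k9a = 0.002,       # Abeta42 vessel-wall deposition, fraction/day
    k7a = 0.001,       # Abeta40 parenchymal deposition, fraction/day
    k9 = 0.001,        # Abeta42 parenchymal deposition, fraction/day
    k10 = 0.01,        # LRP-1 receptor loss, fraction/yr (= k2)
    k12 = 7.3e-5,      # microglial conversion to dystrophy, fraction/day
    N0 = 5275,         # neurons per model volume
    M0 = 4500,         # microglia per model volume
    EC0 = n_edge^2 * ec_per_cap, # endothelial cells per model volume
    LRP0 = 9.3e11,     # LRP-1 receptors per model volume
    C1_0 = 450,        # initial parenchymal Abeta40, pg/mL
    C4_0 = 70,         # initial parenchymal Abeta42, pg/mL
    pvs_init_fraction = 0.10, # initial PVS amyloid as fraction of parenchymal
    v0 = 0.2946,       # baseline ISF bulk velocity, mm/day (calibrated)
    k_exit = 0.1304,   # PVS glymphatic exit to cervical lymph, fraction/day (calibrated)
    theta_k1 = 20,     # neuron-loss trigger, multiple of initial parenchymal Abeta40
    mw40 = 4330,       # Abeta40 monomer mass, Da
    mw42 = 4514,       # Abeta42 monomer mass, Da
    model_volume = geom$model_volume,    # mm^3
    segment_length = geom$segment_length # mm, convective path length
  )
  class(params) <- "ab_params"
  validate_params(params)
}

#' Validate a model parameter set
#'
#' Checks completeness, non-negativity of all rates, the literature bounds on
#' `v0` (0.144-0.43 mm/day), `pvs_init_fraction` in (0, 1], and positive
#' initial pools. Warns (once) if `k10` was decoupled from `k2`.
#'
#' @param params A parameter list as produced by [default_params()].
#' @return The validated parameter list, invisibly classed `ab_params`.
#' @export
validate_params <- function(params) {
  if (!is.list(params)) {
    abort("params must be a list", class = "glymphsim_invalid_parameter")
  }
  missing <- setdiff(PARAM_FIELDS, names(params))
  if (length(missing) > 0) {
    abort(paste0("params is missing fields: ", paste(missing, collapse = ", ")),
          class = "glymphsim_invalid_parameter")
  }
  unknown <- setdiff(names(params), PARAM_FIELDS)
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter fields: ", paste(unknown, collapse = ", ")),
          class = "glymphsim_invalid_parameter")
  }
  num_ok <- vapply(params[PARAM_FIELDS],
                   function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                   logical(1))
  if (!all(num_ok)) {
    abort(paste0("non-numeric or non-finite parameter(s): ",
                 paste(PARAM_FIELDS[!num_ok], collapse = ", ")),
          class = "glymphsim_invalid_parameter")
  }
  rates <- c("d", "k1", "k2", "k3", "k8", "k4", "k5", "k11", "k6", "k7",
             "k9a", "k7a", "k9", "k10", "k12", "k_exit")
  neg <- rates[vapply(params[rates], function(x) x < 0, logical(1))]
  if (length(neg) > 0) {
    abort(paste0("rates must be non-negative: ", paste(neg, collapse = ", ")),
          class = "glymphsim_invalid_parameter")
  }
  annual <- c("d", "k1", "k2", "k10")
  too_big <- annual[vapply(params[annual], function(x) x >= 1, logical(1))]
  if (length(too_big) > 0) {
    abort(paste0("annual fractions must be < 1: ", paste(too_big, collapse = ", ")),
          class = "glymphsim_invalid_parameter")
  }
  if (params$v0 < 0.144 || params$v0 > 0.43) {
    abort("v0 must lie in the literature range [0.144, 0.43] mm/day",
          class = "glymphsim_invalid_parameter")
  }
  if (params$pvs_init_fraction <= 0 || params$pvs_init_fraction > 1) {
    abort("pvs_init_fraction must lie in (0, 1]",
          class = "glymphsim_invalid_parameter")
  }
  pools <- c("N0", "M0", "EC0", "LRP0", "mw40", "mw42", "model_volume",
             "segment_length")
  nonpos <- pools[vapply(params[pools], function(x) x <= 0, logical(1))]
  if (length(nonpos) > 0) {
    abort(paste0("must be positive: ", paste(nonpos, collapse = ", ")),
          class = "glymphsim_invalid_parameter")
  }
  if (params$C1_0 < 0 || params$C4_0 < 0 || params$theta_k1 <= 0) {
    abort("C1_0, C4_0 must be non-negative and theta_k1 positive",
          class = "glymphsim_invalid_parameter")
  }
  class(params) <- "ab_params"
  invisible(params)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced. Unknown field
#' names are rejected (fail-closed: a typo in a rate-constant name must not
#' silently leave the default in place). Overriding `k2` also moves `k10`
#' with it unless `k10` is overridden explicitly, preserving the model's
#' coupling of receptor loss to endothelial senescence.
#'
#' @param params A parameter list from [default_params()].
#' @param ... Named scalar overrides, e.g. `k6 = 0.12`.
#' @return The modified, revalidated parameter list.
#' @export
#' @examples
#' update_params(default_params(), k4 = 2)
update_params <- function(params, ...) {
  overrides <- list(...)
  if (length(overrides) == 0) return(validate_params(params))
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    abort("all overrides must be named", class = "glymphsim_invalid_parameter")
  }
  unknown <- setdiff(names(overrides), PARAM_FIELDS)
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter field(s): ", paste(unknown, collapse = ", "),
                 "; valid fields are: ", paste(PARAM_FIELDS, collapse = ", ")),
          class = "glymphsim_invalid_parameter")
  }
  if ("k2" %in% names(overrides) && !("k10" %in% names(overrides))) {
    overrides$k10 <- overrides$k2
  }
  params[names(overrides)] <- overrides
  validate_params(params)
}

#' @export
print.ab_params <- function(x, ...) {
  cat("<ab_params> model parameter set\n")
  flat <- unlist(x[PARAM_FIELDS])
  print(flat)
  invisible(x)
}

#' Tidy a parameter set into a long tibble
#'
#' @param x An `ab_params` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `value`.
#' @method tidy ab_params
#' @export
tidy.ab_params <- function(x, ...) {
  tibble(parameter = PARAM_FIELDS,
         value = unlist(x[PARAM_FIELDS], use.names = FALSE))
}
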