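# Minimal reader for the flat key = value configuration dialect used by run
# and parameter files: one `key = value` pair per line, `#` comments, quoted
# strings, booleans, numbers, and [..] arrays of those; dotted keys stay flat.
read_flat_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path),
                 class = "glymphsim_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  out <- list()
  parse_scalar <- function(tok, lineno) {
    tok <- trimws(tok)
    if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
    if (tok %in% c("true", "false")) return(tok == "true")
    num <- suppressWarnings(as.numeric(tok))
    if (!is.na(num)) return(num)
    rlang::abort(sprintf("config line %d: cannot parse value `%s`", lineno, tok),
                 class = "glymphsim_config_error")
  }
  strip_comment <- function(line) {
    chars <- strsplit(line, "")[[1]]
    inq <- FALSE
    for (j in seq_along(chars)) {
      if (chars[j] == '"') inq <- !inq
      else if (chars[j] == "#" && !inq) return(substr(line, 1, j - 1))
    }
    line
  }
  for (i in seq_along(lines)) {
    line <- trimws(strip_comment(lines[i]))
    if (line == "" || startsWith(line, "#")) next
    if (grepl("^\\[.*\\]$", line)) {
      rlang::abort(sprintf("config line %d: tables are not supported; use dotted keys", i),
                   class = "glymphsim_config_error")
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) {
      rlang::abort(sprintf("config line %d is not a key = value pair", i),
                   class = "glymphsim_config_error")
    }
    key <- trimws(substr(line, 1, eq - 1))
    val <- trimws(substr(line, eq + 1, nchar(line)))
    if (!grepl("^[A-Za-z0-9_.]+$", key)) {
      rlang::abort(sprintf("config line %d: malformed key `%s`", i, key),
                   class = "glymphsim_config_error")
    }
    if (grepl("^\\[.*\\]$", val)) {
      inner <- trimws(gsub("^\\[|\\]$", "", val))
      toks <- if (inner == "") character(0) else strsplit(inner, ",")[[1]]
      out[[key]] <- unlist(lapply(toks, parse_scalar, lineno = i))
    } else {
      out[[key]] <- parse_scalar(val, i)
    }
  }
  out
}

RUN_CONFIG_KEYS <- c("scenario", "years", "dt", "record_stride", "output_dir",
                     "formats", "heart_rate", "apoe",
                     "stiffness.fold_change", "stiffness.duration_days",
                     "stiffness.compliance_law")

#' Load a run configuration file
#'
#' Reads a flat `key = value` configuration (see `inst/extdata` for an
#' example) into a validated run configuration. Recognized keys:
#' `scenario`, `years`, `dt`, `record_stride`, `output_dir`, `formats`,
#' `heart_rate`, `apoe`, `stiffness.fold_change`, `stiffness.duration_days`,
#' `stiffness.compliance_law`, and any model parameter field name (e.g.
#' `k6 = 0.2`) as an override. Unknown keys are rejected outright: a typo in
#' a rate-constant name must fail loudly, not silently simulate the default.
#'
#' @param path Path to the configuration file.
#' @return A list of class `ab_run_config` with elements `scenario` (an
#'   [scenario()] object), `years`, `dt`, `record_stride`, `output_dir`,
#'   `formats`.
#' @export
load_config <- function(path) {
  raw <- read_flat_config(path)
  keys <- names(raw)
  unknown <- setdiff(keys, c(RUN_CONFIG_KEYS, PARAM_FIELDS))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
                 class = "glymphsim_config_error")
  }
  get_or <- function(key, default) if (key %in% keys) raw[[key]] else default

  scen_name <- get_or("scenario", "normal_aging")
  overrides <- raw[intersect(keys, PARAM_FIELDS)]

  inline <- any(c("heart_rate", "apoe", "stiffness.fold_change",
                  "stiffness.compliance_law") %in% keys) ||
    length(overrides) > 0
  if (inline) {
    base <- if (scen_name %in% names(builtin_scenarios())) {
      builtin_scenarios()[[scen_name]]
    } else {
      scenario(scen_name)
    }
    stiff <- base$stiffness
    if ("stiffness.fold_change" %in% keys) {
      stiff <- stiffness_profile(
        fold_change = raw[["stiffness.fold_change"]],
        duration = get_or("stiffness.duration_days", 18250),
        law = get_or("stiffness.compliance_law", "inverse"))
    } else if ("stiffness.compliance_law" %in% keys) {
      if (is.null(stiff)) {
        rlang::abort("stiffness.compliance_law given without stiffness.fold_change",
                     class = "glymphsim_config_error")
      }
      stiff <- stiffness_profile(stiff$fold_change, stiff$duration,
                                 raw[["stiffness.compliance_law"]])
    }
    scen <- scenario(
      name = scen_name,
      heart_rate = get_or("heart_rate", base$heart_rate),
      stiffness = stiff,
      apoe = get_or("apoe", base$apoe),
      k4_override = base$k4_override,
      param_overrides = utils::modifyList(base$param_overrides, overrides),
      notes = base$notes)
  } else {
    if (!scen_name %in% names(builtin_scenarios())) {
      rlang::abort(paste0("unknown scenario \"", scen_name, "\"; valid: ",
                          paste(names(builtin_scenarios()), collapse = ", ")),
                   class = "glymphsim_config_error")
    }
    scen <- builtin_scenarios()[[scen_name]]
  }

  cfg <- list(
    scenario = scen,
    years = get_or("years", 50),
    dt = get_or("dt", 1),
    record_stride = get_or("record_stride", 1),
    output_dir = get_or("output_dir", "."),
    formats = get_or("formats", c("csv", "json"))
  )
  if (cfg$years <= 0 || cfg$dt <= 0 || cfg$record_stride < cfg$dt) {
    rlang::abort("config must satisfy years > 0, dt > 0, record_stride >= dt",
                 class = "glymphsim_config_error")
  }
  if (!all(cfg$formats %in% c("csv", "json"))) {
    rlang::abort("formats must be a subset of [\"csv\", \"json\"]",
                 class = "glymphsim_config_error")
  }
  structure(cfg, class = "ab_run_config")
}

#' Read a model parameter preset file
#'
#' Parameter presets are serialized as a flat `key = value` file whose keys
#' are exactly the model parameter field names (see [default_params()] for
#' units). Missing keys keep the values from `base`; unknown keys are
#' rejected.
#'
#' @param path Path to the preset file.
#' @param base Base parameter set to fill unspecified fields.
#' @return A validated `ab_params` parameter set.
#' @export
#' @examples
#' f <- system.file("extdata", "params_apoe3.toml", package = "glymphsim")
#' read_params_config(f)$k6
read_params_config <- function(path, base = default_params()) {
  raw <- read_flat_config(path)
  unknown <- setdiff(names(raw), PARAM_FIELDS)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown parameter key(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "glymphsim_config_error")
  }
  do.call(update_params, c(list(base), raw))
}

#' Write a model parameter preset file
#'
#' @param params An `ab_params` parameter set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path) {
  validate_params(params)
  lines <- c("# glymphsim model parameter preset (flat key = value)",
             "# units: see ?default_params",
             sprintf("%s = %.17g", PARAM_FIELDS,
                     unlist(params[PARAM_FIELDS], use.names = FALSE)))
  writeLines(lines, path)
  invisible(path)
}
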