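#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

pool_metadata <- function() {
  tibble::tibble(
    pool = c("N", "M", "EC", "LRP", "C1", "C4", "C2", "C5",
             "C3", "C6", "C9", "C10"),
    kind = c(rep("cells", 3), "receptors", rep("soluble", 4), rep("deposit", 4)),
    compartment = c(rep("parenchyma", 2), "vessel", "vessel",
                    "parenchyma", "parenchyma", "pvs", "pvs",
                    "vessel", "vessel", "parenchyma", "parenchyma"),
    species = c(rep(NA_character_, 4),
                "Abeta40", "Abeta42", "Abeta40", "Abeta42",
                "Abeta40", "Abeta42", "Abeta40", "Abeta42")
  )
}

#' Tidy a trajectory into long format
#'
#' One row per recorded day and pool, annotated with pool kind (cells,
#' receptors, soluble amyloid, deposit), compartment and amyloid species.
#'
#' @param x An `ab_trajectory` from [run_simulation()].
#' @param ... Unused.
#' @return A long tibble with columns `t_days`, `pool`, `value`, `kind`,
#'   `compartment`, `species`.
#' @method tidy ab_trajectory
#' @export
tidy.ab_trajectory <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), "t_days", dplyr::all_of(pool_metadata()$pool)),
    -"t_days", names_to = "pool", values_to = "value")
  dplyr::left_join(long, pool_metadata(), by = "pool")
}

#' One-row summary of a trajectory
#'
#' @param x An `ab_trajectory`.
#' @param ... Unused.
#' @return A tibble with the scenario name, horizon, final deposit
#'   endpoints, surviving cell-pool fractions and the mass-balance residual.
#' @method glance ab_trajectory
#' @export
glance.ab_trajectory <- function(x, ...) {
  e <- endpoints(x)
  p <- attr(x, "params_used")
  tibble::tibble(
    scenario = attr(x, "scenario_name"),
    years = attr(x, "years"),
    n_recorded = nrow(x),
    parenchyma_Abeta40 = e[["C9"]],
    parenchyma_Abeta42 = e[["C10"]],
    vessel_Abeta40 = e[["C3"]],
    vessel_Abeta42 = e[["C6"]],
    neuron_fraction = e[["N"]] / p$N0,
    microglia_fraction = e[["M"]] / p$M0,
    ec_fraction = e[["EC"]] / p$EC0,
    lrp_fraction = e[["LRP"]] / p$LRP0,
    mass_balance_residual = mass_balance_residual(x)
  )
}

#' Plot a trajectory
#'
#' Faceted line plot of the pools over time on a per-kind free y scale.
#'
#' @param object An `ab_trajectory`.
#' @param kinds Which pool kinds to show (subset of `"cells"`,
#'   `"receptors"`, `"soluble"`, `"deposit"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ab_trajectory
#' @export
autoplot.ab_trajectory <- function(object,
                                   kinds = c("cells", "receptors",
                                             "soluble", "deposit"), ...) {
  long <- dplyr::filter(tidy.ab_trajectory(object), .data$kind %in% kinds)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$t_days / 365, y = .data$value,
                               colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = "count / molecules",
                  title = attr(object, "scenario_name")) +
    ggplot2::theme_minimal()
}

#' Plot a normalized endpoint report
#'
#' Bar chart of log10 ratio-to-baseline per scenario, faceted by compartment
#' and species.
#'
#' @param report A [normalized_report()] tibble.
#' @return A ggplot object.
#' @export
plot_report <- function(report) {
  ggplot2::ggplot(dplyr::filter(report, .data$ratio_defined),
                  ggplot2::aes(x = .data$scenario,
                               y = log10(.data$ratio_to_baseline))) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(compartment ~ species) +
    ggplot2::labs(y = "log10 ratio to normal aging", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the cell and receptor pools of a trajectory
#'
#' @param traj An `ab_trajectory`.
#' @return A ggplot object showing N, M, EC and LRP as fractions of their
#'   initial values.
#' @export
plot_cell_pools <- function(traj) {
  p <- attr(traj, "params_used")
  d <- tibble::tibble(
    t_years = rep(traj$t_days / 365, 4),
    pool = rep(c("neurons", "microglia", "endothelial", "LRP-1"),
               each = nrow(traj)),
    fraction = c(traj$N / p$N0, traj$M / p$M0, traj$EC / p$EC0,
                 traj$LRP / p$LRP0)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_years, y = .data$fraction,
                                  colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (years)", y = "fraction of initial") +
    ggplot2::theme_minimal()
}
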