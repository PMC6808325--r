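#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Markov cohort result into its per-cycle trace
#'
#' @param x a `markov_result`.
#' @param ... unused.
#' @return tibble: `cycle`, state occupancy columns (`HD`, `CAPD`,
#'   `Death`), per-cycle `cycle_ly`/`cycle_qaly`/`cycle_cost` and their
#'   discounted twins.
#' @export
tidy.markov_result <- function(x, ...) {
  dplyr::mutate(x$trace, scenario = x$scenario, .before = 1)
}

#' One-row summary of a Markov cohort result
#'
#' @param x a `markov_result`.
#' @param ... unused.
#' @return one-row tibble: scenario label, undiscounted and discounted
#'   totals, horizon settings.
#' @export
glance.markov_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario, !!!x$totals,
    n_cycles = x$settings$n_cycles,
    discount_rate = x$settings$discount_rate
  )
}

#' Per-scenario Monte Carlo means of a PSA run
#'
#' @param x a `psa_result`.
#' @param ... unused.
#' @return tibble, one row per scenario: mean and standard error of the
#'   sampled (discounted) cost and QALYs, and the iteration count.
#' @export
glance.psa_result <- function(x, ...) {
  x |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cost = mean(.data$cost), se_cost = stats::sd(.data$cost) / sqrt(dplyr::n()),
      mean_qaly = mean(.data$qaly), se_qaly = stats::sd(.data$qaly) / sqrt(dplyr::n()),
      mean_disc_cost = mean(.data$disc_cost),
      mean_disc_qaly = mean(.data$disc_qaly),
      .groups = "drop"
    )
}

#' Summary of an incremental cost-effectiveness ladder
#'
#' @param x a `cea_result` from [icer_ladder()].
#' @param ... unused.
#' @return one-row tibble: scenario counts by dominance status and the
#'   range of frontier ICERs.
#' @export
glance.cea_result <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(x),
    n_nondominated = sum(x$dominance == "nondominated"),
    n_strictly_dominated = sum(x$dominance == "strictly_dominated"),
    n_extendedly_dominated = sum(x$dominance == "extendedly_dominated"),
    min_frontier_icer = suppressWarnings(min(x$icer, na.rm = TRUE)),
    max_frontier_icer = suppressWarnings(max(x$icer, na.rm = TRUE))
  )
}
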