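#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier survivor curve
#'
#' Step plot of the product-limit estimate with a pointwise 95%
#' Greenwood band.
#'
#' @param object a `km_curve` from [km_estimate()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    lower = pmax(0, .data$survival - 1.96 * .data$std_err),
    upper = pmin(1, .data$survival + 1.96 * .data$std_err)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         stat = "identity", alpha = 0.2) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Follow-up (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot cohort state occupancy over the model horizon
#'
#' @param object a `markov_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.markov_result <- function(object, ...) {
  df <- object$trace |>
    dplyr::select("cycle", dplyr::all_of(health_states)) |>
    tidyr::pivot_longer(-"cycle", names_to = "state",
                        values_to = "occupancy") |>
    dplyr::mutate(state = factor(.data$state, levels = health_states))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (years)", y = "State occupancy",
                  fill = NULL, title = object$scenario) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of one-way sensitivity results
#'
#' Horizontal bars spanning the incremental net monetary benefit at each
#' parameter's low and high range bound, around the baseline NMB,
#' widest (most influential) parameters on top.
#'
#' @param tornado a `tornado_result` from [one_way_tornado()].
#' @param top_n show only the `top_n` widest bars (default all).
#' @return a ggplot object.
#' @export
plot_tornado <- function(tornado, top_n = nrow(tornado)) {
  df <- tornado |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(
      parameter = factor(.data$parameter, levels = rev(.data$parameter)),
      lo = pmin(.data$nmb_at_low, .data$nmb_at_high),
      hi = pmax(.data$nmb_at_low, .data$nmb_at_high)
    )
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(tornado, "baseline_nmb"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Incremental net monetary benefit (RM)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_tornado
#' @param object,... autoplot method arguments.
#' @export
autoplot.tornado_result <- function(object, ...) plot_tornado(object, ...)

#' Cost-effectiveness acceptability curves
#'
#' One line per scenario: the probability of attaining the maximum net
#' monetary benefit, across the willingness-to-pay grid.
#'
#' @param curve a `ceac_curve` from [ceac()].
#' @return a ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$threshold,
                                      y = .data$probability,
                                      colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay threshold (RM per QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_ceac
#' @param object,... autoplot method arguments.
#' @export
autoplot.ceac_curve <- function(object, ...) plot_ceac(object)
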