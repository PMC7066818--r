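#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort trace
#'
#' State occupancy over the 70 one-year cycles.
#'
#' @param object A `cohort_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                               colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "cycle (years since entry at age 30)", y = "occupancy",
      title = paste("Cohort trace -", object$country, object$sex)
    ) +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Horizontal bars spanning the low/high output values of each perturbed
#' parameter, widest at the top.
#'
#' @param object A `tornado_result` from [tornado()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tornado_result <- function(object, ...) {
  df <- dplyr::filter(object, !.data$failed) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = rev(.data$parameter)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$low, xend = .data$high,
                                       yend = .data$parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$base), linetype = 2) +
    ggplot2::labs(x = "output at +/-30% perturbation", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane and acceptability curve
#'
#' Plots the PSA draws on the incremental cost-effectiveness plane
#' (`type = "plane"`) or the cost-effectiveness acceptability curve
#' (`type = "ceac"`).
#'
#' @param object A `psa_result` from [run_psa()].
#' @param type `"plane"` or `"ceac"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psa_result <- function(object, type = c("plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    ggplot2::ggplot(object$draws,
                    ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::labs(x = "incremental QALYs per 1000 children",
                    y = "incremental cost (EUR 2016)",
                    title = "Cost-effectiveness plane") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$ceac,
                    ggplot2::aes(x = .data$threshold, y = .data$probability)) +
      ggplot2::geom_line() +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "willingness to pay (EUR/QALY)",
                    y = "P(cost-effective)",
                    title = "Cost-effectiveness acceptability curve") +
      ggplot2::theme_minimal()
  }
}

#' Budget impact over the horizon
#'
#' Annual net payer cost and its cumulative total.
#'
#' @param object A `bia_result` from [run_bia()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bia_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$net), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "firebrick") +
    ggplot2::labs(x = "year", y = "net payer cost (EUR 2016)",
                  title = "Budget impact (bars: annual net, line: cumulative)") +
    ggplot2::theme_minimal()
}
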