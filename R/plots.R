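#' Plot a cost-effectiveness acceptability curve
#'
#' Probability that each strategy has the highest net monetary benefit as
#' a function of the monetary value of a QALY.
#'
#' @param ceac a [build_ceac()] tibble.
#' @return a ggplot.
#' @export
plot_ceac <- function(ceac) {
  ggplot2::ggplot(ceac, ggplot2::aes(x = .data$lambda, y = .data$probability,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Monetary value of a QALY (€)",
                  y = "Probability most cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of the incremental (effect, cost) pairs over the PSA draws,
#' CO-PCI vs. MV-PCI, with the origin marked.
#'
#' @param increments a [psa_increments()] tibble.
#' @param lambda optional willingness-to-pay threshold drawn as a line.
#' @return a ggplot.
#' @export
plot_cep <- function(increments, lambda = NULL) {
  p <- ggplot2::ggplot(increments,
                       ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (€)") +
    ggplot2::theme_minimal()
  if (!is.null(lambda)) {
    p <- p + ggplot2::geom_abline(slope = lambda, intercept = 0,
                                  linetype = "dashed")
  }
  p
}

#' @rdname plot_ceac
#' @param object a `cohort_trace` from [run_markov()].
#' @param ... unused.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  states <- setdiff(names(object),
                    c("cycle", "cost", "qaly", "cum_cost", "cum_qaly"))
  long <- tidyr::pivot_longer(object[, c("cycle", states)],
                              -"cycle", names_to = "state",
                              values_to = "occupancy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cycle (months)", y = "State occupancy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
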