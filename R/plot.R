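#' Plot methods
#'
#' `autoplot()` methods for traces and rate curves, plus a histogram/KDE plot
#' of an unbinding-force sample, all returning ggplot objects.
#'
#' @param object a `dyn_trace` or `dyn_rate_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @name dynforce-plots
NULL

#' @rdname dynforce-plots
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_col labs
#'   scale_y_log10
#' @method autoplot dyn_trace
#' @export
autoplot.dyn_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$force_pN)) +
    geom_line(linewidth = 0.2) +
    labs(x = "Time (s)", y = "Force (pN)",
         title = attr(object, "condition") %||% NULL)
}

#' @rdname dynforce-plots
#' @method autoplot dyn_rate_curve
#' @export
autoplot.dyn_rate_curve <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$force_pN, y = .data$rate_per_s))
  if (any(is.finite(object$ci_lo))) {
    p <- p + geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.3, fill = "steelblue")
  }
  p + geom_line() + scale_y_log10() +
    labs(x = "|Force| (pN)", y = "Unbinding rate (1/s)",
         title = paste(attr(object, "condition"), attr(object, "direction")))
}

#' @rdname dynforce-plots
#' @param data force sample (data frame with `force_pN` or numeric vector).
#' @param kde overlay the reflected-kernel density estimate.
#' @export
plot_force_histogram <- function(data, kde = TRUE, ...) {
  hist_tbl <- normalized_histogram(data)
  p <- ggplot(hist_tbl, aes(x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$prob)) +
    geom_col(width = 1, fill = "grey70", colour = "grey30") +
    labs(x = "|Unbinding force| (pN)", y = "Probability per 1-pN bin")
  n <- attr(hist_tbl, "n")
  if (kde && n >= 10) {
    dens <- kde_pdf(data)
    p <- p + geom_line(data = dens, aes(x = .data$force_pN, y = .data$density),
                       colour = "firebrick")
  }
  p
}
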