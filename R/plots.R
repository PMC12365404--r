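#' Plot a posterior-predictive effect curve
#'
#' Renders the output of [posterior_predict()] as a median line with its
#' credible band, against the (single) covariate in the grid. Requires
#' ggplot2.
#'
#' @param pp data.frame from [posterior_predict()].
#' @param xlab,ylab axis labels; `xlab` defaults to the grid covariate.
#' @return a ggplot object.
#' @export
plot_effect_curve <- function(pp, xlab = NULL, ylab = "predicted rate") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_effect_curve requires the ggplot2 package", call. = FALSE)
  xvar <- setdiff(names(pp), c("median", "lower", "upper"))
  if (length(xvar) != 1)
    stop("the prediction grid must have exactly one covariate column", call. = FALSE)
  ggplot2::ggplot(pp, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.8) +
    ggplot2::labs(x = xlab %||% xvar, y = ylab) +
    ggplot2::theme_minimal()
}
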