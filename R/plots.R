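# ggplot2 displays for report objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_smooth geom_col
#'   labs facet_wrap theme_minimal position_identity
NULL

#' Scatterplot of COBRA scores against the clinical assessment
#'
#' @param object A `cobra_correlation` from [correlation_report()] or
#'   [stratified_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cobra_correlation <- function(object, ...) {
  dat <- object$data
  if (is.null(dat)) abort("This report carries no joined data to plot.")
  p <- ggplot(dat, aes(x = clinical_score, y = cobra_score)) +
    geom_point(alpha = 0.7) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linewidth = 0.4, colour = "grey40") +
    labs(
      x = "clinical score", y = "COBRA score",
      title = sprintf("r = %.3f, %d%% CI [%.3f, %.3f], n = %d",
                      object$r, round(100 * object$level),
                      object$ci_low, object$ci_high, object$n)
    ) +
    theme_minimal()
  p
}

#' Confidence histograms for a pair of subjects
#'
#' @param object A `cobra_confidence_summary` from
#'   [confidence_distribution_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cobra_confidence_summary <- function(object, ...) {
  h <- object$histograms
  ggplot(h, aes(x = (lower + upper) / 2, y = proportion,
                fill = subject_id)) +
    geom_col(position = position_identity(), alpha = 0.5,
             width = h$upper[1] - h$lower[1]) +
    labs(x = "confidence", y = "proportion",
         title = sprintf("overlap coefficient = %.3f", object$overlap)) +
    theme_minimal()
}
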