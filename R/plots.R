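#' Score-versus-age cohort plot
#'
#' Combined (or sub-) myelination score against age on a logarithmic age
#' axis, coloured by subtype, with lines connecting scans of the same
#' patient when follow-ups are present -- the standard way to visualise
#' diverging subtype trajectories against the control maturation curve.
#'
#' @param scores per-scan score table from [score_scans()] (a `subtype`
#'   column is used for colour when present).
#' @param which which score column to plot: `"combined"`, `"t2_sum"` or
#'   `"t1_sum"`.
#' @return a ggplot object.
#' @export
plot_score_age <- function(scores, which = c("combined", "t2_sum", "t1_sum")) {
  which <- match.arg(which)
  stopifnot(is.data.frame(scores), which %in% names(scores))
  has_subtype <- "subtype" %in% names(scores)
  p <- ggplot2::ggplot(
    scores,
    ggplot2::aes(x = .data$age_years, y = .data[[which]],
                 colour = if (has_subtype) .data$subtype else NULL,
                 group = .data$patient_id)
  ) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "age (years, log scale)", y = which,
                  colour = "subtype") +
    ggplot2::theme_minimal()
  p
}

#' Plot a ROC curve
#'
#' @param object a `pmd_roc` object from [roc_analysis()].
#' @param ... unused.
#' @return a ggplot object showing the ROC curve with the Youden-optimal
#'   cut-off marked.
#' @method autoplot pmd_roc
#' @export
autoplot.pmd_roc <- function(object, ...) {
  curve <- attr(object, "curve")
  curve <- curve[order(1 - curve$specificity, curve$sensitivity), ]
  best <- curve[which.max(curve$youden_j), ]
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::annotate("text", x = 1 - best$specificity, y = best$sensitivity,
                      label = sprintf(" cut-off %.1f", best$threshold),
                      hjust = 0, vjust = 1.2, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}
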