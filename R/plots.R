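#' ROC curve of a cross-validation result
#'
#' @param object an `lmpair_cv`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lmpair_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s ROC", object$scheme),
      subtitle = sprintf("mean AUC = %.4f%s", object$mean_auc,
                         if (is.na(object$std_auc)) ""
                         else sprintf(" (sd %.4f)", object$std_auc))
    ) +
    ggplot2::theme_minimal()
}

#' Score-vs-rank plot of ranked predictions
#'
#' Known training associations are highlighted, which makes it easy to
#' see how far they rise above the candidate background.
#'
#' @param object an `lmpair_predictions` tibble.
#' @param max_rank truncate the x axis at this rank (default 2000).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lmpair_predictions <- function(object, max_rank = 2000, ...) {
  df <- object[object$rank <= max_rank, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
                                   colour = .data$known)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "#c0392b"),
                                 name = "known") +
    ggplot2::labs(x = "Rank", y = "KATZ score",
                  title = "Ranked disease / lncRNA-miRNA pair predictions") +
    ggplot2::theme_minimal()
}
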