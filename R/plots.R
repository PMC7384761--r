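# ggplot2 displays for the result objects.

#' Plot a ROC curve
#'
#' @param object A `ta_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ta_roc <- function(object, ...) {
  df <- tibble(
    fpr = c(0, 1 - object$curve$specificity, 1),
    sensitivity = c(0, object$curve$sensitivity, 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::coord_equal()
}

#' Plot observed/expected cross-tissue overlap ratios
#'
#' @param overlap Output of [overlap_analysis()].
#' @return A ggplot object: overlap ratio against -log10 threshold, with the
#'   independence line at ratio 1.
#' @export
plot_overlap_ratio <- function(overlap) {
  ggplot2::ggplot(overlap,
                  ggplot2::aes(x = -log10(.data$threshold), y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(-log[10] ~ "significance threshold"),
                  y = "Observed / expected shared local-eQTL")
}

#' Plot AUC by method and subsample size
#'
#' @param auc_summary Tibble with columns `method`, `size`, `auc` (and
#'   optionally `auc_min`, `auc_max` for error bars).
#' @return A ggplot object.
#' @export
plot_auc_by_size <- function(auc_summary) {
  p <- ggplot2::ggplot(auc_summary,
                       ggplot2::aes(x = factor(.data$size), y = .data$auc,
                                    fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = "Strains in subsample", y = "AUC", fill = "Method")
  if (all(c("auc_min", "auc_max") %in% names(auc_summary))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$auc_min, ymax = .data$auc_max),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    )
  }
  p
}
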