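#' Plot the biopsy-sampling convergence curve
#'
#' Mean macro-AUROC (+/- SD over ensemble members) as a function of the
#' number of sampled fragments, with the full-resection reference level
#' and the 3% relative-gap band that defines practical convergence.
#'
#' @param object A `cms_sim_curve` from [convergence_curve()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cms_sim_curve
#' @export
autoplot.cms_sim_curve <- function(object, ...) {
  ref <- object$reference_auroc[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$m, y = .data$mean_auroc)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
      ymin = ref * 0.97, ymax = ref, alpha = 0.15, fill = "red") +
    ggplot2::geom_hline(yintercept = ref, linetype = "dashed", colour = "red") +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_auroc - .data$sd_auroc,
      ymax = .data$mean_auroc + .data$sd_auroc), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$m) +
    ggplot2::labs(x = "fragments per biopsy sample (m)",
      y = "macro one-vs-rest AUROC",
      title = "Virtual-biopsy performance vs fragment count",
      subtitle = "dashed: full-resection reference; band: within 3% of reference") +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param labels True class labels.
#' @param scores Probability matrix/tibble (`p_CMS1`..`p_CMS4`).
#' @return A ggplot object with one panel-free curve per class.
#' @export
plot_roc_curves <- function(labels, scores) {
  pts <- dplyr::bind_rows(lapply(CMS_CLASSES, function(k) {
    p <- roc_points(labels, scores, k)
    p$class <- k
    p
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
    colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
      colour = NULL, title = "One-vs-rest ROC curves") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param conf Matrix from [confusion_counts()].
#' @return A ggplot tile heatmap with counts.
#' @export
plot_confusion <- function(conf) {
  df <- as.data.frame(as.table(conf))
  names(df) <- c("true", "called", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$called, y = .data$true,
    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(CMS_CLASSES)) +
    ggplot2::labs(x = "called", y = "true class", fill = "cases") +
    ggplot2::theme_minimal()
}

#' Plot per-subtype odds ratios
#'
#' Forest-style plot of the one-vs-rest pCR odds ratios with their 95%
#' confidence intervals on a log scale.
#'
#' @param or_table Tibble from [subtype_pcr_analysis()].
#' @return A ggplot object.
#' @export
plot_odds_ratios <- function(or_table) {
  ggplot2::ggplot(or_table, ggplot2::aes(x = .data$odds_ratio, y = .data$group)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
      xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio for pCR (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
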