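#' Plot per-residue early-folding probability profiles
#'
#' One line panel per protein, with the decision threshold drawn as a dashed
#' horizontal rule.
#'
#' @param scores A score tibble (see [read_scores()] / [write_scores()]),
#'   with columns `protein_id`, `residue_number`, `probability`.
#' @param tau Threshold to draw (default 0.163).
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, tau = 0.163) {
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$residue_number, y = .data$probability)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = tau, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~protein_id, scales = "free_x") +
    ggplot2::labs(x = "residue", y = "early-folding probability") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `efold_cv` object.
#' @param ... Unused.
#' @return A ggplot object: one point per fold and metric, with the fold
#'   average marked.
#' @method autoplot efold_cv
#' @export
autoplot.efold_cv <- function(object, ...) {
  metric_cols <- c("sen", "spe", "acc", "bac", "pre", "mcc", "auc",
                   "ppv_top10", "ppv_top5")
  long <- tidyr::pivot_longer(object$folds[, c("fold", metric_cols)],
                              all_of(metric_cols),
                              names_to = "metric", values_to = "value")
  avg <- tidyr::pivot_longer(object$average[, metric_cols], all_of(metric_cols),
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5, colour = "#2c7fb8") +
    ggplot2::geom_point(data = avg, colour = "firebrick", size = 3, shape = 18) +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Cross-validation metrics (red diamond: fold average)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
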