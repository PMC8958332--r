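#' @describeIn threshold_roc ROC and precision-recall curves.
#' @method autoplot pcu_roc
#' @export
autoplot.pcu_roc <- function(object, ...) {
  curve <- object$curve |>
    tidyr::pivot_longer(cols = c("fpr", "recall"), names_to = "panel",
                        values_to = "x") |>
    mutate(y = ifelse(.data$panel == "fpr", .data$tpr, .data$precision),
           panel = ifelse(.data$panel == "fpr", "ROC",
                          "Precision-recall"))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(
      x = "FPR / recall", y = "TPR / precision",
      title = sprintf("Threshold sweep (truth: %s)", object$truth_label),
      subtitle = sprintf("ROC AUC %.3f, PR AUC %.3f",
                         object$auc_roc, object$auc_pr)) +
    ggplot2::theme_minimal()
}

#' @describeIn dynamical_correlation correlation heatmap.
#' @param object a `pcu_dyncorr`.
#' @method autoplot pcu_dyncorr
#' @export
autoplot.pcu_dyncorr <- function(object, ...) {
  df <- as_tibble(object$R, rownames = "var1") |>
    tidyr::pivot_longer(-"var1", names_to = "var2",
                        values_to = "correlation")
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Sample dynamical correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

#' Histogram of per-node verification ratios
#'
#' The fraction of verified over predicted conditions for each DAG node,
#' optionally restricted to the between-layer classes (`a->s`, `a->p`)
#' which carry the causal content of the units.
#'
#' @param records verification records.
#' @param between_layer_only restrict to `a->s` and `a->p` conditions.
#' @return A ggplot object.
#' @export
plot_verification_ratio <- function(records, between_layer_only = FALSE) {
  if (between_layer_only)
    records <- filter(records, .data$klass %in% c("a->s", "a->p"))
  df <- records_by_node(records)
  ggplot2::ggplot(df, ggplot2::aes(.data$ratio)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.1),
                            closed = "right", fill = "grey35") +
    ggplot2::labs(x = "verified / predicted conditions per node",
                  y = "nodes") +
    ggplot2::theme_minimal()
}
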