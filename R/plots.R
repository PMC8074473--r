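#' Heatmap of posterior edge scores
#'
#' @param object An [infer_network()] fit.
#' @param ... Unused.
#' @return A ggplot object: parents on the vertical axis, children on
#'   the horizontal, tile fill = posterior edge probability.
#' @export
autoplot.nhdbn_fit <- function(object, ...) {
  sc <- object$scores
  sc$parent <- factor(sc$parent, levels = rev(sort(unique(sc$parent))))
  sc$child <- factor(sc$child, levels = sort(unique(sc$child)))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$child, y = .data$parent,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "child (target)", y = "parent (regulator)",
                  fill = "edge score",
                  title = paste("Posterior edge scores,", object$model)) +
    ggplot2::theme_minimal()
}

#' Trace plots for one chain
#'
#' @param object A [run_chain()] result.
#' @param ... Unused.
#' @return A ggplot object with traces of the log marginal likelihood,
#'   the parent-set size and the number of segments over retained draws.
#' @export
autoplot.nhdbn_chain <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$samples[, c("draw", "log_marginal", "n_parents", "n_segments")],
    -"draw", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$draw, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "retained draw",
                  title = paste0(object$model, " chain, target ",
                                 object$target)) +
    ggplot2::theme_minimal()
}

#' Precision-recall curve plot
#'
#' @inheritParams pr_curve
#' @return A ggplot object of the precision-recall curve, annotated with
#'   the area under it.
#' @export
plot_pr_curve <- function(scores, truth) {
  curve <- pr_curve(scores, truth)
  auc <- precision_recall_auc(scores, truth)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$recall,
                                      y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("Precision-recall curve (AUC = %.3f)",
                                  auc),
                  x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}
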