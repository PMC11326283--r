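#' Plot the pretraining trajectory
#'
#' Validation cross-entropy (per masked position) and macro-averaged
#' accuracy against optimizer steps.
#'
#' @param object an `mlm_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mlm_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$report,
                            c("loss_mean", "macro_accuracy"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(loss_mean = "validation cross-entropy / position",
                            macro_accuracy = "macro-averaged accuracy"))) +
    ggplot2::labs(x = "optimizer step", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an embedding cluster plan
#'
#' First two principal components of the embedding space, colored by
#' cluster assignment.
#'
#' @param object a `cluster_plan`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cluster_plan <- function(object, ...) {
  if (is.null(object$scores)) stop("cluster plan carries no projected coordinates")
  df <- tibble::tibble(PC1 = object$scores[, 1],
                       PC2 = if (ncol(object$scores) > 1) object$scores[, 2] else 0,
                       cluster = factor(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   color = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::labs(title = sprintf("k = %d on %d principal components",
                                  object$k, object$pca_components)) +
    ggplot2::theme_minimal()
}

#' Plot held-out predictions of a leave-one-cluster-out evaluation
#'
#' Predicted against experimental log permeability, one panel per
#' held-out cluster, with the classification cutoff marked.
#'
#' @param object a `locv_eval_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.locv_eval_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$truth, y = .data$prediction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 3, color = "red3") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "experimental logP", y = "ensemble prediction") +
    ggplot2::theme_minimal()
}
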