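#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pretraining trajectory
#'
#' @param x an `mlm_fit` from [train_mlm()].
#' @param ... unused.
#' @return tibble with one row per evaluation: step, split, loss_mean,
#'   loss_sum, macro_accuracy.
#' @export
tidy.mlm_fit <- function(x, ...) x$report

#' @rdname tidy.mlm_fit
#' @export
glance.mlm_fit <- function(x, ...) {
  last <- x$report[nrow(x$report), ]
  tibble::tibble(
    n_parameters = n_parameters(x$model$config),
    steps = max(x$report$step),
    final_loss = last$loss_mean,
    final_macro_accuracy = last$macro_accuracy
  )
}

#' Tidy cluster-selection quality indices
#'
#' @param x a `cluster_plan` from [reduce_and_cluster()].
#' @param ... unused.
#' @return the per-candidate quality tibble (silhouette, Davies-Bouldin,
#'   Calinski-Harabasz), with the chosen k flagged.
#' @export
tidy.cluster_plan <- function(x, ...) {
  dplyr::mutate(x$quality, selected = .data$k == x$k)
}

#' @rdname tidy.cluster_plan
#' @export
glance.cluster_plan <- function(x, ...) {
  tibble::tibble(k = x$k, pca_components = x$pca_components,
                 n = length(x$labels),
                 silhouette = x$quality$silhouette[x$quality$k == x$k])
}

#' Tidy a leave-one-cluster-out evaluation
#'
#' @param x a `locv_eval_report` from [evaluate_locv()].
#' @param ... unused.
#' @return per-test-cluster metric tibble.
#' @export
tidy.locv_eval_report <- function(x, ...) x$per_cluster

#' @rdname tidy.locv_eval_report
#' @export
glance.locv_eval_report <- function(x, ...) x$aggregate
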