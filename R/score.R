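#' Classification-style scoring of permeability predictions
#'
#' Binarizes the experimental values at `cutoff` (permeable iff
#' `logP_exp >= cutoff`), scores the continuous predictions as a ranking
#' (ROC-AUC by trapezoidal integration, PR-AUC by step-wise interpolation
#' of the precision-recall points) and reports the regression RMSE. When
#' the test set contains a single class the AUCs are undefined and
#' returned as `NA` with a warning; RMSE is still computed.
#'
#' @param predictions numeric vector of predicted log10 permeability.
#' @param records tibble with a `logP_exp` column, aligned to
#'   `predictions` (or a bare numeric vector of true values).
#' @param cutoff permeability threshold on the log10 cm/s scale.
#' @return one-row tibble: `roc_auc`, `pr_auc`, `rmse`, `n`, `n_permeable`.
#' @export
score_predictions <- function(predictions, records, cutoff = -5.5) {
  truth <- if (is.numeric(records)) records else records$logP_exp
  if (length(predictions) != length(truth)) {
    stop("predictions and records are not aligned")
  }
  labels <- truth >= cutoff
  rmse <- sqrt(mean((predictions - truth)^2))
  if (length(unique(labels)) < 2L) {
    warning("single-class test set: ROC/PR AUC undefined")
    roc <- NA_real_; pr <- NA_real_
  } else {
    roc <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                          predictor = predictions,
                                          levels = c(FALSE, TRUE),
                                          direction = "<", quiet = TRUE)))
    pr <- pr_auc(predictions, labels)
  }
  tibble::tibble(roc_auc = roc, pr_auc = pr, rmse = rmse,
                 n = length(truth), n_permeable = sum(labels))
}

# Area under the precision-recall curve by step-wise interpolation: walking
# the ranking from the highest score, precision at each achieved recall
# level is accumulated over recall increments. Tied scores are processed as
# one group.
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  o <- order(scores, decreasing = TRUE)
  lab <- as.logical(labels)[o]
  sc <- scores[o]
  grp <- cumsum(!duplicated(sc))
  tp_g <- tapply(lab, grp, sum)
  n_g <- tapply(rep(1L, length(lab)), grp, sum)
  tp <- cumsum(tp_g)
  np <- cumsum(n_g)
  P <- sum(lab)
  if (P == 0L) return(NA_real_)
  precision <- tp / np
  recall <- tp / P
  prev_r <- c(0, utils::head(recall, -1))
  sum((recall - prev_r) * precision)
}

#' Aggregate per-cluster scores
#'
#' Mean and standard deviation of each metric over the held-out test
#' clusters. Clusters with undefined AUCs are excluded from the AUC
#' aggregates with a warning.
#'
#' @param per_cluster tibble with one row per test cluster (as produced by
#'   [evaluate_locv()] or repeated [score_predictions()] calls) containing
#'   `roc_auc`, `pr_auc`, `rmse`.
#' @return one-row tibble of means and standard deviations.
#' @export
aggregate_scores <- function(per_cluster) {
  if (any(is.na(per_cluster$roc_auc))) {
    warning(sum(is.na(per_cluster$roc_auc)),
            " cluster(s) with undefined AUC excluded from the AUC aggregate")
  }
  tibble::tibble(
    n_clusters = nrow(per_cluster),
    roc_auc_mean = mean(per_cluster$roc_auc, na.rm = TRUE),
    roc_auc_sd = stats::sd(per_cluster$roc_auc, na.rm = TRUE),
    pr_auc_mean = mean(per_cluster$pr_auc, na.rm = TRUE),
    pr_auc_sd = stats::sd(per_cluster$pr_auc, na.rm = TRUE),
    rmse_mean = mean(per_cluster$rmse),
    rmse_sd = stats::sd(per_cluster$rmse)
  )
}
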