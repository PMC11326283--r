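#' PCA reduction and k-means cluster selection
#'
#' Centers the embedding matrix, projects it onto the smallest principal
#' subspace retaining at least `variance_target` of the variance, and runs
#' k-means (multiple restarts, fixed seed) for every candidate k. The
#' selected k maximizes the mean silhouette width; the Davies-Bouldin
#' (lower is better) and Calinski-Harabasz (higher is better) indices are
#' reported alongside for confirmation.
#'
#' @param X numeric matrix, rows = molecules.
#' @param variance_target fraction of variance the retained components must
#'   explain.
#' @param k_candidates integer vector of candidate cluster counts.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts per candidate.
#' @return list of class `cluster_plan`: `labels`, `k`, `pca_components`,
#'   `quality` (tibble over candidates), `scores` (projected coordinates).
#' @export
reduce_and_cluster <- function(X, variance_target = 0.99,
                               k_candidates = 2:6, seed = 1L, nstart = 10L) {
  stopifnot(is.matrix(X), nrow(X) >= max(k_candidates))
  if (all(apply(X, 2, stats::var) < 1e-12)) {
    stop("embedding matrix is degenerate (zero variance in every column)")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- which(cumvar >= variance_target - 1e-12)[1]
  if (is.na(ncomp)) ncomp <- length(cumvar)
  Z <- pc$x[, seq_len(ncomp), drop = FALSE]
  D <- stats::dist(Z)
  rows <- list()
  fits <- list()
  for (k in sort(unique(as.integer(k_candidates)))) {
    set.seed(seed)
    km <- stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 50L)
    sil <- mean(cluster::silhouette(km$cluster, D)[, "sil_width"])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      k = k,
      silhouette = sil,
      davies_bouldin = davies_bouldin_index(Z, km$cluster),
      calinski_harabasz = calinski_harabasz_index(Z, km$cluster)
    )
    fits[[as.character(k)]] <- km
  }
  quality <- dplyr::bind_rows(rows)
  best <- quality$k[which.max(quality$silhouette)]
  structure(list(labels = fits[[as.character(best)]]$cluster,
                 k = best,
                 pca_components = ncomp,
                 quality = quality,
                 scores = Z),
            class = "cluster_plan")
}

#' @export
print.cluster_plan <- function(x, ...) {
  cat("<cluster_plan> k = ", x$k, " over ", length(x$labels), " records (",
      x$pca_components, " principal components)\n", sep = "")
  print(x$quality)
  invisible(x)
}

# Mean over clusters of the worst ratio of within-cluster scatter sums to
# centroid separation.
davies_bouldin_index <- function(Z, labels) {
  ks <- sort(unique(labels))
  cen <- do.call(rbind, lapply(ks, function(k) colMeans(Z[labels == k, , drop = FALSE])))
  s <- vapply(seq_along(ks), function(i) {
    pts <- Z[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums((pts - rep(cen[i, ], each = nrow(pts)))^2)))
  }, numeric(1))
  m <- length(ks)
  if (m < 2L) return(NA_real_)
  mean(vapply(seq_len(m), function(i) {
    max(vapply(setdiff(seq_len(m), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cen[i, ] - cen[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

# Between-cluster over within-cluster dispersion, scaled by degrees of
# freedom.
calinski_harabasz_index <- function(Z, labels) {
  n <- nrow(Z)
  ks <- sort(unique(labels))
  m <- length(ks)
  if (m < 2L || n <= m) return(NA_real_)
  grand <- colMeans(Z)
  ssb <- 0; ssw <- 0
  for (k in ks) {
    pts <- Z[labels == k, , drop = FALSE]
    cen <- colMeans(pts)
    ssb <- ssb + nrow(pts) * sum((cen - grand)^2)
    ssw <- ssw + sum((pts - rep(cen, each = nrow(pts)))^2)
  }
  (ssb / (m - 1)) / (ssw / (n - m))
}

#' Leave-one-cluster-out schedule with k-fold validation splits
#'
#' Each cluster serves exactly once as the held-out test set. The remaining
#' records form `folds` train/validation folds: at cluster granularity when
#' the number of remaining clusters equals `folds` (each remaining cluster
#' is one validation fold), at record granularity otherwise (seeded random
#' assignment balanced across folds). Test records never appear in any
#' train or validation fold of their iteration.
#'
#' @param plan a `cluster_plan` (or bare integer label vector).
#' @param folds number of cross-validation folds per iteration.
#' @param seed seed for record-granular fold assignment.
#' @return a tibble of class `locv_schedule`: one row per (iteration,
#'   record) with columns `iteration`, `test_cluster`, `record`, `role`
#'   (`"test"` or `"fold<j>"`).
#' @export
make_locv_schedule <- function(plan, folds = 5L, seed = 1L) {
  labels <- if (inherits(plan, "cluster_plan")) plan$labels else as.integer(plan)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("need at least 2 clusters for leave-one-cluster-out")
  set.seed(seed)
  rows <- list()
  for (it in seq_along(ks)) {
    test_k <- ks[it]
    test_idx <- which(labels == test_k)
    rest_idx <- which(labels != test_k)
    if (folds > length(rest_idx)) {
      stop("fold count (", folds, ") exceeds the ", length(rest_idx),
           " non-test records of cluster ", test_k)
    }
    rest_ks <- setdiff(ks, test_k)
    if (length(rest_ks) == folds) {
      fold_of <- match(labels[rest_idx], rest_ks)
    } else {
      fold_of <- sample(rep_len(seq_len(folds), length(rest_idx)))
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      iteration = it,
      test_cluster = test_k,
      record = c(test_idx, rest_idx),
      role = c(rep("test", length(test_idx)), paste0("fold", fold_of))
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("locv_schedule", class(out))
  attr(out, "folds") <- as.integer(folds)
  out
}
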