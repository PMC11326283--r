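test_that("planted blobs are recovered with the right k and high silhouette", {
  bl <- blob_matrix()
  plan <- reduce_and_cluster(bl$X, k_candidates = 2:6, seed = 4L)
  expect_equal(plan$k, 3L)
  expect_gt(max(plan$quality$silhouette), 0.5)
  # labels agree with the planted partition up to permutation
  tab <- table(plan$labels, bl$truth)
  expect_equal(sum(apply(tab, 1, max)), length(bl$truth))
  # duplicated rows do not change the partition (up to permutation)
  Xdup <- rbind(bl$X, bl$X[1:10, ])
  plan2 <- reduce_and_cluster(Xdup, k_candidates = 2:6, seed = 4L)
  tab2 <- table(plan2$labels[seq_len(nrow(bl$X))], plan$labels)
  expect_equal(sum(apply(tab2, 1, max)), nrow(bl$X))
})

test_that("variance targets control the retained components", {
  bl <- blob_matrix()
  plan_full <- reduce_and_cluster(bl$X, variance_target = 1.0, k_candidates = 2:3, seed = 1L)
  expect_equal(plan_full$pca_components, min(dim(bl$X)) - 0L)
  plan_small <- reduce_and_cluster(bl$X, variance_target = 0.5, k_candidates = 2:3, seed = 1L)
  expect_lt(plan_small$pca_components, plan_full$pca_components)
  expect_error(reduce_and_cluster(matrix(1, 20, 4), k_candidates = 2:3), "degenerate")
})

test_that("quality indices rank an obvious partition above a shuffled one", {
  bl <- blob_matrix()
  good <- bl$truth
  set.seed(8)
  shuffled <- sample(good)
  db_good <- peplm:::davies_bouldin_index(bl$X, good)
  db_bad <- peplm:::davies_bouldin_index(bl$X, shuffled)
  expect_lt(db_good, db_bad)
  ch_good <- peplm:::calinski_harabasz_index(bl$X, good)
  ch_bad <- peplm:::calinski_harabasz_index(bl$X, shuffled)
  expect_gt(ch_good, ch_bad)
})

test_that("leave-one-cluster-out schedules cover every record exactly once as test", {
  labels <- rep(1:6, times = c(20, 15, 25, 10, 18, 12))
  sch <- make_locv_schedule(labels, folds = 5L, seed = 2L)
  its <- unique(sch$iteration)
  expect_length(its, 6L)
  test_sets <- lapply(its, function(it) sch$record[sch$iteration == it & sch$role == "test"])
  # union of test sets = all records, pairwise disjoint
  expect_setequal(unlist(test_sets), seq_along(labels))
  expect_equal(sum(lengths(test_sets)), length(labels))
  for (it in its) {
    sub <- sch[sch$iteration == it, ]
    test_idx <- sub$record[sub$role == "test"]
    train_idx <- sub$record[sub$role != "test"]
    expect_length(intersect(test_idx, train_idx), 0L)
    # cluster-granular folds: 5 remaining clusters, one per fold
    folds <- unique(sub$role[sub$role != "test"])
    expect_length(folds, 5L)
    for (f in folds) {
      expect_length(unique(labels[sub$record[sub$role == f]]), 1L)
    }
  }
})

test_that("record-granular folds kick in when cluster counts do not match", {
  labels <- rep(1:2, each = 30)
  sch <- make_locv_schedule(labels, folds = 5L, seed = 2L)
  sub <- sch[sch$iteration == 1L & sch$role != "test", ]
  expect_length(unique(sub$role), 5L)
  expect_equal(sort(table(sub$role), decreasing = TRUE)[[1]], 6L)
  expect_error(make_locv_schedule(rep(1:2, each = 3), folds = 5L), "exceeds")
  expect_error(make_locv_schedule(rep(1L, 10), folds = 2L), "at least 2 clusters")
})
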