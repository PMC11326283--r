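test_that("ranking metrics match hand-computed cases", {
  # perfect ordering
  truth <- c(-7, -6.5, -5.2, -4.8)
  pred <- c(-7.1, -6.6, -5.1, -4.9)
  sc <- score_predictions(pred, truth, cutoff = -5.5)
  expect_equal(sc$roc_auc, 1)
  expect_equal(sc$pr_auc, 1)
  # hand arithmetic RMSE
  sc2 <- score_predictions(c(-5.0, -6.0), c(-4.9, -6.1), cutoff = -5.5)
  expect_equal(sc2$rmse, 0.1, tolerance = 1e-12)
  # constant predictor: tie convention gives ROC-AUC 0.5 and RMSE = RMS
  # deviation of the targets around the constant
  truth3 <- c(-7, -6, -5, -4)
  sc3 <- score_predictions(rep(-5.5, 4), truth3, cutoff = -5.5)
  expect_equal(sc3$roc_auc, 0.5)
  expect_equal(sc3$rmse, sqrt(mean((truth3 + 5.5)^2)))
  # single-class set: AUCs undefined, RMSE still reported
  expect_warning(sc4 <- score_predictions(c(-7, -6), c(-7, -6.5), cutoff = -5.5),
                 "single-class")
  expect_true(is.na(sc4$roc_auc))
  expect_equal(sc4$rmse, sqrt(mean(c(0, 0.5)^2)))
})

test_that("ROC-AUC agrees with the rank-statistic closed form on random data", {
  set.seed(31)
  for (r in 1:20) {
    n <- 40L
    truth <- stats::runif(n, -8, -4)
    pred <- truth + stats::rnorm(n, sd = 1)
    labels <- truth >= -5.5
    if (length(unique(labels)) < 2L) next
    sc <- score_predictions(pred, truth, cutoff = -5.5)
    # Mann-Whitney U equivalence
    pos <- pred[labels]; neg <- pred[!labels]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(sc$roc_auc, mean(cmp), tolerance = 1e-10)
  }
})

test_that("PR-AUC equals the brute-force step integral and handles ties", {
  set.seed(8)
  for (r in 1:10) {
    n <- 30L
    labels <- stats::runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    scores <- round(stats::rnorm(n), 1)  # coarse grid forces ties
    got <- peplm:::pr_auc(scores, labels)
    # oracle: walk unique thresholds, accumulate precision over recall steps
    thr <- sort(unique(scores), decreasing = TRUE)
    prev_r <- 0; auc <- 0
    for (t in thr) {
      sel <- scores >= t
      prec <- sum(labels & sel) / sum(sel)
      rec <- sum(labels & sel) / sum(labels)
      auc <- auc + (rec - prev_r) * prec
      prev_r <- rec
    }
    expect_equal(got, auc, tolerance = 1e-12)
  }
})

test_that("cutoff changes relabel records but never move the RMSE", {
  set.seed(2)
  truth <- stats::runif(30, -8, -4)
  pred <- truth + stats::rnorm(30, 0.2)
  a <- score_predictions(pred, truth, cutoff = -5.5)
  b <- score_predictions(pred, truth, cutoff = -6.0)
  expect_equal(a$rmse, b$rmse)
  expect_false(isTRUE(all.equal(a$n_permeable, b$n_permeable)))
})

test_that("aggregation reports mean and SD over clusters and flags undefined AUCs", {
  per <- tibble::tibble(cluster = 1:3,
                        roc_auc = c(0.9, 0.8, NA),
                        pr_auc = c(0.85, 0.75, NA),
                        rmse = c(0.5, 0.7, 0.6))
  expect_warning(ag <- aggregate_scores(per), "undefined AUC")
  expect_equal(ag$roc_auc_mean, 0.85)
  expect_equal(ag$rmse_mean, 0.6)
  expect_equal(ag$n_clusters, 3L)
})

test_that("ensemble prediction is the arithmetic mean of the fold models", {
  v <- test_vocab()
  set.seed(13)
  mk <- function() {
    m <- init_model(model_config(vocab_size = vocab_size(v), layers = 1L,
                                 heads = 2L, hidden = 16L, intermediate = 16L,
                                 context = 96L))
    m$head <- list(w = stats::rnorm(16, sd = 0.1), b = stats::rnorm(1))
    m
  }
  models <- replicate(5, mk(), simplify = FALSE)
  smiles <- test_corpus()[1:6]
  single <- vapply(models, predict_permeability, records = smiles, vocab = v,
                   numeric(length(smiles)))
  ens <- ensemble_predict(models, smiles, v)
  expect_equal(ens, rowMeans(single), tolerance = 1e-12)
  same <- ensemble_predict(models[c(1, 1, 1)], smiles, v)
  expect_equal(same, single[, 1], tolerance = 1e-12)
  expect_error(ensemble_predict(list(), smiles, v), "at least one")
})
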