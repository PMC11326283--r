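test_that("evaluation metrics match closed forms on degenerate predictors", {
  v <- test_vocab()
  V <- vocab_size(v)
  # a model with zeroed head emits the uniform distribution: loss = ln(V)
  m <- tiny_model()
  m$params$lm_W[] <- 0
  m$params$lm_b[] <- 0
  enc <- encode_batch(test_corpus()[1:40], v)
  ev <- evaluate_mlm(m, enc, masking_config(), seed = 5L)
  expect_equal(ev$loss_mean, log(V), tolerance = 1e-8)
})

test_that("macro accuracy averages classes unweighted", {
  v <- test_vocab()
  V <- vocab_size(v)
  enc <- encode_batch(test_corpus()[1:40], v)
  # reproduce the evaluation masking draw to know the label classes
  set.seed(5)
  mb <- apply_masking(enc, masking_config(), V)
  classes <- sort(unique(mb$labels[mb$labels != -1L]))
  target <- as.integer(classes[which.max(tabulate(match(mb$labels[mb$labels != -1L], classes)))])
  # a constant predictor always emitting the most frequent class: macro
  # accuracy is 1 / (number of observed classes), however frequent it is
  m <- tiny_model()
  m$params$lm_W[] <- 0
  m$params$lm_b[] <- 0
  m$params$lm_b[target + 1L] <- 50
  ev <- evaluate_mlm(m, enc, masking_config(), seed = 5L)
  expect_equal(ev$macro_accuracy, 1 / length(classes), tolerance = 1e-12)
})

test_that("training reduces validation loss and is deterministic; lr = 0 is a no-op", {
  corpus <- test_corpus()
  v <- test_vocab()
  cfg <- model_config(vocab_size = vocab_size(v), layers = 2L, heads = 2L,
                      hidden = 32L, intermediate = 64L, context = 96L)
  fit <- train_mlm(corpus, v, cfg, steps = 40L, batch_size = 32L, lr = 1e-3,
                   eval_interval = 20L, seed = 6L)
  rep <- fit$report
  expect_lt(rep$loss_mean[nrow(rep)], rep$loss_mean[1])
  fit2 <- train_mlm(corpus, v, cfg, steps = 40L, batch_size = 32L, lr = 1e-3,
                    eval_interval = 20L, seed = 6L)
  expect_equal(fit$report, fit2$report, tolerance = 1e-12)
  fit0 <- train_mlm(corpus, v, cfg, steps = 10L, batch_size = 32L, lr = 0,
                    eval_interval = 5L, seed = 6L)
  expect_equal(max(abs(fit0$report$loss_mean - fit0$report$loss_mean[1])), 0,
               tolerance = 1e-10)
  expect_error(train_mlm(corpus[1:5], v, cfg, batch_size = 32L), "smaller than one batch")
})

test_that("checkpoints round-trip and refuse a mismatched vocabulary", {
  v <- test_vocab()
  m <- tiny_model()
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, v, f)
  m2 <- load_checkpoint(f, v)
  expect_equal(m$params$tok_emb, m2$params$tok_emb)
  other <- train_vocabulary("CCNCC", tokenizer_config(budget = 10L))
  expect_error(load_checkpoint(f, other), "different vocabulary")
})
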