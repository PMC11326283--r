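test_that("full-size configuration instantiates in the 42-46M parameter range", {
  cfg <- model_config(vocab_size = 586L)
  expect_equal(cfg$layers, 6L)
  expect_equal(cfg$heads, 12L)
  expect_equal(cfg$hidden, 768L)
  n <- n_parameters(cfg)
  expect_gte(n, 42e6)
  expect_lte(n, 46e6)
  # closed form agrees with an actually instantiated (smaller) model
  small <- model_config(vocab_size = 50L, layers = 2L, heads = 2L, hidden = 16L,
                        intermediate = 32L, context = 16L)
  set.seed(1)
  m <- init_model(small)
  expect_equal(n_parameters(m), n_parameters(small))
})

test_that("output distributions normalize per position", {
  v <- test_vocab()
  m <- tiny_model()
  enc <- encode_batch(test_corpus()[1:4], v)
  probs <- mlm_forward(m, enc$ids, enc$attention)
  expect_equal(dim(probs)[3], vocab_size(v))
  sums <- apply(probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  # single-token input
  p1 <- mlm_forward(m, matrix(c(2L, 7L, 3L), 1), matrix(1L, 1, 3))
  expect_equal(dim(p1), c(1, 3, vocab_size(v)))
})

test_that("rotary embeddings make attention depend only on relative offsets", {
  m <- tiny_model()
  ids <- matrix(c(2L, 8L, 9L, 10L, 3L), 1)
  att <- matrix(1L, 1, 5)
  base <- encoder_forward(m, ids, att)$hidden
  shifted <- encoder_forward(m, ids, att, positions = (0:4) + 17)$hidden
  expect_equal(shifted, base, tolerance = 1e-8)
})

test_that("over-length and out-of-vocabulary inputs are rejected", {
  m <- tiny_model()
  big <- matrix(7L, 1, m$config$context + 1L)
  expect_error(encoder_forward(m, big, big * 0L + 1L), "exceeds")
  bad <- matrix(c(2L, 999999L, 3L), 1)
  expect_error(encoder_forward(m, bad, bad * 0L + 1L), "out of range")
})

test_that("analytic gradients match finite differences", {
  set.seed(12)
  cfg <- model_config(vocab_size = 12L, layers = 1L, heads = 2L, hidden = 8L,
                      intermediate = 12L, context = 8L)
  m <- init_model(cfg)
  ids <- matrix(c(2L, 6L, 7L, 8L, 3L), 1)
  att <- matrix(1L, 1, 5)
  lab <- matrix(-1L, 1, 5); lab[1, 3] <- 9L
  fw <- encoder_forward(m, ids, att)
  ls <- mlm_loss_and_grad(m, fw, lab)
  gr <- encoder_backward(m, fw, ls$dX)
  gr$lm_W <- ls$d_lm_W; gr$lm_b <- ls$d_lm_b
  gflat <- peplm:::flatten_params(gr)
  flat <- peplm:::flatten_params(m$params)
  lossfn <- function(flat2) {
    m2 <- m; m2$params <- peplm:::unflatten_params(flat2, m$params)
    fw2 <- encoder_forward(m2, ids, att)
    mlm_loss_and_grad(m2, fw2, lab, with_grad = FALSE)$loss_mean
  }
  eps <- 1e-5
  for (nm in c("tok_emb", "layers1.Wv", "layers1.Wo", "layers1.W1",
               "layers1.ln1_g", "lm_W")) {
    i <- which.max(abs(gflat[[nm]]))  # probe the most influential entry
    f2 <- flat; f2[[nm]][i] <- f2[[nm]][i] + eps
    up <- lossfn(f2)
    f2[[nm]][i] <- f2[[nm]][i] - 2 * eps
    dn <- lossfn(f2)
    num <- (up - dn) / (2 * eps)
    expect_equal(gflat[[nm]][i], num, tolerance = 1e-4, label = nm)
  }
})
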