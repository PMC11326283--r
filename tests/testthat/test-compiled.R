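# The compiled kernels must reproduce the interpreted reference
# implementation exactly (same math, same cache semantics).

test_that("compiled and interpreted encoders agree to machine precision", {
  v <- test_vocab()
  set.seed(55)
  m <- init_model(model_config(vocab_size = vocab_size(v), layers = 2L,
                               heads = 4L, hidden = 32L, intermediate = 64L,
                               context = 96L))
  enc <- encode_batch(test_corpus()[1:8], v)
  h_cpp <- withr::with_options(list(peplm.use_compiled = TRUE),
                               peplm:::encoder_hidden(m, enc$ids, enc$attention))
  h_r <- withr::with_options(list(peplm.use_compiled = FALSE),
                             peplm:::encoder_hidden(m, enc$ids, enc$attention))
  expect_lt(max(abs(h_cpp - h_r)), 1e-10)
})

test_that("compiled and interpreted gradients agree for both objectives", {
  v <- test_vocab()
  set.seed(56)
  m <- init_model(model_config(vocab_size = vocab_size(v), layers = 2L,
                               heads = 2L, hidden = 16L, intermediate = 32L,
                               context = 96L))
  m$head <- list(w = stats::rnorm(16, sd = 0.1), b = -5.5)
  enc <- encode_batch(test_corpus()[1:6], v)
  y <- seq(-7, -5, length.out = 6)
  g_cpp <- withr::with_options(list(peplm.use_compiled = TRUE),
                               peplm:::regression_step_grads(m, enc, y, 1:6))
  g_r <- withr::with_options(list(peplm.use_compiled = FALSE),
                             peplm:::regression_step_grads(m, enc, y, 1:6))
  expect_setequal(names(g_cpp), names(g_r))
  for (nm in names(g_r)) {
    expect_lt(max(abs(g_r[[nm]] - g_cpp[[nm]])), 1e-10)
  }
  set.seed(57)
  mb <- apply_masking(enc, masking_config(), vocab_size(v))
  s_cpp <- withr::with_options(list(peplm.use_compiled = TRUE),
                               peplm:::mlm_step_grads(m, mb))
  s_r <- withr::with_options(list(peplm.use_compiled = FALSE),
                             peplm:::mlm_step_grads(m, mb))
  expect_equal(s_cpp$loss_sum, s_r$loss_sum, tolerance = 1e-12)
  expect_equal(s_cpp$n, s_r$n)
  for (nm in names(s_r$grads)) {
    expect_lt(max(abs(s_r$grads[[nm]] - s_cpp$grads[[nm]])), 1e-10)
  }
})
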