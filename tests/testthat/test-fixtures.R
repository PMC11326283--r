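test_that("noiseless fixtures are exactly linear in the planted descriptors", {
  lib <- test_library()
  fx <- make_toy_permeability_dataset(80, lib, generator_config(max_length = 8L),
                                      noise_sd = 0, undetectable_fraction = 0,
                                      other_assay_fraction = 0, seed = 7L)
  rec <- fx$records
  fit <- stats::lm(logP_exp ~ n_residues + n_methyl + has_peg + is_cyclic, data = rec)
  co <- stats::coef(fit)
  expect_equal(unname(co["(Intercept)"]), unname(fx$coefficients["intercept"]),
               tolerance = 1e-9)
  expect_equal(unname(co["n_residues"]), unname(fx$coefficients["n_residues"]),
               tolerance = 1e-9)
  expect_equal(unname(co["has_pegTRUE"]), unname(fx$coefficients["has_peg"]),
               tolerance = 1e-9)
  expect_lt(sigma(fit), 1e-9)
})

test_that("noisy fixtures recover coefficients within standard errors", {
  lib <- test_library()
  fx <- make_toy_permeability_dataset(500, lib, generator_config(max_length = 10L),
                                      noise_sd = 0.3, undetectable_fraction = 0,
                                      other_assay_fraction = 0, seed = 23L)
  fit <- stats::lm(logP_exp ~ n_residues + n_methyl + has_peg + is_cyclic,
                   data = fx$records)
  est <- stats::coef(summary(fit))
  planted <- fx$coefficients[c("intercept", "n_residues", "n_methyl",
                               "has_peg", "is_cyclic")]
  # 3.5 SE per coefficient keeps the family-wise error of the five
  # simultaneous checks near the single-test 3 SE level
  for (i in seq_len(5)) {
    expect_lt(abs(est[i, "Estimate"] - planted[i]), 3.5 * est[i, "Std. Error"])
  }
})

test_that("descriptors recomputed from the written file equal the in-memory values", {
  lib <- test_library()
  f <- tempfile(fileext = ".csv")
  fx <- make_toy_permeability_dataset(60, lib, generator_config(max_length = 8L),
                                      seed = 29L, path = f)
  back <- read_permeability_table(f, validate = FALSE)
  d <- compute_descriptors(back$smiles)
  expect_equal(d$n_residues, fx$records$n_residues)
  expect_equal(d$n_methyl, fx$records$n_methyl)
  expect_equal(d$has_peg, fx$records$has_peg)
  expect_equal(d$is_cyclic, fx$records$is_cyclic)
})

test_that("undetectable and off-assay rows are injected and the filter removes exactly them", {
  lib <- test_library()
  fx <- make_toy_permeability_dataset(200, lib, generator_config(max_length = 6L),
                                      undetectable_fraction = 0.05,
                                      other_assay_fraction = 0.10, seed = 31L)
  rec <- fx$records
  expect_equal(sum(rec$assay != "PAMPA"), 20L)
  expect_equal(sum(rec$logP_exp == -10), sum(rec$undetectable))
  expect_equal(sum(rec$undetectable), round(0.05 * sum(rec$assay == "PAMPA")))
  kept <- filter_records(rec)
  expect_equal(nrow(kept), sum(rec$assay == "PAMPA") - sum(rec$undetectable))
  expect_false(any(kept$logP_exp == -10))
  expect_error(make_toy_permeability_dataset(10, lib, coefficients = c(a = 1)),
               "coefficients")
})
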