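test_that("sampled specs recover the configured residue and stereo rates", {
  lib <- test_library()
  peps <- generate_peptides(3000, lib, generator_config(max_length = 20L),
                            seed = 11L, smiles = FALSE)
  n_res <- sum(peps$length)
  frac_u <- sum(peps$n_unnatural) / n_res
  expect_lt(abs(frac_u - 0.10), 3 * sqrt(0.1 * 0.9 / n_res))
  n_st <- sum(peps$n_stereocenters)
  frac_d <- sum(peps$n_d) / n_st
  expect_lt(abs(frac_d - 0.10), 3 * sqrt(0.1 * 0.9 / n_st))
  # lengths cover the configured range uniformly enough to span it
  expect_setequal(range(peps$length), c(1L, 20L))
})

test_that("degenerate probabilities behave deterministically", {
  lib <- test_library()
  peps <- generate_peptides(200, lib,
                            generator_config(max_length = 10L, unnatural_fraction = 0,
                                             nmeth_peptide_fraction = 0, peg_fraction = 0),
                            seed = 3L, smiles = FALSE)
  expect_true(all(peps$n_unnatural == 0))
  expect_true(all(peps$n_methyl == 0))
  expect_false(any(peps$pegylated))
  # glycine carries no stereocenter, so it can never be D
  gly_d <- vapply(peps$spec, function(s) {
    any(s$residues$code == "Gly" & s$residues$stereo != "none")
  }, logical(1))
  expect_false(any(gly_d))
  natonly <- lib[lib$natural, ]
  class(natonly) <- class(lib)
  expect_error(sample_peptide_spec(natonly, generator_config(unnatural_fraction = 0.1)),
               "no unnatural residues")
})

test_that("cyclization draws are uniform over types and degrade to linear when infeasible", {
  lib <- test_library()
  # all five chemistries feasible: two thiols, an amine, a carboxyl, length > 2
  spec <- make_spec(c("Ala", "Cys", "Lys", "Asp", "Cys", "Gly"))
  cfg <- generator_config()
  set.seed(42)
  draws <- replicate(4000, assign_cyclization(spec, lib, cfg)$cyclization$type)
  tab <- table(draws) / length(draws)
  expect_setequal(names(tab), cfg$cyclization_types)
  se3 <- 3 * sqrt(0.2 * 0.8 / length(draws))
  expect_true(all(abs(tab - 0.2) < se3))
  # no thiols: disulfide draw leaves the peptide linear
  nothiol <- make_spec(c("Ala", "Gly"))
  cfg_ds <- generator_config(cyclization_types = "disulfide")
  set.seed(1)
  expect_identical(assign_cyclization(nothiol, lib, cfg_ds)$cyclization$type, "linear")
  # single residue cannot close head-to-tail
  single <- make_spec("Ala")
  cfg_ht <- generator_config(cyclization_types = "head_to_tail")
  set.seed(1)
  expect_identical(assign_cyclization(single, lib, cfg_ht)$cyclization$type, "linear")
})

test_that("N-methylation hits the expected number of backbone amides", {
  lib <- test_library()
  spec <- make_spec(rep("Ala", 11))  # 10 backbone amides
  cfg <- generator_config(nmeth_peptide_fraction = 1)
  set.seed(9)
  counts <- replicate(3000, length(apply_n_methylation(spec, lib, cfg)$n_methyl_sites))
  se3 <- 3 * sqrt(10 * 0.2 * 0.8) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 2), se3)
  # position 1 (the alpha-amine) is never a backbone amide
  expect_false(any(replicate(50, 1L %in% apply_n_methylation(spec, lib, cfg)$n_methyl_sites)))
  # proline backbone N is tertiary and never methylated
  pro <- make_spec(c("Ala", "Pro", "Ala"))
  set.seed(2)
  hits <- replicate(200, apply_n_methylation(pro, lib, cfg)$n_methyl_sites)
  expect_false(any(vapply(hits, function(h) 2L %in% h, logical(1))))
})

test_that("PEGylation only uses free amines and draws 1-4 monomers uniformly", {
  lib <- test_library()
  cyc <- make_spec(rep("Ala", 4),
                   cyclization = list(type = "head_to_tail", sites = c(1L, 4L)))
  cfg <- generator_config(peg_fraction = 1)
  set.seed(5)
  expect_null(apply_pegylation(cyc, lib, cfg)$peg)
  free <- make_spec(c("Ala", "Lys", "Gly"))
  set.seed(5)
  pegs <- replicate(4000, apply_pegylation(free, lib, cfg)$peg, simplify = FALSE)
  expect_true(all(!vapply(pegs, is.null, logical(1))))
  mono <- vapply(pegs, `[[`, integer(1), "n_monomers")
  expect_identical(sort(unique(mono)), 1:4)
  tab <- table(mono) / length(mono)
  expect_true(all(abs(tab - 0.25) < 3 * sqrt(0.25 * 0.75 / length(mono))))
  sites <- vapply(pegs, function(p) as.character(p$site), character(1))
  expect_setequal(unique(sites), c("nterm", "2"))
})

test_that("assembled SMILES match textbook monomers and the reference peptide builder", {
  lib <- test_library()
  expect_identical(build_smiles(make_spec("Gly"), lib),
                   canonicalize_smiles("NCC(=O)O"))
  expect_identical(build_smiles(make_spec(c("Gly", "Gly")), lib),
                   canonicalize_smiles("NCC(=O)NCC(=O)O"))
  # independent oracle: RDKit's sequence reader, natural L peptides
  one <- c(A = "Ala", R = "Arg", L = "Leu", G = "Gly", C = "Cys", K = "Lys",
           E = "Glu", P = "Pro", W = "Trp", H = "His", S = "Ser", M = "Met")
  for (sq in c("ARLG", "CKE", "PGW", "HSM")) {
    codes <- unname(one[strsplit(sq, "")[[1]]])
    expect_identical(build_smiles(make_spec(codes), lib),
                     peptide_sequence_smiles(sq), label = sq)
  }
})

test_that("a fully modified tetrapeptide realizes all five modification classes", {
  lib <- test_library()
  # Ala->unnatural substitution, D stereo, sidechain-to-tail lactam,
  # backbone N-methylation, and PEG on the remaining free amine
  spec <- make_spec(c("Dab", "Arg", "Leu", "Gly"),
                    stereo = c("L", "L", "D", "none"),
                    cyclization = list(type = "sidechain_to_tail", sites = c(1L, 4L)),
                    n_methyl_sites = 3L,
                    peg = list(site = "nterm", n_monomers = 2L))
  sm <- build_smiles(spec, lib)
  expect_false(is.na(sm))
  d <- compute_descriptors(sm)
  expect_equal(d$n_residues, 4L)
  expect_equal(d$n_methyl, 1L)
  expect_true(d$has_peg)
  expect_true(d$is_cyclic)
})

test_that("residue count is conserved in the built molecules", {
  lib <- test_library()
  peps <- generate_peptides(150, lib, generator_config(max_length = 12L), seed = 21L)
  d <- compute_descriptors(peps$smiles)
  expect_equal(d$n_residues, peps$length)
  expect_equal(d$is_cyclic, peps$cyclization != "linear")
})

test_that("corpus generation is deterministic and summary matches the draw", {
  lib <- test_library()
  f1 <- tempfile(); f2 <- tempfile()
  s1 <- generate_corpus(120, lib, generator_config(max_length = 6L), seed = 33L, output = f1)
  s2 <- generate_corpus(120, lib, generator_config(max_length = 6L), seed = 33L, output = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unserialize(serialize(s1, NULL)), s2)
  expect_equal(s1$n, 120)
  expect_true(all(smiles_is_valid(readLines(f1))))
  f0 <- tempfile()
  s0 <- generate_corpus(0, lib, generator_config(), seed = 1L, output = f0)
  expect_identical(readLines(f0), character(0))
  expect_equal(s0$n, 0)
})
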