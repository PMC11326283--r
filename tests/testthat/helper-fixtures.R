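# Shared fixtures, built once per test session and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, fn(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

test_library <- function() memo("library", function() load_residue_library())

# a small corpus of short generated peptides (shared by tokenizer/mlm tests)
test_corpus <- function() memo("corpus", function() {
  generate_peptides(400, test_library(), generator_config(max_length = 8L),
                    seed = 101L)$smiles
})

test_vocab <- function() memo("vocab", function() {
  train_vocabulary(test_corpus(), tokenizer_config(budget = 200L))
})

# hand-built peptide spec
make_spec <- function(codes, stereo = NULL, cyclization = list(type = "linear", sites = integer(0)),
                      n_methyl_sites = integer(0), peg = NULL) {
  lib <- test_library()
  if (is.null(stereo)) {
    has <- lib$stereo[match(codes, lib$code)]
    stereo <- ifelse(has, "L", "none")
  }
  structure(list(residues = tibble::tibble(code = codes, stereo = stereo),
                 cyclization = cyclization, n_methyl_sites = n_methyl_sites,
                 peg = peg),
            class = "peptide_spec")
}

# tiny encoder shared by model-level tests
tiny_model <- function(vocab = test_vocab(), seed = 7L) {
  memo(paste0("tiny_model_", seed), function() {
    set.seed(seed)
    init_model(model_config(vocab_size = vocab_size(vocab), layers = 2L,
                            heads = 2L, hidden = 16L, intermediate = 32L,
                            context = 96L))
  })
}

# three well-separated gaussian blobs for clustering tests
blob_matrix <- function(n_per = 30L, d = 8L, sep = 12, seed = 5L) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(3 * d), 3, d) * sep
  X <- do.call(rbind, lapply(1:3, function(k) {
    matrix(stats::rnorm(n_per * d), n_per, d) + rep(centers[k, ], each = n_per)
  }))
  list(X = X, truth = rep(1:3, each = n_per))
}
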