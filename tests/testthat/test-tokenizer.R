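test_that("pretokenizer separates halogens and bracket atoms, preserving the string", {
  expect_identical(pretokenize("CCl"), c("C", "Cl"))
  expect_identical(pretokenize("C[Ag+]Br"), c("C", "[Ag+]", "Br"))
  expect_identical(pretokenize(""), character(0))
  expect_identical(pretokenize("BrBBr"), c("Br", "B", "Br"))
  # exhaustive small-string check against a character-walking oracle
  oracle <- function(s) {
    out <- character(0); i <- 1L
    while (i <= nchar(s)) {
      ch <- substr(s, i, i)
      if (ch == "[") {
        j <- regexpr("]", substr(s, i, nchar(s)), fixed = TRUE)
        out <- c(out, substr(s, i, i + j - 1L)); i <- i + j
      } else if (substr(s, i, i + 1L) %in% c("Cl", "Br")) {
        out <- c(out, substr(s, i, i + 1L)); i <- i + 2L
      } else {
        out <- c(out, ch); i <- i + 1L
      }
    }
    out
  }
  set.seed(4)
  pieces <- c("C", "c", "N", "O", "Cl", "Br", "B", "(", ")", "=", "1", "[nH]", "[O-]")
  for (r in 1:50) {
    s <- paste(sample(pieces, sample(1:8, 1), replace = TRUE), collapse = "")
    expect_identical(pretokenize(s), oracle(s), label = s)
    expect_identical(paste(pretokenize(s), collapse = ""), s)
  }
  expect_error(pretokenize("C[unclosed"), "offset 2")
})

test_that("vocabulary training learns frequent n-grams under the budget", {
  v <- train_vocabulary("CCC", tokenizer_config(budget = 10L))
  expect_identical(v$tokens[1:5], c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]"))
  expect_true(all(c("CC", "CCC") %in% v$tokens))
  # budget equal to the base alphabet: nothing learned
  v0 <- train_vocabulary("CCC", tokenizer_config(budget = 1L))
  expect_identical(v0$tokens, c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]", "C"))
  expect_error(train_vocabulary(character(0)), "empty corpus")
  # deterministic for fixed corpus and config
  v1 <- train_vocabulary(test_corpus(), tokenizer_config(budget = 120L))
  v2 <- train_vocabulary(test_corpus(), tokenizer_config(budget = 120L))
  expect_identical(v1$tokens, v2$tokens)
  # learned parenthetical motifs are full balanced groups
  learned <- v1$tokens[-seq_len(5L + v1$n_base)]
  paren <- grep("[()]", learned, value = TRUE)
  if (length(paren) > 0L) {
    expect_true(all(grepl("^\\(.*\\)$", paren)))
  }
})

test_that("encoding frames, pads, truncates and round-trips", {
  v <- test_vocab()
  e <- encode_smiles("", v, context_len = 8L)
  expect_identical(e$ids, c(2L, 3L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(e$true_length, 2L)
  expect_identical(e$attention, c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  # multi-character token used whole when present
  vx <- train_vocabulary("CCC", tokenizer_config(budget = 10L))
  ex <- encode_smiles("CCC", vx, context_len = 6L)
  expect_equal(ex$true_length, 3L)  # [CLS] CCC [SEP]
  expect_error(encode_smiles("C", v, context_len = 2L), "context_len")
  # round trip over generated molecules
  for (s in test_corpus()[1:200]) {
    dec <- decode_ids(encode_smiles(s, v, context_len = 256L), v)
    expect_identical(as.character(dec), s)
    expect_false(attr(dec, "lossy"))
  }
  # truncation breaks the round trip but keeps framing
  long <- strrep("C", 50)
  et <- encode_smiles(long, v, context_len = 10L)
  expect_equal(et$true_length, 10L)
  expect_identical(et$ids[1], 2L)
  expect_identical(et$ids[10], 3L)
})

test_that("unknown spans map to [UNK] and decoding flags the loss", {
  v <- test_vocab()
  e <- encode_smiles("CWC", v, context_len = 10L)  # W never occurs in peptide SMILES
  expect_true(1L %in% e$ids)
  dec <- decode_ids(e, v)
  expect_true(attr(dec, "lossy"))
  only_special <- decode_ids(c(2L, 4L, 3L, 0L), v)
  expect_identical(as.character(only_special), "")
  expect_error(decode_ids(c(2L, 999999L), v), "out of range")
})

test_that("coverage and compression hold on the training corpus", {
  v <- test_vocab()
  corpus <- test_corpus()
  enc <- lapply(corpus, encode_smiles, vocab = v, context_len = 512L)
  expect_false(any(vapply(enc, function(e) 1L %in% e$ids, logical(1))))
  tokens_learned <- sum(vapply(enc, function(e) e$true_length - 2L, integer(1)))
  chars <- sum(nchar(corpus))
  atoms <- sum(vapply(corpus, function(s) length(pretokenize(s)), integer(1)))
  expect_lt(tokens_learned / chars, atoms / chars)  # beats single-atom baseline
})

test_that("vocabulary files round-trip bit-exactly", {
  v <- test_vocab()
  f <- tempfile()
  write_vocabulary(v, f)
  v2 <- read_vocabulary(f)
  expect_identical(v$tokens, v2$tokens)
  expect_equal(v$n_base, v2$n_base)
  f2 <- tempfile()
  write_vocabulary(v2, f2)
  expect_identical(readLines(f), readLines(f2))
  writeLines(c("a", "b"), f)
  expect_error(read_vocabulary(f), "special tokens")
})
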