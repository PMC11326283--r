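SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
PAD_ID <- 0L
UNK_ID <- 1L
CLS_ID <- 2L
SEP_ID <- 3L
MASK_ID <- 4L

#' Atom-aware SMILES pretokenizer
#'
#' Splits a SMILES string into atomic tokens: the two-letter halogens `Cl`
#' and `Br` are kept whole (distinct from C/B), bracket expressions
#' `[...]` are kept as single units, and every other character is its own
#' token. The concatenation of the output always equals the input.
#'
#' @param smiles a single SMILES string.
#' @return character vector of atomic tokens.
#' @export
pretokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (!nzchar(smiles)) return(character(0))
  m <- gregexpr("\\[[^][]*\\]|Cl|Br|.", smiles)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  bad <- which(toks %in% c("[", "]"))
  if (length(bad) > 0L) {
    stop("unbalanced bracket in SMILES at offset ", m[bad[1]])
  }
  toks
}

#' Tokenizer configuration
#'
#' @param max_ngram_chars maximum character length of a learned token.
#' @param budget total number of non-special tokens in the vocabulary
#'   (single-character base alphabet plus learned n-grams). The default 581
#'   matches the vocabulary size used with the full pretraining corpus.
#' @param learn_runs,learn_bracketed,learn_parenthetical category flags:
#'   plain multi-atom runs, runs containing bracket atoms, and full
#'   balanced `(...)` motifs.
#' @return list of class `tokenizer_config`.
#' @export
tokenizer_config <- function(max_ngram_chars = 5L, budget = 581L,
                             learn_runs = TRUE, learn_bracketed = TRUE,
                             learn_parenthetical = TRUE) {
  if (max_ngram_chars < 1L) stop("max_ngram_chars must be >= 1")
  if (budget < 1L) stop("budget must be >= 1")
  structure(list(max_ngram_chars = as.integer(max_ngram_chars),
                 budget = as.integer(budget),
                 learn_runs = learn_runs,
                 learn_bracketed = learn_bracketed,
                 learn_parenthetical = learn_parenthetical),
            class = "tokenizer_config")
}

new_vocabulary <- function(learned, base) {
  tokens <- c(SPECIAL_TOKENS, base, learned)
  if (anyDuplicated(tokens)) stop("duplicate tokens in vocabulary")
  structure(list(tokens = tokens,
                 n_base = length(base),
                 max_token_chars = max(nchar(tokens[-seq_len(5L)]), 1L)),
            class = "smiles_vocabulary")
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat("<smiles_vocabulary> ", length(x$tokens), " tokens (5 special, ",
      x$n_base, " base, ", length(x$tokens) - 5L - x$n_base, " learned)\n",
      sep = "")
  invisible(x)
}

#' Size of a vocabulary
#' @param vocab a `smiles_vocabulary`.
#' @return integer token count (including the 5 special tokens).
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

# token id lookup; returns NA for unknown tokens. Ids are 0-based.
token_ids <- function(vocab, tokens) match(tokens, vocab$tokens) - 1L

#' Train an n-gram SMILES vocabulary
#'
#' Builds the vocabulary as: the 5 special tokens at ids 0-4, every single
#' atomic token observed in the corpus, and the most frequent multi-atom
#' n-grams (contiguous atomic-token runs of character length up to
#' `max_ngram_chars`, restricted to the enabled categories) up to the
#' budget. Frequency ties break lexicographically; the result is
#' deterministic for a fixed corpus and configuration.
#'
#' @param corpus path of a one-SMILES-per-line file, or a character vector
#'   of SMILES.
#' @param config a [tokenizer_config()].
#' @return a `smiles_vocabulary`.
#' @export
train_vocabulary <- function(corpus, config = tokenizer_config()) {
  lines <- if (length(corpus) == 1L && file.exists(corpus)) {
    readLines(corpus, warn = FALSE)
  } else {
    corpus
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("cannot train a vocabulary on an empty corpus")
  atom_lists <- lapply(lines, pretokenize)
  # separator longer than any learnable n-gram keeps runs within one line
  sep <- strrep("#", config$max_ngram_chars + 1L)
  atoms <- unlist(lapply(atom_lists, function(a) c(a, sep)), use.names = FALSE)
  base <- sort(unique(unlist(atom_lists, use.names = FALSE)))
  if (config$budget < length(base)) {
    stop("budget (", config$budget, ") is smaller than the base alphabet (",
         length(base), ")")
  }
  n_learn <- config$budget - length(base)
  learned <- character(0)
  if (n_learn > 0L) {
    counts <- list()
    n <- length(atoms)
    max_run <- config$max_ngram_chars  # every atom is >= 1 character
    for (k in 2:max(2L, max_run)) {
      if (k > n) break
      shifted <- lapply(seq_len(k), function(j) atoms[j:(n - k + j)])
      grams <- do.call(paste0, shifted)
      grams <- grams[nchar(grams) <= config$max_ngram_chars]
      if (length(grams)) counts[[length(counts) + 1L]] <- table(grams)
    }
    if (length(counts)) {
      tab <- stats::aggregate(
        count ~ gram,
        data = do.call(rbind, lapply(counts, function(t) {
          data.frame(gram = names(t), count = as.integer(t))
        })),
        FUN = sum
      )
      keep <- vapply(tab$gram, ngram_category_ok, logical(1), config = config)
      tab <- tab[keep, , drop = FALSE]
      tab <- tab[order(-tab$count, tab$gram), , drop = FALSE]
      learned <- utils::head(tab$gram, n_learn)
    }
  }
  new_vocabulary(learned, base)
}

# category filter for candidate n-grams
ngram_category_ok <- function(g, config) {
  has_paren <- grepl("[()]", g)
  has_bracket <- grepl("[][]", g)
  if (has_paren) {
    if (!config$learn_parenthetical) return(FALSE)
    # only a full balanced (...) group qualifies
    if (!grepl("^\\(", g) || !grepl("\\)$", g)) return(FALSE)
    chars <- strsplit(g, "")[[1]]
    depth <- cumsum((chars == "(") - (chars == ")"))
    return(all(depth[-length(depth)] >= 1) && depth[length(depth)] == 0)
  }
  if (has_bracket) return(config$learn_bracketed)
  config$learn_runs
}

#' Encode a SMILES string
#'
#' Greedy longest-match segmentation over atomic tokens, framed with
#' `[CLS]`/`[SEP]` and padded with `[PAD]` to the context length. Spans not
#' covered by the vocabulary map to `[UNK]`; sequences longer than
#' `context_len - 2` are tail-truncated before `[SEP]`.
#'
#' @param smiles a single SMILES string.
#' @param vocab a `smiles_vocabulary`.
#' @param context_len total sequence length after framing and padding.
#' @return an `encoded_sequence`: list with integer `ids` (0-based),
#'   `attention` (1 for real positions, 0 for padding), and `true_length`.
#' @export
encode_smiles <- function(smiles, vocab, context_len = 768L) {
  if (context_len < 3L) stop("context_len must be at least 3")
  atoms <- pretokenize(smiles)
  inner <- integer(0)
  if (length(atoms) > 0L) {
    ends <- cumsum(nchar(atoms))
    starts <- ends - nchar(atoms) + 1L
    n <- length(atoms)
    inner <- integer(n)  # upper bound
    m <- 0L
    i <- 1L
    while (i <= n) {
      jmax <- i
      while (jmax < n && ends[jmax + 1L] - starts[i] + 1L <= vocab$max_token_chars) {
        jmax <- jmax + 1L
      }
      hit_id <- NA_integer_
      hit_j <- i
      for (j in seq(jmax, i)) {
        cand <- substr(smiles, starts[i], ends[j])
        id <- token_ids(vocab, cand)
        if (!is.na(id)) { hit_id <- id; hit_j <- j; break }
      }
      m <- m + 1L
      inner[m] <- if (is.na(hit_id)) UNK_ID else hit_id
      i <- hit_j + 1L
    }
    inner <- inner[seq_len(m)]
  }
  if (length(inner) > context_len - 2L) inner <- inner[seq_len(context_len - 2L)]
  ids <- c(CLS_ID, inner, SEP_ID)
  true_length <- length(ids)
  ids <- c(ids, rep(PAD_ID, context_len - true_length))
  structure(list(ids = ids,
                 attention = as.integer(seq_len(context_len) <= true_length),
                 true_length = true_length),
            class = "encoded_sequence")
}

#' Decode token ids back to a SMILES string
#'
#' Concatenates the non-special tokens; the inverse of [encode_smiles()]
#' whenever no truncation occurred and no span mapped to `[UNK]`. If the
#' sequence contains `[UNK]` the result carries attribute `lossy = TRUE`.
#'
#' @param seq an `encoded_sequence` (or bare integer id vector).
#' @param vocab a `smiles_vocabulary`.
#' @return a single string, with attribute `lossy`.
#' @export
decode_ids <- function(seq, vocab) {
  ids <- if (inherits(seq, "encoded_sequence")) seq$ids else as.integer(seq)
  if (any(ids < 0L | ids >= vocab_size(vocab))) {
    stop("token id out of range for this vocabulary")
  }
  toks <- vocab$tokens[ids + 1L]
  lossy <- any(ids == UNK_ID)
  out <- paste0(toks[!(toks %in% SPECIAL_TOKENS)], collapse = "")
  attr(out, "lossy") <- lossy
  out
}

#' Save / load a vocabulary
#'
#' Plain-text format: one token per line, line number - 1 = token id.
#' Save and load round-trip bit-exactly.
#'
#' @param vocab a `smiles_vocabulary`.
#' @param path file path.
#' @return `write_vocabulary` returns `path` invisibly; `read_vocabulary`
#'   returns the vocabulary.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path, warn = FALSE)
  if (length(tokens) < 5L || !identical(tokens[1:5], SPECIAL_TOKENS)) {
    stop("not a vocabulary file: expected the 5 special tokens on lines 1-5")
  }
  rest <- tokens[-(1:5)]
  n_base <- sum(vapply(rest, function(t) length(pretokenize(t)) == 1L, logical(1)))
  structure(list(tokens = tokens,
                 n_base = n_base,
                 max_token_chars = max(nchar(rest), 1L)),
            class = "smiles_vocabulary")
}

#' Encode many SMILES into an id matrix
#'
#' @param smiles character vector.
#' @param vocab a `smiles_vocabulary`.
#' @param context_len sequence length; defaults to 2 plus the longest
#'   segmentation observed (capped at 768).
#' @return list with integer matrices `ids` and `attention` (rows =
#'   molecules) and vector `true_length`.
#' @export
encode_batch <- function(smiles, vocab, context_len = NULL) {
  encs <- lapply(smiles, encode_smiles, vocab = vocab,
                 context_len = if (is.null(context_len)) 768L else context_len)
  tl <- vapply(encs, `[[`, integer(1), "true_length")
  want <- if (is.null(context_len)) max(tl) else context_len
  ids <- t(vapply(encs, function(e) e$ids[seq_len(want)], integer(want)))
  att <- t(vapply(encs, function(e) e$attention[seq_len(want)], integer(want)))
  list(ids = ids, attention = att, true_length = tl)
}
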