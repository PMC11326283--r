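#' Masking configuration
#'
#' BERT-style corruption: each eligible position (non-special, non-padding)
#' is independently selected with probability `select_prob`; a selected
#' position becomes `[MASK]` with probability `mask_share`, a uniformly
#' random non-special token with probability `random_share`, or keeps its
#' original token with probability `keep_share`.
#'
#' @param select_prob per-position selection probability.
#' @param mask_share,random_share,keep_share corruption split; must sum to 1.
#' @return list of class `masking_config`.
#' @export
masking_config <- function(select_prob = 0.15, mask_share = 0.80,
                           random_share = 0.10, keep_share = 0.10) {
  if (select_prob < 0 || select_prob > 1) stop("select_prob must lie in [0, 1]")
  if (abs(mask_share + random_share + keep_share - 1) > 1e-12) {
    stop("mask_share + random_share + keep_share must equal 1")
  }
  structure(list(select_prob = select_prob, mask_share = mask_share,
                 random_share = random_share, keep_share = keep_share),
            class = "masking_config")
}

IGNORE_LABEL <- -1L

#' Apply masked-language-model corruption to an encoded batch
#'
#' Special-token and padding positions are never selected. Labels carry the
#' original token id at selected positions and the ignore marker (-1)
#' elsewhere; unselected inputs are left untouched. Uses the current RNG
#' stream.
#'
#' @param batch list with integer matrices `ids` and `attention` (as from
#'   [encode_batch()]).
#' @param cfg a [masking_config()].
#' @param vocab_size vocabulary size (for the random-token draw).
#' @return a `masked_batch`: list with `input_ids`, `labels`, `attention`.
#' @export
apply_masking <- function(batch, cfg = masking_config(), vocab_size) {
  ids <- batch$ids
  eligible <- ids >= 5L  # special tokens occupy ids 0-4
  sel <- eligible & (matrix(stats::runif(length(ids)), nrow(ids)) < cfg$select_prob)
  labels <- matrix(IGNORE_LABEL, nrow(ids), ncol(ids))
  labels[sel] <- ids[sel]
  input <- ids
  if (any(sel)) {
    u <- stats::runif(sum(sel))
    fate <- ifelse(u < cfg$mask_share, "mask",
                   ifelse(u < cfg$mask_share + cfg$random_share, "random", "keep"))
    vals <- ids[sel]
    vals[fate == "mask"] <- MASK_ID
    n_rand <- sum(fate == "random")
    if (n_rand > 0L) {
      if (vocab_size <= 5L) stop("vocabulary has no non-special tokens to corrupt with")
      vals[fate == "random"] <- sample(5:(vocab_size - 1L), n_rand, replace = TRUE)
    }
    input[sel] <- vals
  }
  structure(list(input_ids = input, labels = labels, attention = batch$attention),
            class = "masked_batch")
}
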