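#' Embed molecules with a pretrained encoder
#'
#' One fixed-length vector per molecule: the mean of the final-layer hidden
#' states over non-special, non-padding positions. Deterministic for a
#' given checkpoint.
#'
#' @param records a `permeability_records` tibble, or a character vector of
#'   SMILES.
#' @param model a `peplm_model`.
#' @param vocab the matching `smiles_vocabulary`.
#' @param batch_rows sequences per forward chunk.
#' @return numeric matrix, rows = molecules, columns = hidden units.
#' @export
embed_records <- function(records, model, vocab, batch_rows = 64L) {
  smiles <- if (is.character(records)) records else records$smiles
  enc <- encode_batch(smiles, vocab, context_len = NULL)
  if (ncol(enc$ids) > model$config$context) {
    warning("sequences longer than the model context were truncated")
    enc <- encode_batch(smiles, vocab, context_len = model$config$context)
  }
  n <- nrow(enc$ids)
  out <- matrix(0, n, model$config$hidden)
  for (start in seq(1L, n, by = batch_rows)) {
    rows <- start:min(start + batch_rows - 1L, n)
    out[rows, ] <- pooled_hidden(model, enc$ids[rows, , drop = FALSE],
                                 enc$attention[rows, , drop = FALSE])$pooled
  }
  out
}

# Mean-pool final hidden states over content positions (ids >= 5).
pooled_hidden <- function(model, ids, attention, train = FALSE) {
  if (!train) {
    hid <- encoder_hidden(model, ids, attention)
    fw <- list(hidden = hid, B = nrow(ids), T = ncol(ids))
  } else {
    fw <- encoder_forward(model, ids, attention, train = TRUE)
  }
  B <- fw$B; T <- fw$T
  content <- t(ids) >= 5L                   # T x B, matches row order
  wts <- as.vector(content)
  seq_of_row <- rep(seq_len(B), each = T)
  counts <- tapply(wts, seq_of_row, sum)
  pooled <- rowsum(fw$hidden * wts, group = seq_of_row) / pmax(1, as.vector(counts))
  list(pooled = pooled, fw = fw, wts = wts, seq_of_row = seq_of_row,
       counts = pmax(1, as.vector(counts)))
}
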