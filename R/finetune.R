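#' Finetune a pretrained encoder for permeability regression
#'
#' Replaces the language-modeling head with a single fully connected layer
#' of the hidden width producing one scalar, applied to the mean-pooled
#' final hidden states, and finetunes all weights under mean-squared-error
#' loss with AdamW. The validation set is scored after every epoch and the
#' checkpoint with the lowest validation MSE is returned. Defaults follow
#' the finetuning recipe for the full-size pretrained model (lr 5e-6,
#' dropout 0.15, weight decay 0.001, batch 16, up to 10,000 steps); tiny
#' desk-scale models need a larger learning rate.
#'
#' @param model a pretrained `peplm_model` (e.g. `fit$model` from
#'   [train_mlm()]).
#' @param vocab the matching `smiles_vocabulary`.
#' @param train tibble with columns `smiles` and `logP_exp`.
#' @param validation tibble with the same columns; must be non-empty
#'   (checkpoint selection is undefined without it).
#' @param lr learning rate.
#' @param dropout dropout rate on residual branches during finetuning.
#' @param weight_decay AdamW weight decay.
#' @param batch_size records per step.
#' @param max_steps optimizer step budget (0 returns the initial weights
#'   with a freshly attached head).
#' @param patience stop early after this many epochs without validation
#'   improvement (`Inf` disables early stopping).
#' @param seed RNG seed.
#' @param verbose print one line per epoch.
#' @return a `peplm_model` with a `head` element (`w`, `b`) and attribute
#'   `history` (tibble of epoch, step, validation MSE).
#' @export
finetune_regression <- function(model, vocab, train, validation,
                                lr = 5e-6, dropout = 0.15,
                                weight_decay = 0.001, batch_size = 16L,
                                max_steps = 10000L, patience = Inf,
                                seed = 1L, verbose = FALSE) {
  if (nrow(train) == 0L) stop("empty training set")
  if (is.null(validation) || nrow(validation) == 0L) {
    stop("empty validation set: checkpoint selection is undefined")
  }
  set.seed(seed)
  cfg <- model$config
  cfg$dropout <- dropout
  model$config <- cfg
  H <- cfg$hidden
  # head bias starts at the train mean so optimization begins at the
  # constant-predictor baseline instead of zero (targets sit around -6)
  model$head <- list(w = stats::rnorm(H, sd = 0.02), b = mean(train$logP_exp))
  enc_tr <- encode_batch(train$smiles, vocab, context_len = NULL)
  enc_va <- encode_batch(validation$smiles, vocab, context_len = NULL)
  y_tr <- train$logP_exp
  y_va <- validation$logP_exp
  flat <- flatten_params(model$params)
  flat$head.w <- model$head$w
  flat$head.b <- model$head$b
  opt <- adamw_init_flat(flat)
  n <- nrow(enc_tr$ids)
  steps_per_epoch <- max(1L, ceiling(n / batch_size))
  best <- list(mse = val_mse(model, enc_va, y_va), flat = flat, step = 0L)
  history <- list(tibble::tibble(epoch = 0L, step = 0L, val_mse = best$mse))
  step <- 0L
  epoch <- 0L
  stale <- 0L
  while (step < max_steps && stale < patience) {
    epoch <- epoch + 1L
    perm <- sample.int(n)
    for (s in seq_len(steps_per_epoch)) {
      if (step >= max_steps) break
      take <- perm[((s - 1L) * batch_size + 1L):min(s * batch_size, n)]
      g <- regression_step_grads(model, enc_tr, y_tr, take)
      step <- step + 1L
      res <- adamw_step(flat, g, opt, lr = lr, weight_decay = weight_decay)
      flat <- res$flat
      opt <- res$state
      model$params <- unflatten_params(flat, model$params)
      model$head <- list(w = flat$head.w, b = flat$head.b)
    }
    mse <- val_mse(model, enc_va, y_va)
    history[[length(history) + 1L]] <- tibble::tibble(epoch = epoch, step = step,
                                                      val_mse = mse)
    if (verbose) message(sprintf("epoch %d (step %d)  val MSE %.4f", epoch, step, mse))
    if (mse < best$mse) {
      best <- list(mse = mse, flat = flat, step = step)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
  }
  model$params <- unflatten_params(best$flat, model$params)
  model$head <- list(w = best$flat$head.w, b = best$flat$head.b)
  model$config$dropout <- 0
  attr(model, "history") <- dplyr::bind_rows(history)
  attr(model, "best_val_mse") <- best$mse
  model
}

adamw_init_flat <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

regression_step_grads <- function(model, enc, y, take) {
  ids <- enc$ids[take, , drop = FALSE]
  att <- enc$attention[take, , drop = FALSE]
  if (use_compiled()) {
    out <- .cpp_reg_step(model$params, model$head$w, model$head$b, ids, att,
                         y[take], model$config$heads, model$config$dropout)
    return(out[setdiff(names(out), c("pred", "loss"))])
  }
  ph <- pooled_hidden(model, ids, att, train = TRUE)
  pred <- as.vector(ph$pooled %*% model$head$w) + model$head$b
  err <- pred - y[take]
  B <- length(take)
  dpred <- 2 * err / B
  g <- list()
  g$head.w <- as.vector(crossprod(ph$pooled, dpred))
  g$head.b <- sum(dpred)
  dpooled <- outer(dpred, model$head$w)
  # scatter pooled gradient back to the content rows of each sequence
  dX <- dpooled[ph$seq_of_row, , drop = FALSE] *
    (ph$wts / ph$counts[ph$seq_of_row])
  gr <- encoder_backward(model, ph$fw, dX)
  gf <- flatten_params(gr)
  c(gf, g)
}

val_mse <- function(model, enc, y, batch_rows = 64L) {
  mean((predict_encoded(model, enc, batch_rows) - y)^2)
}

predict_encoded <- function(model, enc, batch_rows = 64L) {
  n <- nrow(enc$ids)
  pred <- numeric(n)
  for (start in seq(1L, n, by = batch_rows)) {
    rows <- start:min(start + batch_rows - 1L, n)
    ph <- pooled_hidden(model, enc$ids[rows, , drop = FALSE],
                        enc$attention[rows, , drop = FALSE])
    pred[rows] <- as.vector(ph$pooled %*% model$head$w) + model$head$b
  }
  pred
}

#' Predict permeability with a finetuned model
#'
#' @param model a finetuned `peplm_model` (with a regression head).
#' @param records a `permeability_records` tibble or character vector of
#'   SMILES.
#' @param vocab the matching `smiles_vocabulary`.
#' @return numeric vector of predicted log10 permeability.
#' @export
predict_permeability <- function(model, records, vocab) {
  if (is.null(model$head)) stop("model has no regression head; finetune first")
  smiles <- if (is.character(records)) records else records$smiles
  enc <- encode_batch(smiles, vocab,
                      context_len = NULL)
  predict_encoded(model, enc)
}

#' Ensemble prediction from k-fold models
#'
#' Per-record arithmetic mean of the scalar outputs of the fold models.
#'
#' @param models non-empty list of finetuned `peplm_model`s sharing one
#'   vocabulary and configuration.
#' @param records records or SMILES to predict.
#' @param vocab the shared `smiles_vocabulary`.
#' @return numeric vector of ensemble predictions.
#' @export
ensemble_predict <- function(models, records, vocab) {
  if (length(models) == 0L) stop("ensemble requires at least one model")
  preds <- vapply(models, predict_permeability, records = records,
                  vocab = vocab, numeric(if (is.character(records)) length(records) else nrow(records)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}
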