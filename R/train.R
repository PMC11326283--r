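# ---- AdamW ------------------------------------------------------------------

adamw_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

# One AdamW update on the flattened parameter list. Layer norms and biases
# are exempt from weight decay, as is conventional.
adamw_step <- function(flat, grads_flat, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    gr <- grads_flat[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    decay <- if (weight_decay > 0 && !grepl("(^|\\.)(b[a-z0-9]*|ln[12]_[gb]|lm_b)$", nm)) {
      weight_decay * flat[[nm]]
    } else 0
    flat[[nm]] <- flat[[nm]] - lr * (upd + decay)
  }
  list(flat = flat, state = state)
}

unflatten_params <- function(flat, skeleton) {
  rebuild <- function(p, prefix = "") {
    for (nm in names(p)) {
      v <- p[[nm]]
      if (is.list(v)) {
        for (i in seq_along(v)) {
          p[[nm]][[i]] <- rebuild(v[[i]], paste0(prefix, nm, i, "."))
        }
      } else {
        p[[nm]] <- flat[[paste0(prefix, nm)]]
      }
    }
    p
  }
  rebuild(skeleton)
}

# ---- loss -------------------------------------------------------------------

# Cross-entropy over label positions. Returns loss (sum and per-position
# mean) and the gradient w.r.t. the final hidden states.
mlm_loss_and_grad <- function(model, fw, labels, with_grad = TRUE) {
  lab <- as.vector(t(labels))             # align with sequence-major rows
  rows <- which(lab != IGNORE_LABEL)
  if (length(rows) == 0L) {
    return(list(loss_sum = 0, loss_mean = NA_real_, n = 0L, dX = NULL))
  }
  Hsub <- fw$hidden[rows, , drop = FALSE]
  logits <- add_bias(Hsub %*% model$params$lm_W, model$params$lm_b)
  P <- softmax_rows(logits)
  tgt <- lab[rows] + 1L
  picked <- P[cbind(seq_along(rows), tgt)]
  loss_sum <- -sum(log(pmax(picked, 1e-12)))
  out <- list(loss_sum = loss_sum, loss_mean = loss_sum / length(rows),
              n = length(rows), pred = max.col(P, ties.method = "first") - 1L,
              target = lab[rows])
  if (with_grad) {
    dlogits <- P
    dlogits[cbind(seq_along(rows), tgt)] <- dlogits[cbind(seq_along(rows), tgt)] - 1
    dlogits <- dlogits / length(rows)     # mean-normalized objective
    out$d_lm_W <- crossprod(Hsub, dlogits)
    out$d_lm_b <- colSums(dlogits)
    dX <- matrix(0, nrow(fw$hidden), ncol(fw$hidden))
    dX[rows, ] <- tcrossprod(dlogits, model$params$lm_W)
    out$dX <- dX
  }
  out
}

# One optimizer step's gradients for the MLM objective, via the compiled
# kernel when available.
mlm_step_grads <- function(model, mb) {
  if (use_compiled()) {
    out <- .cpp_mlm_step(model$params, mb$input_ids, mb$attention, mb$labels,
                         model$config$heads, model$config$dropout)
    n <- out$n
    if (n == 0L) return(list(n = 0L, grads = NULL))
    grads <- out[setdiff(names(out), c("loss_sum", "n"))]
    return(list(n = n, loss_sum = out$loss_sum, grads = grads))
  }
  fw <- encoder_forward(model, mb$input_ids, mb$attention, train = TRUE)
  ls <- mlm_loss_and_grad(model, fw, mb$labels)
  if (ls$n == 0L) return(list(n = 0L, grads = NULL))
  grads <- encoder_backward(model, fw, ls$dX)
  grads$lm_W <- ls$d_lm_W
  grads$lm_b <- ls$d_lm_b
  list(n = ls$n, loss_sum = ls$loss_sum, grads = flatten_params(grads))
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing archive holding the model
#' configuration, the weights, and a hash of the vocabulary it was trained
#' with; loading against a different vocabulary is refused.
#'
#' @param model a `peplm_model`.
#' @param vocab the `smiles_vocabulary` the model was trained with.
#' @param path file path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, vocab, path) {
  saveRDS(list(config = model$config, params = model$params,
               vocab_hash = rlang::hash(vocab$tokens),
               head = model$head), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, vocab) {
  ck <- readRDS(path)
  if (!identical(ck$vocab_hash, rlang::hash(vocab$tokens))) {
    stop("checkpoint was trained with a different vocabulary")
  }
  structure(list(config = ck$config, params = ck$params, head = ck$head),
            class = "peplm_model")
}

# ---- pretraining ------------------------------------------------------------

#' Pretrain the masked language model
#'
#' Optimizes cross-entropy at corrupted positions with AdamW under a linear
#' warmup schedule, evaluating on a held-out split of the corpus every
#' `eval_interval` steps. Fully reproducible from `seed`.
#'
#' @param corpus path to a one-SMILES-per-line file, or a character vector.
#' @param vocab a `smiles_vocabulary`.
#' @param config a [model_config()]; its `vocab_size` must match `vocab`.
#' @param steps optimizer steps.
#' @param batch_size sequences per step.
#' @param lr peak learning rate.
#' @param warmup_steps linear warmup length.
#' @param validation_fraction share of lines held out for validation.
#' @param eval_interval evaluate every this many steps.
#' @param masking a [masking_config()].
#' @param seed integer seed.
#' @param context_len encode length; defaults to the longest corpus line
#'   (capped at the model context).
#' @param verbose print one line per evaluation.
#' @return list of class `mlm_fit`: `model`, `report` (tibble of step,
#'   split, loss_mean, loss_sum, macro_accuracy), `vocab_hash`.
#' @export
train_mlm <- function(corpus, vocab, config, steps = 200L, batch_size = 64L,
                      lr = 5e-5, warmup_steps = ceiling(steps / 10),
                      validation_fraction = 0.1, eval_interval = 50L,
                      masking = masking_config(), seed = 1L,
                      context_len = NULL, verbose = FALSE) {
  lines <- if (length(corpus) == 1L && file.exists(corpus)) {
    readLines(corpus, warn = FALSE)
  } else corpus
  lines <- lines[nzchar(lines)]
  if (length(lines) < batch_size) {
    stop("corpus (", length(lines), " lines) is smaller than one batch (",
         batch_size, ")")
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must lie in (0, 1)")
  }
  if (config$vocab_size != vocab_size(vocab)) {
    stop("model config vocab_size does not match the vocabulary")
  }
  set.seed(seed)
  n_val <- max(1L, round(length(lines) * validation_fraction))
  val_idx <- sample.int(length(lines), n_val)
  train_lines <- lines[-val_idx]
  val_lines <- lines[val_idx]
  enc_train <- encode_batch(train_lines, vocab, context_len = context_len)
  enc_val <- encode_batch(val_lines, vocab, context_len = context_len)
  Tmax <- max(ncol(enc_train$ids), ncol(enc_val$ids))
  if (Tmax > config$context) stop("corpus needs context ", Tmax,
                                  " but model context is ", config$context)
  model <- init_model(config)
  flat <- flatten_params(model$params)
  opt <- adamw_init(model$params)
  V <- config$vocab_size
  eval_seed <- sample.int(.Machine$integer.max, 1L)
  report <- list()
  evaluate_now <- function(model, step) {
    ev <- evaluate_mlm(model, enc_val, masking, seed = eval_seed)
    if (verbose) {
      message(sprintf("step %d  val loss %.4f  macro acc %.3f",
                      step, ev$loss_mean, ev$macro_accuracy))
    }
    tibble::tibble(step = step, split = "validation", loss_mean = ev$loss_mean,
                   loss_sum = ev$loss_sum, macro_accuracy = ev$macro_accuracy)
  }
  report[[1]] <- evaluate_now(model, 0L)
  n_train <- nrow(enc_train$ids)
  order_pool <- integer(0)
  for (step in seq_len(steps)) {
    if (length(order_pool) < batch_size) {
      order_pool <- c(order_pool, sample.int(n_train))
    }
    take <- order_pool[seq_len(batch_size)]
    order_pool <- order_pool[-seq_len(batch_size)]
    sub <- list(ids = enc_train$ids[take, , drop = FALSE],
                attention = enc_train$attention[take, , drop = FALSE])
    mb <- apply_masking(sub, masking, V)
    gflat <- mlm_step_grads(model, mb)
    if (gflat$n > 0L && lr > 0) {
      lr_t <- if (step <= warmup_steps && warmup_steps > 0) {
        lr * step / warmup_steps
      } else lr
      res <- adamw_step(flat, gflat$grads, opt, lr = lr_t, weight_decay = 0.01)
      flat <- res$flat
      opt <- res$state
      model$params <- unflatten_params(flat, model$params)
    }
    if (step %% eval_interval == 0L || step == steps) {
      report[[length(report) + 1L]] <- evaluate_now(model, step)
    }
  }
  structure(list(model = model, report = dplyr::bind_rows(report),
                 vocab_hash = rlang::hash(vocab$tokens)),
            class = "mlm_fit")
}

#' Evaluate a masked language model
#'
#' Applies the masking scheme to held-out sequences and reports
#' cross-entropy at the corrupted positions (sum over positions and
#' per-position mean) together with macro-averaged accuracy: per-token-class
#' accuracy averaged unweighted over the classes observed among the labels.
#'
#' @param model a `peplm_model`.
#' @param data held-out lines (character), or an encoded batch from
#'   [encode_batch()].
#' @param masking a [masking_config()].
#' @param vocab required when `data` is character.
#' @param seed seed for the evaluation masking draw.
#' @param batch_rows sequences per forward chunk.
#' @return list with `loss_sum`, `loss_mean`, `macro_accuracy`, `n_masked`.
#' @export
evaluate_mlm <- function(model, data, masking = masking_config(), vocab = NULL,
                         seed = 1L, batch_rows = 64L) {
  if (is.character(data)) {
    if (is.null(vocab)) stop("vocab is required to encode character data")
    data <- encode_batch(data, vocab)
  }
  if (nrow(data$ids) == 0L) stop("empty evaluation set")
  set.seed(seed)
  mb <- apply_masking(data, masking, model$config$vocab_size)
  n <- nrow(mb$input_ids)
  loss_sum <- 0; n_masked <- 0L
  pred_all <- integer(0); tgt_all <- integer(0)
  for (start in seq(1L, n, by = batch_rows)) {
    rows <- start:min(start + batch_rows - 1L, n)
    hid <- encoder_hidden(model, mb$input_ids[rows, , drop = FALSE],
                          mb$attention[rows, , drop = FALSE])
    ls <- mlm_loss_and_grad(model, list(hidden = hid),
                            mb$labels[rows, , drop = FALSE],
                            with_grad = FALSE)
    loss_sum <- loss_sum + ls$loss_sum
    n_masked <- n_masked + ls$n
    pred_all <- c(pred_all, ls$pred)
    tgt_all <- c(tgt_all, ls$target)
  }
  if (n_masked == 0L) stop("masking selected no positions in the evaluation set")
  per_class <- tapply(pred_all == tgt_all, tgt_all, mean)
  list(loss_sum = loss_sum, loss_mean = loss_sum / n_masked,
       macro_accuracy = mean(per_class), n_masked = n_masked)
}

#' @export
print.mlm_fit <- function(x, ...) {
  last <- x$report[nrow(x$report), ]
  cat("<mlm_fit> ", format(n_parameters(x$model$config), big.mark = ","),
      " parameters; final validation loss ", sprintf("%.4f", last$loss_mean),
      ", macro accuracy ", sprintf("%.3f", last$macro_accuracy), "\n", sep = "")
  invisible(x)
}
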