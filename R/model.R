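#' Encoder configuration
#'
#' BERT-style bidirectional encoder with rotary position embeddings (RoPE),
#' post-layer normalization, GELU feed-forward blocks, and a linear
#' language-modeling head. The full-size defaults (6 layers, 12 heads,
#' hidden 768, intermediate 3072, context 768) instantiate at ~44M
#' trainable parameters with a 586-token vocabulary.
#'
#' @param vocab_size vocabulary size (including special tokens).
#' @param layers transformer blocks.
#' @param heads attention heads; must divide `hidden`.
#' @param hidden embedding width.
#' @param intermediate feed-forward inner width.
#' @param context maximum sequence length.
#' @param dropout dropout rate on residual branches (0 disables).
#' @return list of class `model_config`.
#' @export
model_config <- function(vocab_size, layers = 6L, heads = 12L, hidden = 768L,
                         intermediate = 3072L, context = 768L, dropout = 0) {
  if (hidden %% heads != 0L) stop("hidden must be divisible by heads")
  if ((hidden / heads) %% 2L != 0L) stop("head dimension must be even for rotary embeddings")
  if (context < 3L) stop("context must be at least 3")
  structure(list(vocab_size = as.integer(vocab_size), layers = as.integer(layers),
                 heads = as.integer(heads), hidden = as.integer(hidden),
                 intermediate = as.integer(intermediate),
                 context = as.integer(context), dropout = dropout),
            class = "model_config")
}

#' Number of trainable parameters
#'
#' @param x a `model_config` or an initialized model.
#' @return integer parameter count.
#' @export
n_parameters <- function(x) {
  if (inherits(x, "peplm_model")) {
    return(sum(vapply(flatten_params(x$params), length, numeric(1))))
  }
  cfg <- x
  emb <- cfg$vocab_size * cfg$hidden
  attn <- 4L * (cfg$hidden * cfg$hidden + cfg$hidden)
  ffn <- cfg$hidden * cfg$intermediate + cfg$intermediate +
    cfg$intermediate * cfg$hidden + cfg$hidden
  ln <- 4L * cfg$hidden
  head <- cfg$hidden * cfg$vocab_size + cfg$vocab_size
  emb + cfg$layers * (attn + ffn + ln) + head
}

#' Initialize an encoder
#'
#' Weights are drawn N(0, 0.02^2), biases start at zero, layer-norm gains
#' at one. Uses the current RNG stream.
#'
#' @param config a [model_config()].
#' @return list of class `peplm_model` with elements `config` and `params`.
#' @export
init_model <- function(config) {
  H <- config$hidden; I <- config$intermediate; V <- config$vocab_size
  rnorm_mat <- function(r, c) matrix(stats::rnorm(r * c, sd = 0.02), r, c)
  layer <- function() list(
    Wq = rnorm_mat(H, H), bq = numeric(H),
    Wk = rnorm_mat(H, H), bk = numeric(H),
    Wv = rnorm_mat(H, H), bv = numeric(H),
    Wo = rnorm_mat(H, H), bo = numeric(H),
    ln1_g = rep(1, H), ln1_b = numeric(H),
    W1 = rnorm_mat(H, I), b1 = numeric(I),
    W2 = rnorm_mat(I, H), b2 = numeric(H),
    ln2_g = rep(1, H), ln2_b = numeric(H)
  )
  params <- list(
    tok_emb = rnorm_mat(V, H),
    layers = lapply(seq_len(config$layers), function(i) layer()),
    lm_W = rnorm_mat(H, V), lm_b = numeric(V)
  )
  structure(list(config = config, params = params), class = "peplm_model")
}

#' @export
print.peplm_model <- function(x, ...) {
  cfg <- x$config
  cat("<peplm_model> ", cfg$layers, " layers, ", cfg$heads, " heads, hidden ",
      cfg$hidden, ", vocab ", cfg$vocab_size, ", ",
      format(n_parameters(cfg), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    v <- p[[nm]]
    if (is.list(v)) {
      for (i in seq_along(v)) {
        out <- c(out, flatten_params(v[[i]], paste0(prefix, nm, i, ".")))
      }
    } else {
      out[[paste0(prefix, nm)]] <- v
    }
  }
  out
}

# ---- numerical pieces -------------------------------------------------------

add_bias <- function(M, b) M + rep(b, each = nrow(M))

gelu <- function(x) {
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}

# forward pass caching the tanh term so the backward pass need not redo it
gelu_with_cache <- function(x) {
  t <- tanh(sqrt(2 / pi) * (x + 0.044715 * x^3))
  list(y = 0.5 * x * (1 + t), t = t)
}

gelu_grad <- function(x, t = NULL) {
  if (is.null(t)) t <- tanh(sqrt(2 / pi) * (x + 0.044715 * x^3))
  0.5 * (1 + t) + 0.5 * x * (1 - t^2) * sqrt(2 / pi) * (1 + 3 * 0.044715 * x^2)
}

LN_EPS <- 1e-5

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- Xc * inv
  list(y = add_bias(xhat * rep(g, each = nrow(X)), b), xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  n <- ncol(cache$xhat)
  dxhat <- dY * rep(g, each = nrow(dY))
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  rs1 <- rowMeans(dxhat)
  rs2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - rs1 - cache$xhat * rs2)
  list(dX = dX, dg = dg, db = db)
}

# Rotary embedding machinery. C and S are (rows x hidden) cos/sin tables;
# dir = +1 applies the rotation, -1 its transpose (used in backprop).
rope_tables <- function(positions, heads, head_dim, hidden) {
  theta <- 10000^(-(2 * (seq_len(head_dim / 2) - 1)) / head_dim)
  colfreq <- rep(rep(theta, each = 2), heads)
  ang <- outer(positions, colfreq)
  list(C = cos(ang), S = sin(ang))
}

rope_swapsign <- function(M) {
  n <- ncol(M)
  swap <- as.vector(rbind(seq(2, n, 2), seq(1, n, 2)))
  sgn <- rep(c(-1, 1), n / 2)
  M[, swap, drop = FALSE] * rep(sgn, each = nrow(M))
}

rope_apply <- function(M, tabs, dir = 1) {
  M * tabs$C + dir * rope_swapsign(M) * tabs$S
}

softmax_rows <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  E <- exp(M - mx)
  E / rowSums(E)
}

# Compiled fast path (src/encoder.cpp) mirrors the R reference
# implementation; set options(peplm.use_compiled = FALSE) to force the
# interpreted path everywhere.
use_compiled <- function() {
  isTRUE(getOption("peplm.use_compiled", TRUE))
}

# Inference-only forward: final hidden states without caches.
encoder_hidden <- function(model, ids, attention) {
  cfg <- model$config
  if (ncol(ids) > cfg$context) stop("sequence length ", ncol(ids),
                                    " exceeds model context ", cfg$context)
  if (any(ids >= cfg$vocab_size)) stop("token id out of range for model vocabulary")
  if (use_compiled()) {
    .cpp_encoder_hidden(model$params, ids, attention, cfg$heads)
  } else {
    encoder_forward(model, ids, attention)$hidden
  }
}

# ---- encoder forward --------------------------------------------------------

# ids, attention: B x T integer matrices (0-based ids). Returns the final
# hidden states as a (B*T) x H matrix (rows ordered sequence-major) plus the
# caches backprop needs. `positions` may shift the rotary phase (used by the
# offset-invariance tests); defaults to 0..T-1 for every sequence.
encoder_forward <- function(model, ids, attention, train = FALSE,
                            positions = NULL) {
  cfg <- model$config
  p <- model$params
  B <- nrow(ids); T <- ncol(ids)
  if (T > cfg$context) stop("sequence length ", T, " exceeds model context ", cfg$context)
  if (any(ids >= cfg$vocab_size)) stop("token id out of range for model vocabulary")
  H <- cfg$hidden; nh <- cfg$heads; dh <- H / nh
  idx <- as.vector(t(ids)) + 1L          # row r = (b-1)*T + t
  X <- p$tok_emb[idx, , drop = FALSE]
  if (is.null(positions)) positions <- rep(seq_len(T) - 1, B)
  tabs <- rope_tables(positions, nh, dh, H)
  drop_rate <- if (train) cfg$dropout else 0
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    lp <- p$layers[[l]]
    Q <- rope_apply(add_bias(X %*% lp$Wq, lp$bq), tabs)
    K <- rope_apply(add_bias(X %*% lp$Wk, lp$bk), tabs)
    V <- add_bias(X %*% lp$Wv, lp$bv)
    O <- matrix(0, B * T, H)
    A_list <- vector("list", B * nh)
    for (b in seq_len(B)) {
      rows <- ((b - 1) * T + 1):(b * T)
      keymask <- ifelse(attention[b, ] == 1, 0, -1e30)
      for (h in seq_len(nh)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dh)
        S <- S + rep(keymask, each = T)
        A <- softmax_rows(S)
        A_list[[(b - 1) * nh + h]] <- A
        O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      }
    }
    attn_out <- add_bias(O %*% lp$Wo, lp$bo)
    dmask1 <- NULL
    if (drop_rate > 0) {
      dmask1 <- matrix(stats::runif(length(attn_out)) >= drop_rate,
                       nrow(attn_out)) / (1 - drop_rate)
      attn_out <- attn_out * dmask1
    }
    ln1 <- ln_forward(X + attn_out, lp$ln1_g, lp$ln1_b)
    Xn <- ln1$y
    H1 <- add_bias(Xn %*% lp$W1, lp$b1)
    gc_ <- gelu_with_cache(H1)
    G <- gc_$y
    ffn_out <- add_bias(G %*% lp$W2, lp$b2)
    dmask2 <- NULL
    if (drop_rate > 0) {
      dmask2 <- matrix(stats::runif(length(ffn_out)) >= drop_rate,
                       nrow(ffn_out)) / (1 - drop_rate)
      ffn_out <- ffn_out * dmask2
    }
    ln2 <- ln_forward(Xn + ffn_out, lp$ln2_g, lp$ln2_b)
    caches[[l]] <- list(X = X, Q = Q, K = K, V = V, O = O, A = A_list,
                        ln1 = ln1, Xn = Xn, H1 = H1, G = G, gelu_t = gc_$t,
                        dmask1 = dmask1, dmask2 = dmask2)
    X <- ln2$y
    caches[[l]]$ln2 <- ln2
  }
  list(hidden = X, caches = caches, tabs = tabs, idx = idx, B = B, T = T)
}

#' Forward pass of the masked language model
#'
#' Runs the encoder and the language-modeling head, returning a per-position
#' probability distribution over the vocabulary. Padding positions are
#' excluded from attention via the attention flags.
#'
#' @param model a `peplm_model`.
#' @param ids integer matrix (sequences x positions) of 0-based token ids,
#'   or an `encoded_sequence`.
#' @param attention matching 0/1 attention matrix.
#' @return array of probabilities, dim (sequences, positions, vocab).
#' @export
mlm_forward <- function(model, ids, attention = NULL) {
  if (inherits(ids, "encoded_sequence")) {
    attention <- matrix(ids$attention, 1)
    ids <- matrix(ids$ids, 1)
  }
  if (is.null(attention)) attention <- matrix(1L, nrow(ids), ncol(ids))
  fw <- encoder_forward(model, ids, attention)
  logits <- add_bias(fw$hidden %*% model$params$lm_W, model$params$lm_b)
  probs <- softmax_rows(logits)
  aperm(array(t(probs), c(model$config$vocab_size, fw$T, fw$B)), c(3, 2, 1))
}

# ---- encoder backward -------------------------------------------------------

# dX: gradient w.r.t. final hidden states, (B*T) x H. Returns gradient lists
# mirroring the parameter structure.
encoder_backward <- function(model, fw, dX) {
  cfg <- model$config
  p <- model$params
  H <- cfg$hidden; nh <- cfg$heads; dh <- H / nh
  B <- fw$B; T <- fw$T
  grads <- list(layers = vector("list", cfg$layers))
  for (l in rev(seq_len(cfg$layers))) {
    lp <- p$layers[[l]]
    ca <- fw$caches[[l]]
    g <- list()
    bl2 <- ln_backward(dX, ca$ln2, lp$ln2_g)
    g$ln2_g <- bl2$dg; g$ln2_b <- bl2$db
    dffn <- bl2$dX
    if (!is.null(ca$dmask2)) dffn <- dffn * ca$dmask2
    g$W2 <- crossprod(ca$G, dffn)
    g$b2 <- colSums(dffn)
    dG <- tcrossprod(dffn, lp$W2)
    dH1 <- dG * gelu_grad(ca$H1, ca$gelu_t)
    g$W1 <- crossprod(ca$Xn, dH1)
    g$b1 <- colSums(dH1)
    dXn <- bl2$dX + tcrossprod(dH1, lp$W1)
    bl1 <- ln_backward(dXn, ca$ln1, lp$ln1_g)
    g$ln1_g <- bl1$dg; g$ln1_b <- bl1$db
    dattn <- bl1$dX
    if (!is.null(ca$dmask1)) dattn <- dattn * ca$dmask1
    g$Wo <- crossprod(ca$O, dattn)
    g$bo <- colSums(dattn)
    dO <- tcrossprod(dattn, lp$Wo)
    dQ <- matrix(0, B * T, H); dK <- matrix(0, B * T, H); dV <- matrix(0, B * T, H)
    for (b in seq_len(B)) {
      rows <- ((b - 1) * T + 1):(b * T)
      for (h in seq_len(nh)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        A <- ca$A[[(b - 1) * nh + h]]
        dOb <- dO[rows, cols, drop = FALSE]
        Vb <- ca$V[rows, cols, drop = FALSE]
        dA <- tcrossprod(dOb, Vb)
        dV[rows, cols] <- crossprod(A, dOb)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- (dS %*% ca$K[rows, cols, drop = FALSE]) / sqrt(dh)
        dK[rows, cols] <- crossprod(dS, ca$Q[rows, cols, drop = FALSE]) / sqrt(dh)
      }
    }
    dQ <- rope_apply(dQ, fw$tabs, dir = -1)
    dK <- rope_apply(dK, fw$tabs, dir = -1)
    X <- ca$X
    g$Wq <- crossprod(X, dQ); g$bq <- colSums(dQ)
    g$Wk <- crossprod(X, dK); g$bk <- colSums(dK)
    g$Wv <- crossprod(X, dV); g$bv <- colSums(dV)
    dX <- bl1$dX + tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) +
      tcrossprod(dV, lp$Wv)
    grads$layers[[l]] <- g
  }
  demb <- matrix(0, cfg$vocab_size, H)
  agg <- rowsum(dX, group = fw$idx)
  demb[as.integer(rownames(agg)), ] <- agg
  grads$tok_emb <- demb
  grads
}
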