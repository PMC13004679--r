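#' Encoder configuration
#'
#' Hyperparameters of the small transformer used to embed tokenized patient
#' records. The encoder is trained in two phases: a masked-encounter
#' objective (cross-entropy at masked code positions) followed by a
#' contrastive objective over temporally contiguous segment pairs of the same
#' patient (normalized-temperature cross-entropy on cosine similarities).
#'
#' @param n_layers transformer layers.
#' @param n_heads attention heads; must divide `hidden_dim`.
#' @param hidden_dim model width; patient embeddings have width
#'   `2 * hidden_dim` (first-layer + final-layer pooling).
#' @param dropout dropout rate applied to sublayer outputs during training.
#' @param max_len maximum token-sequence length.
#' @param mask_fraction fraction of code tokens masked per sequence.
#' @param temperature contrastive softmax temperature (> 0).
#' @param batch_size sequences per optimization step.
#' @param epochs,contrastive_epochs training epochs per phase.
#' @param learning_rate Adam step size for masked pretraining.
#' @param contrastive_learning_rate Adam step size for the contrastive phase;
#'   defaults to a third of `learning_rate` so refinement perturbs the
#'   pretrained co-occurrence structure gently.
#' @param seed seed controlling initialization, masking, segment splits and
#'   dropout; training is deterministic given it.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 2L, n_heads = 4L, hidden_dim = 64L,
                           dropout = 0.1, max_len = 256L,
                           mask_fraction = 0.15, temperature = 0.1,
                           batch_size = 64L, epochs = 5L,
                           contrastive_epochs = 3L,
                           learning_rate = 1e-3,
                           contrastive_learning_rate = learning_rate / 3,
                           seed = 1L) {
  if (mask_fraction <= 0 || mask_fraction >= 1)
    stopf("invalid config: mask_fraction must lie in (0, 1)")
  if (temperature <= 0) stopf("invalid config: temperature must be > 0")
  if (hidden_dim %% n_heads != 0)
    stopf("invalid config: hidden_dim must be divisible by n_heads")
  if (dropout < 0 || dropout >= 1) stopf("invalid config: dropout must be in [0, 1)")
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 hidden_dim = as.integer(hidden_dim), dropout = dropout,
                 max_len = as.integer(max_len), mask_fraction = mask_fraction,
                 temperature = temperature, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 contrastive_epochs = as.integer(contrastive_epochs),
                 learning_rate = learning_rate,
                 contrastive_learning_rate = contrastive_learning_rate,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

# embedding table sizes for the age / calendar-year / visit streams
AGE_BINS <- 121L    # integer ages 0..120
YEAR_BINS <- 71L    # calendar years 1990..2060, index year - 1990
VIS_BINS <- 512L

mat_init <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Initialize an encoder
#'
#' @param config an [encoder_config()].
#' @param vocab_size total token vocabulary size (codes + 5 specials).
#' @return object of class `ehr_encoder` holding parameters and the config.
#' @export
init_encoder <- function(config, vocab_size) {
  set.seed(config$seed)
  d <- config$hidden_dim
  xav <- function(nr, nc) mat_init(nr, nc, sqrt(2 / (nr + nc)))
  layers <- lapply(seq_len(config$n_layers), function(l) list(
    Wq = xav(d, d), bq = numeric(d),
    Wk = xav(d, d), bk = numeric(d),
    Wv = xav(d, d), bv = numeric(d),
    Wo = xav(d, d), bo = numeric(d),
    g1 = rep(1, d), be1 = numeric(d),
    W1 = xav(d, 4 * d), b1 = numeric(4 * d),
    W2 = xav(4 * d, d), b2 = numeric(d),
    g2 = rep(1, d), be2 = numeric(d)
  ))
  params <- list(
    emb = list(tok = mat_init(vocab_size, d, 0.02),
               age = mat_init(AGE_BINS, d, 0.02),
               year = mat_init(YEAR_BINS, d, 0.02),
               vis = mat_init(VIS_BINS, d, 0.02)),
    layers = layers,
    head = list(W = xav(d, vocab_size), b = numeric(vocab_size)),
    # linear projection used only by the contrastive objective; the patient
    # embeddings are taken from the encoder states before this projection
    proj = list(W = xav(d, d), b = numeric(d))
  )
  structure(list(params = params, config = config, vocab_size = vocab_size),
            class = "ehr_encoder")
}

#' @exportS3Method print ehr_encoder
print.ehr_encoder <- function(x, ...) {
  cat(sprintf("Transformer encoder: %d layers, %d heads, width %d, vocab %d\n",
              x$config$n_layers, x$config$n_heads, x$config$hidden_dim,
              x$vocab_size))
  invisible(x)
}

# ---- batching ---------------------------------------------------------------

# pack a list of token_sequence into concatenated index vectors
pack_batch <- function(sequences) {
  lens <- vapply(sequences, function(s) length(s$tokens), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  rows <- mapply(function(a, b) a:b, starts, ends, SIMPLIFY = FALSE)
  list(
    tok = unlist(lapply(sequences, `[[`, "tokens"), use.names = FALSE),
    age = unlist(lapply(sequences, `[[`, "ages"), use.names = FALSE),
    year = unlist(lapply(sequences, `[[`, "years"), use.names = FALSE),
    vis = unlist(lapply(sequences, `[[`, "visit_index"), use.names = FALSE),
    rows = rows, lens = lens, n = length(sequences)
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ---- forward ---------------------------------------------------------------

layer_norm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  list(Y = sweep(xhat * 1, 2, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(cache, dY, g) {
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

addb <- function(X, b) X + rep(b, each = nrow(X))

attn_fwd <- function(Q, K, V, rows, n_heads) {
  d <- ncol(Q); dk <- d %/% n_heads
  H <- matrix(0, nrow(Q), d)
  A_list <- vector("list", length(rows) * n_heads)
  sc <- 1 / sqrt(dk)
  for (s in seq_along(rows)) {
    r <- rows[[s]]
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(Q[r, cols, drop = FALSE], K[r, cols, drop = FALSE]) * sc
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      A <- E / rowSums(E)
      H[r, cols] <- A %*% V[r, cols, drop = FALSE]
      A_list[[(s - 1L) * n_heads + h]] <- A
    }
  }
  list(H = H, A = A_list)
}

attn_bwd <- function(dH, Q, K, V, A_list, rows, n_heads) {
  d <- ncol(Q); dk <- d %/% n_heads
  dQ <- matrix(0, nrow(Q), d); dK <- dQ; dV <- dQ
  sc <- 1 / sqrt(dk)
  for (s in seq_along(rows)) {
    r <- rows[[s]]
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- A_list[[(s - 1L) * n_heads + h]]
      dHs <- dH[r, cols, drop = FALSE]
      Vs <- V[r, cols, drop = FALSE]
      dA <- tcrossprod(dHs, Vs)
      dV[r, cols] <- crossprod(A, dHs)
      dS <- A * (dA - rowSums(dA * A))
      dQ[r, cols] <- (dS %*% K[r, cols, drop = FALSE]) * sc
      dK[r, cols] <- crossprod(dS, Q[r, cols, drop = FALSE]) * sc
    }
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

# forward pass; returns first- and final-layer hidden states plus caches
enc_forward <- function(enc, bt, train = FALSE) {
  p <- enc$params; cfg <- enc$config
  idx <- list(tok = bt$tok + 1L,
              age = clamp(bt$age, 0L, AGE_BINS - 1L) + 1L,
              year = clamp(bt$year - 1990L, 0L, YEAR_BINS - 1L) + 1L,
              vis = clamp(bt$vis, 1L, VIS_BINS))
  X <- p$emb$tok[idx$tok, , drop = FALSE] + p$emb$age[idx$age, , drop = FALSE] +
    p$emb$year[idx$year, , drop = FALSE] + p$emb$vis[idx$vis, , drop = FALSE]
  caches <- vector("list", cfg$n_layers)
  Hs <- vector("list", cfg$n_layers)
  keep <- 1 - cfg$dropout
  for (l in seq_len(cfg$n_layers)) {
    lp <- p$layers[[l]]
    Q <- addb(X %*% lp$Wq, lp$bq)
    K <- addb(X %*% lp$Wk, lp$bk)
    V <- addb(X %*% lp$Wv, lp$bv)
    at <- attn_fwd(Q, K, V, bt$rows, cfg$n_heads)
    O <- addb(at$H %*% lp$Wo, lp$bo)
    m_attn <- NULL
    if (train && cfg$dropout > 0) {
      m_attn <- matrix((stats::runif(length(O)) < keep) / keep, nrow(O))
      O <- O * m_attn
    }
    ln1 <- layer_norm_fwd(X + O, lp$g1, lp$be1)
    Z1 <- addb(ln1$Y %*% lp$W1, lp$b1)
    F1 <- pmax(Z1, 0)
    F2 <- addb(F1 %*% lp$W2, lp$b2)
    m_ffn <- NULL
    if (train && cfg$dropout > 0) {
      m_ffn <- matrix((stats::runif(length(F2)) < keep) / keep, nrow(F2))
      F2 <- F2 * m_ffn
    }
    ln2 <- layer_norm_fwd(ln1$Y + F2, lp$g2, lp$be2)
    caches[[l]] <- list(X = X, Q = Q, K = K, V = V, at = at, H = at$H,
                        ln1 = ln1, Z1 = Z1, F1 = F1, ln2 = ln2,
                        m_attn = m_attn, m_ffn = m_ffn)
    X <- ln2$Y
    Hs[[l]] <- X
  }
  list(H_first = Hs[[1L]], H_final = X, caches = caches, idx = idx, bt = bt)
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

# backward pass from an upstream gradient on the final hidden states
enc_backward <- function(enc, fw, dH_final) {
  p <- enc$params; cfg <- enc$config
  g <- list(emb = zero_like(p$emb), layers = vector("list", cfg$n_layers))
  dX <- dH_final
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- p$layers[[l]]; ca <- fw$caches[[l]]
    lb2 <- layer_norm_bwd(ca$ln2, dX, lp$g2)
    dR2 <- lb2$dX
    dF2 <- if (!is.null(ca$m_ffn)) dR2 * ca$m_ffn else dR2
    dF1 <- dF2 %*% t(lp$W2)
    dW2 <- crossprod(ca$F1, dF2); db2 <- colSums(dF2)
    dZ1 <- dF1 * (ca$Z1 > 0)
    dY1 <- dZ1 %*% t(lp$W1) + dR2
    dW1 <- crossprod(ca$ln1$Y, dZ1); db1 <- colSums(dZ1)
    lb1 <- layer_norm_bwd(ca$ln1, dY1, lp$g1)
    dR1 <- lb1$dX
    dO <- if (!is.null(ca$m_attn)) dR1 * ca$m_attn else dR1
    dH <- dO %*% t(lp$Wo)
    dWo <- crossprod(ca$H, dO); dbo <- colSums(dO)
    ab <- attn_bwd(dH, ca$Q, ca$K, ca$V, ca$at$A, fw$bt$rows, cfg$n_heads)
    dXl <- dR1 +
      ab$dQ %*% t(lp$Wq) + ab$dK %*% t(lp$Wk) + ab$dV %*% t(lp$Wv)
    g$layers[[l]] <- list(
      Wq = crossprod(ca$X, ab$dQ), bq = colSums(ab$dQ),
      Wk = crossprod(ca$X, ab$dK), bk = colSums(ab$dK),
      Wv = crossprod(ca$X, ab$dV), bv = colSums(ab$dV),
      Wo = dWo, bo = dbo,
      g1 = lb1$dg, be1 = lb1$db,
      W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
      g2 = lb2$dg, be2 = lb2$db
    )
    dX <- dXl
  }
  d <- cfg$hidden_dim
  g$emb$tok <- accumulate_rows(dX, fw$idx$tok, nrow(p$emb$tok))
  g$emb$age <- accumulate_rows(dX, fw$idx$age, nrow(p$emb$age))
  g$emb$year <- accumulate_rows(dX, fw$idx$year, nrow(p$emb$year))
  g$emb$vis <- accumulate_rows(dX, fw$idx$vis, nrow(p$emb$vis))
  g
}

accumulate_rows <- function(dX, idx, n_rows) {
  out <- matrix(0, n_rows, ncol(dX))
  agg <- rowsum(dX, idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# ---- Adam ------------------------------------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

adam_init <- function(params) list(m = zero_like(params), v = zero_like(params), t = 0L)

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
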