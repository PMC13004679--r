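n_code_tokens <- function(s) sum(s$tokens >= 5L)

# positions of code tokens to mask: independent Bernoulli(fraction) draws,
# forced to at least one position per sequence
sample_mask_positions <- function(tokens, fraction) {
  code_pos <- which(tokens >= 5L)
  m <- code_pos[stats::runif(length(code_pos)) < fraction]
  if (!length(m)) m <- code_pos[sample.int(length(code_pos), 1L)]
  m
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Pretrain an encoder with the masked-encounter objective
#'
#' Per epoch, each code token (id >= 5) is independently masked with
#' probability `config$mask_fraction` (at least one per sequence) and replaced
#' by the MASK token; cross-entropy against the original code id is computed
#' at masked positions only. Sequences with fewer than two code tokens are
#' skipped (counted in `n_skipped`). Training is deterministic given
#' `config$seed`.
#'
#' @param sequences list of [encode_patient()] token sequences.
#' @param config an [encoder_config()].
#' @param vocab the `ehr_vocab` the sequences were encoded with.
#' @param encoder optionally, an already-initialized `ehr_encoder` to continue
#'   training.
#' @return list with the trained `encoder`, numeric `loss_history` (mean
#'   masked cross-entropy per epoch) and `n_skipped`.
#' @export
pretrain_masked <- function(sequences, config, vocab, encoder = NULL) {
  usable <- vapply(sequences, n_code_tokens, integer(1)) >= 2L
  n_skipped <- sum(!usable)
  sequences <- sequences[usable]
  if (length(sequences) < 2L) stopf("need at least 2 usable sequences")
  if (is.null(encoder)) encoder <- init_encoder(config, vocab$size)
  opt <- adam_init(encoder$params)
  mask_id <- vocab$specials[["MASK"]]
  losses <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    set.seed(config$seed + 1000L * ep)
    ord <- sample.int(length(sequences))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tot_loss <- 0; tot_m <- 0L
    for (b in batches) {
      seqs <- sequences[b]
      masked <- lapply(seqs, function(s) {
        m <- sample_mask_positions(s$tokens, config$mask_fraction)
        s$mask_pos <- m
        s$targets <- s$tokens[m]
        s$tokens[m] <- mask_id
        s
      })
      bt <- pack_batch(masked)
      starts <- cumsum(c(0L, bt$lens[-length(bt$lens)]))
      gpos <- unlist(mapply(function(s, off) s$mask_pos + off, masked, starts,
                            SIMPLIFY = FALSE), use.names = FALSE)
      targets <- unlist(lapply(masked, `[[`, "targets"), use.names = FALSE)

      fw <- enc_forward(encoder, bt, train = TRUE)
      Hm <- fw$H_final[gpos, , drop = FALSE]
      logits <- addb(Hm %*% encoder$params$head$W, encoder$params$head$b)
      P <- softmax_rows(logits)
      M <- length(targets)
      picks <- cbind(seq_len(M), targets + 1L)
      loss <- -mean(log(pmax(P[picks], 1e-12)))
      dlogits <- P
      dlogits[picks] <- dlogits[picks] - 1
      dlogits <- dlogits / M

      dH <- matrix(0, nrow(fw$H_final), ncol(fw$H_final))
      dH[gpos, ] <- dlogits %*% t(encoder$params$head$W)
      grads <- enc_backward(encoder, fw, dH)
      grads$head <- list(W = crossprod(Hm, dlogits), b = colSums(dlogits))
      grads$proj <- zero_like(encoder$params$proj)

      st <- adam_step(encoder$params, grads, opt, config$learning_rate)
      encoder$params <- st$params; opt <- st$state
      tot_loss <- tot_loss + loss * M; tot_m <- tot_m + M
    }
    losses[ep] <- tot_loss / tot_m
  }
  list(encoder = encoder, loss_history = losses, n_skipped = n_skipped)
}

# split a token sequence into two temporally contiguous segments, each with
# at least two code tokens; the split point is sampled uniformly
split_segments <- function(s) {
  body_idx <- seq_along(s$tokens)[-1L]
  code_pos <- body_idx[s$tokens[body_idx] >= 5L]
  nc <- length(code_pos)
  cuts <- 2:(nc - 2L) # codes 1..cut left, rest right
  cut_code <- cuts[sample.int(length(cuts), 1L)]
  cut_pos <- code_pos[cut_code]
  slice <- function(keep) {
    structure(list(tokens = c(s$tokens[1L], s$tokens[keep]),
                   ages = c(s$ages[keep][1L], s$ages[keep]),
                   years = c(s$years[keep][1L], s$years[keep]),
                   visit_index = c(s$visit_index[keep][1L], s$visit_index[keep]),
                   patient_id = s$patient_id), class = "token_sequence")
  }
  list(slice(body_idx[body_idx <= cut_pos]),
       slice(body_idx[body_idx > cut_pos]))
}

#' Refine an encoder with the contrastive segment objective
#'
#' For each patient a split point is sampled per epoch; the two temporally
#' contiguous segments of the prediagnostic sequence form a positive pair and
#' every other in-batch segment is a negative. Segment representations are
#' mean-pooled final-layer states, L2-normalized; the loss is the normalized-
#' temperature cross-entropy (NT-Xent) on cosine similarities.
#'
#' @param encoder a (pre-trained) `ehr_encoder`.
#' @inheritParams pretrain_masked
#' @return list with the refined `encoder` and `loss_history` (one mean loss
#'   per epoch).
#' @export
contrastive_refine <- function(encoder, sequences, config = encoder$config) {
  usable <- vapply(sequences, n_code_tokens, integer(1)) >= 4L
  sequences <- sequences[usable]
  if (length(sequences) < 2L)
    stopf("contrastive refinement needs >= 2 patients with >= 4 code tokens")
  opt <- adam_init(encoder$params)
  tau <- config$temperature
  losses <- numeric(config$contrastive_epochs)

  for (ep in seq_len(config$contrastive_epochs)) {
    set.seed(config$seed + 2000L * ep)
    ord <- sample.int(length(sequences))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    # a 1-patient batch has no negatives: merge it into the previous batch
    nb <- length(batches)
    if (nb > 1L && length(batches[[nb]]) < 2L) {
      batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
      batches[[nb]] <- NULL
    }
    ep_loss <- 0; ep_n <- 0L
    for (b in batches) {
      if (length(b) < 2L) stopf("contrastive batch needs >= 2 patients")
      segs <- unlist(lapply(sequences[b], split_segments), recursive = FALSE)
      bt <- pack_batch(segs)
      fw <- enc_forward(encoder, bt, train = TRUE)
      Up <- rowsum(fw$H_final, rep.int(seq_along(segs), bt$lens)) / bt$lens
      # linear projection head: the contrastive loss acts on the projected
      # space so that uniformity pressure does not flatten the encoder states
      U <- addb(Up %*% encoder$params$proj$W, encoder$params$proj$b)
      nrm <- sqrt(rowSums(U^2)) + 1e-12
      Z <- U / nrm
      n2 <- nrow(Z)
      S <- tcrossprod(Z) / tau
      diag(S) <- -Inf
      P <- softmax_rows(S)
      pos <- ifelse(seq_len(n2) %% 2L == 1L, seq_len(n2) + 1L, seq_len(n2) - 1L)
      loss <- -mean(log(pmax(P[cbind(seq_len(n2), pos)], 1e-12)))
      dS <- P
      dS[cbind(seq_len(n2), pos)] <- dS[cbind(seq_len(n2), pos)] - 1
      dS <- dS / n2
      dZ <- ((dS + t(dS)) %*% Z) / tau
      dU <- (dZ - Z * rowSums(Z * dZ)) / nrm
      dUp <- dU %*% t(encoder$params$proj$W)
      dH <- dUp[rep.int(seq_along(segs), bt$lens), , drop = FALSE] / bt$lens[rep.int(seq_along(segs), bt$lens)]
      grads <- enc_backward(encoder, fw, dH)
      grads$head <- zero_like(encoder$params$head)
      grads$proj <- list(W = crossprod(Up, dU), b = colSums(dU))
      st <- adam_step(encoder$params, grads, opt,
                      config$contrastive_learning_rate %||% config$learning_rate)
      encoder$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + loss * n2; ep_n <- ep_n + n2
    }
    losses[ep] <- ep_loss / ep_n
  }
  list(encoder = encoder, loss_history = losses)
}

#' Embed patients with a trained encoder
#'
#' The patient representation is the concatenation of the mean (over
#' positions) of the first-layer hidden states and the mean of the final-layer
#' hidden states, giving a `2 * hidden_dim` vector per patient. Inference is
#' deterministic (no dropout).
#'
#' @param encoder an `ehr_encoder`.
#' @param sequences list of token sequences.
#' @param batch_size sequences per forward pass.
#' @return numeric matrix `n_patients x 2*hidden_dim` with patient ids as row
#'   names.
#' @export
embed_patients <- function(encoder, sequences, batch_size = 64L) {
  if (!length(sequences)) stopf("no sequences to embed")
  out <- matrix(NA_real_, length(sequences), 2L * encoder$config$hidden_dim)
  batches <- split(seq_along(sequences), ceiling(seq_along(sequences) / batch_size))
  for (b in batches) {
    bt <- pack_batch(sequences[b])
    fw <- enc_forward(encoder, bt, train = FALSE)
    sid <- rep.int(seq_along(b), bt$lens)
    M1 <- rowsum(fw$H_first, sid) / bt$lens
    M2 <- rowsum(fw$H_final, sid) / bt$lens
    out[b, ] <- cbind(M1, M2)
  }
  if (any(!is.finite(out))) stopf("non-finite values in embedding matrix")
  rownames(out) <- vapply(sequences, function(s) as.character(s$patient_id), "")
  out
}

#' Standardize an embedding matrix column-wise
#'
#' Columns are centered and scaled to unit standard deviation; zero-variance
#' columns are set to 0. Idempotent up to floating-point error.
#'
#' @param X numeric matrix (patients x dimensions).
#' @return matrix of the same shape and row names.
#' @export
standardize_embeddings <- function(X) {
  if (nrow(X) < 2L) stopf("need at least 2 rows to standardize")
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  Xc <- sweep(X, 2L, mu)
  keep <- sd > 0
  Xc[, keep] <- sweep(Xc[, keep, drop = FALSE], 2L, sd[keep], "/")
  Xc[, !keep] <- 0
  Xc
}
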