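#' Fit the full subtyping model on a cohort
#'
#' End-to-end fit: builds the code vocabulary, tokenizes every patient's
#' prediagnostic record by visit, age and calendar year, pretrains the
#' transformer encoder with the masked-encounter objective, refines it with
#' the contrastive segment objective, embeds patients (first + final layer
#' mean pooling), standardizes the embedding columns, and selects the number
#' of subtypes by prediction strength over `k_range` with the full stability
#' report.
#'
#' The default encoder is deliberately desk-scale (2 layers, width 32,
#' sequences truncated to 48 tokens) so that a few-thousand-patient cohort
#' fits in about a minute on one CPU. Default training length is set by
#' total sequence presentations (about 6,000 masked and 2,000 contrastive,
#' minimum 3 + 1 epochs), so smaller cohorts train for more epochs; pass a
#' custom [encoder_config()] to override.
#'
#' @param cohort an `ehr_cohort` (the derivation set).
#' @param encoder an [encoder_config()].
#' @param k_range candidate numbers of clusters.
#' @param threshold prediction-strength selection threshold.
#' @param seed master seed for every stage.
#' @param n_repeats,n_init,B_bootstrap,B_consensus clustering-pipeline
#'   settings (see [select_k()]).
#' @param min_count vocabulary frequency cutoff.
#' @return object of class `ehr_subtype`: vocabulary, trained encoder, loss
#'   histories, standardized `embeddings`, scaling parameters, fitted
#'   `model` (class `cluster_model`), `report` (class `selection_report`),
#'   per-patient `labels` and `confidence`.
#' @export
ehr_subtype <- function(cohort,
                        encoder = encoder_config(hidden_dim = 32L,
                                                 max_len = 48L,
                                                 epochs = max(3L, as.integer(
                                                   ceiling(6000 / nrow(cohort$patients)))),
                                                 contrastive_epochs = max(1L, as.integer(
                                                   ceiling(2000 / nrow(cohort$patients)))),
                                                 learning_rate = 3e-3,
                                                 seed = seed),
                        k_range = 3:8, threshold = 0.95, seed = 1L,
                        n_repeats = 5L, n_init = 10L,
                        B_bootstrap = 20L, B_consensus = 50L,
                        min_count = 1L) {
  t0 <- proc.time()[["elapsed"]]
  vocab <- build_vocabulary(cohort, min_count = min_count)
  seqs <- encode_cohort(cohort, vocab, max_len = encoder$max_len)
  pre <- pretrain_masked(seqs, encoder, vocab)
  ref <- contrastive_refine(pre$encoder, seqs, encoder)
  E <- embed_patients(ref$encoder, seqs, batch_size = encoder$batch_size)
  mu <- colMeans(E)
  sdv <- apply(E, 2L, stats::sd)
  X <- standardize_embeddings(E)
  sel <- select_k(X, k_range = k_range, threshold = threshold, seed = seed,
                  n_repeats = n_repeats, n_init = n_init,
                  B_bootstrap = B_bootstrap, B_consensus = B_consensus)
  structure(list(
    vocab = vocab, encoder = ref$encoder,
    masked_loss = pre$loss_history, contrastive_loss = ref$loss_history,
    embeddings = X, scale_center = mu, scale_sd = sdv,
    model = sel$model, report = sel$report,
    chosen_k = sel$chosen_k, labels = sel$model$assignments,
    confidence = sel$confidence,
    patient_ids = cohort$patients$patient_id,
    k_range = k_range, threshold = threshold, seed = seed,
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "ehr_subtype")
}

#' @exportS3Method print ehr_subtype
print.ehr_subtype <- function(x, ...) {
  cat(sprintf("EHR subtyping fit: %d patients, chosen K = %d%s\n",
              length(x$labels), x$chosen_k,
              if (x$report$fallback_used) " (fallback: argmax PS)" else ""))
  cat(sprintf("  cluster sizes: %s\n",
              paste(tabulate(x$labels, x$chosen_k), collapse = ", ")))
  cat(sprintf("  masked-loss %.3f -> %.3f | contrastive-loss %.3f -> %.3f\n",
              x$masked_loss[1L], x$masked_loss[length(x$masked_loss)],
              x$contrastive_loss[1L], x$contrastive_loss[length(x$contrastive_loss)]))
  invisible(x)
}

#' @exportS3Method summary ehr_subtype
summary.ehr_subtype <- function(object, ...) {
  print(object)
  print(object$report)
  invisible(object)
}

#' Assign new patients to fitted subtypes
#'
#' Encodes the new cohort with the training vocabulary, embeds with the
#' trained encoder, applies the training standardization and labels each
#' patient by the nearest centroid.
#'
#' @param object an `ehr_subtype` fit.
#' @param newdata an `ehr_cohort`.
#' @param ... unused.
#' @return integer subtype labels (1..K) named by patient id.
#' @export
predict.ehr_subtype <- function(object, newdata, ...) {
  seqs <- encode_cohort(newdata, object$vocab,
                        max_len = object$encoder$config$max_len)
  E <- embed_patients(object$encoder, seqs)
  X <- sweep(E, 2L, object$scale_center)
  keep <- object$scale_sd > 0
  X[, keep] <- sweep(X[, keep, drop = FALSE], 2L, object$scale_sd[keep], "/")
  X[, !keep] <- 0
  lab <- assign_clusters(object$model, X)
  stats::setNames(lab, rownames(E))
}

#' @export
plot.ehr_subtype <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ps <- x$report$ps_by_k
  graphics::plot(as.integer(names(ps)), ps, type = "b", pch = 19,
                 xlab = "K", ylab = "prediction strength",
                 ylim = c(0, 1), main = "K selection")
  graphics::abline(h = x$threshold, lty = 2)
  graphics::points(x$chosen_k, ps[as.character(x$chosen_k)], col = 2, cex = 1.6)
  graphics::boxplot(split(x$confidence, x$labels),
                    xlab = "cluster", ylab = "confidence",
                    main = "assignment confidence")
  invisible(x)
}
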