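#' Prediction strength of a K-means clustering
#'
#' Cross-split reproducibility of a K-cluster solution: the data are split
#' 50/50 into train and test halves, K-means is fitted on each, test points
#' are additionally classified by the nearest train centroid, and for every
#' test cluster (with >= 2 members) the proportion of its within-cluster
#' pairs that are co-assigned by the train centroids is computed. The
#' prediction strength of one split is the minimum of these proportions over
#' test clusters; the returned value is the mean over `n_repeats` random
#' splits. `PS(K = 1)` is 1 by definition.
#'
#' @param X numeric matrix.
#' @param K number of clusters.
#' @param n_repeats number of random 50/50 splits.
#' @param seed RNG seed.
#' @param n_init restarts for the internal K-means fits.
#' @return mean prediction strength in `[0, 1]`.
#' @export
prediction_strength <- function(X, K, n_repeats = 5L, seed = 1L, n_init = 10L) {
  X <- as.matrix(X)
  if (K == 1L) return(1)
  n <- nrow(X)
  if (n < 2L * K + 4L) stopf("prediction_strength: need n >= 2K + 4")
  set.seed(seed)
  ps <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    for (try in seq_len(5L)) {
      idx <- sample.int(n, floor(n / 2))
      sub_seed <- seed + 97L * r + 13L * try
      fit_tr <- kmeans_fit(X[idx, , drop = FALSE], K, seed = sub_seed, n_init = n_init)
      fit_te <- kmeans_fit(X[-idx, , drop = FALSE], K, seed = sub_seed + 1L, n_init = n_init)
      if (all(tabulate(fit_tr$assignments, K) > 0) &&
          all(tabulate(fit_te$assignments, K) > 0)) break
      if (try == 5L) stopf("prediction_strength: empty cluster after 5 retries")
    }
    test_lab <- fit_te$assignments
    cross_lab <- assign_clusters(fit_tr, X[-idx, , drop = FALSE])
    ps[r] <- ps_pair_agreement(test_lab, cross_lab, K)
  }
  mean(ps)
}

# minimum over test clusters (>= 2 members) of the share of within-cluster
# pairs co-assigned by the cross labels
ps_pair_agreement <- function(test_lab, cross_lab, K) {
  props <- vapply(seq_len(K), function(j) {
    m <- which(test_lab == j)
    nj <- length(m)
    if (nj < 2L) return(NA_real_)
    cnt <- tabulate(cross_lab[m], K)
    sum(cnt * (cnt - 1) / 2) / (nj * (nj - 1) / 2)
  }, numeric(1))
  min(props, na.rm = TRUE)
}

#' Select the number of clusters by prediction strength
#'
#' Scans `k_range`, computes the mean prediction strength for each K, and
#' chooses the largest K whose prediction strength meets `threshold` (the
#' prespecified primary criterion). If no K qualifies the argmax of
#' prediction strength is returned with `fallback_used = TRUE` and a warning.
#' The final model is refitted at the chosen K and the report is populated
#' with silhouette, Davies-Bouldin, bootstrap ARI, consensus PAC and
#' per-cluster confidence summaries.
#'
#' @param X numeric matrix of (standardized) patient embeddings.
#' @param k_range candidate cluster numbers.
#' @param threshold prediction-strength acceptance threshold.
#' @param seed RNG seed.
#' @param n_repeats splits per prediction-strength estimate.
#' @param n_init K-means restarts.
#' @param B_bootstrap,B_consensus replicates for the stability metrics (set
#'   to 0 to skip).
#' @return list with `chosen_k`, the fitted `model` (class `cluster_model`)
#'   and `report` (class `selection_report`): `ps_by_k`, `fallback_used`,
#'   `silhouette`, `davies_bouldin`, `bootstrap_ari`, `pac`,
#'   `confidence_summary`.
#' @export
select_k <- function(X, k_range = 3:8, threshold = 0.95, seed = 1L,
                     n_repeats = 5L, n_init = 10L,
                     B_bootstrap = 20L, B_consensus = 50L) {
  if (!length(k_range)) stopf("select_k: empty k_range")
  X <- as.matrix(X)
  ps <- vapply(k_range, function(K)
    prediction_strength(X, K, n_repeats = n_repeats, seed = seed + K,
                        n_init = n_init), numeric(1))
  names(ps) <- k_range
  ok <- which(ps >= threshold)
  if (length(ok)) {
    chosen <- max(k_range[ok]); fallback <- FALSE
  } else {
    chosen <- k_range[which.max(ps)]; fallback <- TRUE
    warnf("no K in [%d, %d] reached prediction strength %.2f; falling back to argmax (K = %d)",
          min(k_range), max(k_range), threshold, chosen)
  }
  model <- kmeans_fit(X, chosen, seed = seed, n_init = n_init)
  conf <- confidence_scores(model, X)
  report <- list(
    ps_by_k = ps,
    chosen_k = chosen,
    fallback_used = fallback,
    threshold = threshold,
    silhouette = if (chosen >= 2L) silhouette_score(X, model$assignments) else NA_real_,
    davies_bouldin = if (chosen >= 2L) davies_bouldin(X, model$assignments) else NA_real_,
    bootstrap_ari = if (B_bootstrap > 0L)
      bootstrap_ari(X, model, B = B_bootstrap, seed = seed + 1L, n_init = n_init)
      else NA_real_,
    pac = if (B_consensus > 0L)
      consensus_pac(X, chosen, B = B_consensus, seed = seed + 2L, n_init = n_init)
      else NA_real_,
    confidence_summary = conf$summary
  )
  class(report) <- "selection_report"
  list(chosen_k = chosen, model = model, report = report,
       confidence = conf$scores)
}

#' @exportS3Method print selection_report
print.selection_report <- function(x, ...) {
  cat("Cluster-number selection by prediction strength\n")
  cat(sprintf("  PS by K: %s\n",
              paste(sprintf("%s=%.3f", names(x$ps_by_k), x$ps_by_k), collapse = "  ")))
  cat(sprintf("  chosen K = %d%s (threshold %.2f)\n", x$chosen_k,
              if (x$fallback_used) " [fallback: argmax PS]" else "", x$threshold))
  cat(sprintf("  silhouette %.3f | Davies-Bouldin %.3f | bootstrap ARI %.3f | PAC %.3f\n",
              x$silhouette, x$davies_bouldin, x$bootstrap_ari, x$pac))
  invisible(x)
}

#' Mean silhouette score
#'
#' Standard silhouette over Euclidean distances; requires `2 <= K < n`.
#' @param X numeric matrix; `labels` integer cluster labels.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(X, labels) {
  X <- as.matrix(X)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stopf("silhouette requires at least 2 clusters")
  if (length(ks) >= nrow(X)) stopf("silhouette requires K < n")
  n <- nrow(X)
  # mean distance from every point to every cluster
  D <- sqrt(rowdist2(X, X))
  sizes <- tabulate(match(labels, ks), length(ks))
  sums <- t(rowsum(t(D), match(labels, ks)))  # n x K: sum of distances to each cluster
  s <- numeric(n)
  for (i in seq_len(n)) {
    ki <- match(labels[i], ks)
    if (sizes[ki] == 1L) { s[i] <- 0; next }
    a <- sums[i, ki] / (sizes[ki] - 1L)
    b <- min(sums[i, -ki] / sizes[-ki])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-pair ratio `(s_i + s_j) / d_ij`, where
#' `s_i` is the mean distance of cluster members to their centroid and
#' `d_ij` the distance between centroids. 0 for zero-scatter clusters;
#' scale-invariant.
#'
#' @inheritParams silhouette_score
#' @return nonnegative index.
#' @export
davies_bouldin <- function(X, labels) {
  X <- as.matrix(X)
  ks <- sort(unique(labels))
  K <- length(ks)
  if (K < 2L) stopf("Davies-Bouldin requires at least 2 clusters")
  cent <- do.call(rbind, lapply(ks, function(k)
    colMeans(X[labels == k, , drop = FALSE])))
  scat <- vapply(seq_len(K), function(j) {
    M <- X[labels == ks[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(M, 2L, cent[j, ])^2)))
  }, numeric(1))
  Dc <- sqrt(rowdist2(cent, cent))
  mean(vapply(seq_len(K), function(i)
    max(vapply(seq_len(K)[-i], function(j) (scat[i] + scat[j]) / Dc[i, j],
               numeric(1))), numeric(1)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement from the contingency table;
#' 1 for identical partitions up to relabeling.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("adjusted_rand: label vectors differ in length")
  n <- length(labels_a)
  if (n < 2L) stopf("adjusted_rand: need at least 2 observations")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Bootstrap stability of a clustering (mean ARI)
#'
#' Per replicate, rows are resampled with replacement, K-means is refitted at
#' the model's K, and the ARI between the refit labels and the reference
#' labels is computed on the unique resampled rows.
#'
#' @param X data the model was fitted on.
#' @param model a `cluster_model`.
#' @param B number of bootstrap replicates (> 0).
#' @param seed RNG seed.
#' @param n_init K-means restarts per refit.
#' @return mean ARI over replicates.
#' @export
bootstrap_ari <- function(X, model, B = 50L, seed = 1L, n_init = 10L) {
  if (B <= 0L) stopf("bootstrap_ari: B must be > 0")
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  boots <- lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
  aris <- vapply(seq_len(B), function(b) {
    idx <- boots[[b]]
    fit <- kmeans_fit(X[idx, , drop = FALSE], model$K, seed = seed + b,
                      n_init = n_init)
    u <- !duplicated(idx)
    ref <- model$assignments[idx[u]]
    adjusted_rand(fit$assignments[u], ref)
  }, numeric(1))
  mean(aris)
}

#' Consensus-clustering proportion of ambiguous clustering (PAC)
#'
#' Over `B` rounds, a fraction `subsample` of rows is drawn without
#' replacement and K-means refitted; the consensus matrix holds the
#' co-clustering frequency of each pair among the rounds in which both were
#' sampled. PAC is the fraction of off-diagonal consensus entries strictly
#' inside `(u1, u2)` — near 0 for stable clusterings, large when assignments
#' are ambiguous.
#'
#' @param X numeric matrix.
#' @param K number of clusters.
#' @param B subsample-refit rounds.
#' @param subsample fraction of rows per round.
#' @param u1,u2 ambiguity thresholds, `u1 < u2`.
#' @param seed RNG seed.
#' @param n_init K-means restarts per refit.
#' @return PAC in `[0, 1]`.
#' @export
consensus_pac <- function(X, K, B = 100L, subsample = 0.8, u1 = 0.1, u2 = 0.9,
                          seed = 1L, n_init = 10L) {
  if (u1 >= u2) stopf("consensus_pac: need u1 < u2")
  X <- as.matrix(X)
  n <- nrow(X)
  m <- floor(n * subsample)
  if (m < K) stopf("consensus_pac: subsample too small for K")
  set.seed(seed)
  co <- matrix(0, n, n)
  both <- matrix(0, n, n)
  for (b in seq_len(B)) {
    idx <- sample.int(n, m)
    fit <- kmeans_fit(X[idx, , drop = FALSE], K, seed = seed + b, n_init = n_init)
    same <- outer(fit$assignments, fit$assignments, "==")
    co[idx, idx] <- co[idx, idx] + same
    both[idx, idx] <- both[idx, idx] + 1
  }
  off <- upper.tri(co) & both > 0
  cons <- co[off] / both[off]
  mean(cons > u1 & cons < u2)
}

#' Cross-source generalizability ARI
#'
#' K-means is fitted independently on source A and source B; B's points are
#' labeled twice — by B's own model and by the nearest A centroid — and the
#' ARI between the two labelings of B is returned.
#'
#' @param X_a,X_b embedding matrices with equal column dimension.
#' @param K number of clusters.
#' @param seed RNG seed.
#' @param n_init K-means restarts.
#' @return ARI in `[-1, 1]`.
#' @export
cross_source_ari <- function(X_a, X_b, K, seed = 1L, n_init = 10L) {
  X_a <- as.matrix(X_a); X_b <- as.matrix(X_b)
  if (ncol(X_a) != ncol(X_b))
    stopf("cross_source_ari: embedding dimensions differ (%d vs %d)",
          ncol(X_a), ncol(X_b))
  fit_a <- kmeans_fit(X_a, K, seed = seed, n_init = n_init)
  fit_b <- kmeans_fit(X_b, K, seed = seed, n_init = n_init)
  adjusted_rand(fit_b$assignments, assign_clusters(fit_a, X_b))
}
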