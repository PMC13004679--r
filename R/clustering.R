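kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (k in seq_len(K)[-1L]) {
    if (all(d2 == 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[k, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[k, ])^2))
  }
  centers
}

#' Fit K-means with k-means++ initialization
#'
#' Runs `n_init` restarts of Lloyd's algorithm (via [stats::kmeans()]) from
#' k-means++ seeds and keeps the solution with the lowest total
#' within-cluster sum of squares. Assignments are recomputed as exact
#' nearest-centroid labels with ties broken by the lowest cluster index, so
#' the fitted model satisfies the nearest-centroid invariant.
#'
#' @param X numeric matrix (observations x dimensions).
#' @param K number of clusters (`n >= K`).
#' @param seed RNG seed.
#' @param n_init number of random restarts.
#' @param max_iter,tol Lloyd iteration cap and centroid-shift tolerance.
#' @return object of class `cluster_model`: list with `K`, `centroids`,
#'   `assignments` (1..K), `inertia`, `seed`.
#' @export
kmeans_fit <- function(X, K, seed = 1L, n_init = 10L, max_iter = 300L,
                       tol = 1e-6) {
  X <- as.matrix(X)
  if (nrow(X) < K) stopf("kmeans_fit: n (%d) < K (%d)", nrow(X), K)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    init <- kmeanspp_init(X, K)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = init, iter.max = max_iter,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stopf("kmeans_fit: all %d initializations failed", n_init)
  centroids <- unname(best$centers)
  lab <- nearest_row(X, centroids)
  # guard: nearest-centroid relabeling must keep every cluster non-empty
  if (length(unique(lab)) < K) lab <- best$cluster
  d2 <- rowdist2(X, centroids)
  inertia <- sum(d2[cbind(seq_len(nrow(X)), lab)])
  structure(list(K = as.integer(K), centroids = centroids,
                 assignments = as.integer(lab), inertia = inertia,
                 seed = as.integer(seed)),
            class = "cluster_model")
}

#' @exportS3Method print cluster_model
print.cluster_model <- function(x, ...) {
  cat(sprintf("K-means model: K = %d, inertia = %.4g, cluster sizes: %s\n",
              x$K, x$inertia, paste(tabulate(x$assignments, x$K), collapse = ", ")))
  invisible(x)
}

#' Assign new observations to the nearest centroid
#'
#' Ties are broken by the lowest cluster index.
#' @param model a `cluster_model`.
#' @param X_new matrix with the same number of columns as the centroids.
#' @return integer labels in 1..K.
#' @export
assign_clusters <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(model$centroids))
    stopf("dimension mismatch: %d columns vs %d centroid dimensions",
          ncol(X_new), ncol(model$centroids))
  nearest_row(X_new, model$centroids)
}

#' Distance-based assignment confidence scores
#'
#' Each patient's score is 1 minus their Euclidean distance to the assigned
#' centroid, normalized by the maximum such distance over the dataset:
#' a point on its centroid scores 1, the farthest point scores 0. If all
#' distances are 0 every score is 1.
#'
#' @param model a `cluster_model`.
#' @param X the data the model was fitted on (or compatible data).
#' @return list with numeric `scores` in `[0, 1]` and a per-cluster `summary`
#'   data frame (mean, median, IQR, min, max).
#' @export
confidence_scores <- function(model, X) {
  X <- as.matrix(X)
  lab <- assign_clusters(model, X)
  d <- sqrt(rowdist2(X, model$centroids)[cbind(seq_len(nrow(X)), lab)])
  dmax <- max(d)
  sc <- if (dmax == 0) rep(1, length(d)) else 1 - d / dmax
  summ <- do.call(rbind, lapply(seq_len(model$K), function(k) {
    s <- sc[lab == k]
    data.frame(cluster = k, n = length(s), mean = mean(s),
               median = stats::median(s), iqr = stats::IQR(s),
               min = min(s), max = max(s))
  }))
  list(scores = sc, summary = summ)
}
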