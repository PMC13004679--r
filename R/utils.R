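# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("invalid config: %s must lie in [0, 1]", what)
  invisible(x)
}

assert_pos <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("invalid config: %s must be > 0", what)
  invisible(x)
}

# days per year used for all date <-> year-offset arithmetic
DAYS_PER_YEAR <- 365.25

#' @keywords internal
year_bin <- function(days_from_diagnosis) {
  as.integer(floor(days_from_diagnosis / DAYS_PER_YEAR))
}

# squared Euclidean distances between rows of X (n x d) and rows of C (k x d)
rowdist2 <- function(X, C) {
  n2x <- rowSums(X^2)
  n2c <- rowSums(C^2)
  d2 <- outer(n2x, n2c, "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  d2
}

# nearest-row index with ties broken by lowest index
nearest_row <- function(X, C) {
  max.col(-rowdist2(X, C), ties.method = "first")
}
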