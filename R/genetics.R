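cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

welch_row <- function(a, b, name_a, name_b) {
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stopf("degenerate zero-variance groups in PRS comparison (%s vs %s)",
          name_a, name_b)
  tt <- stats::t.test(a, b)
  data.frame(group_a = name_a, group_b = name_b,
             n_a = length(a), n_b = length(b),
             mean_a = mean(a), mean_b = mean(b),
             t = unname(tt$statistic), p_value = tt$p.value,
             cohens_d = cohens_d(a, b), stringsAsFactors = FALSE)
}

#' Pairwise polygenic-score contrasts
#'
#' Welch two-sided t-tests for every cluster pair and, when control scores
#' are supplied, each cluster against controls; Benjamini-Hochberg FDR is
#' applied across the whole family and Cohen's d (pooled s.d.) reported.
#'
#' @param prs standardized polygenic scores for cases.
#' @param labels cluster labels aligned with `prs`.
#' @param control_prs optional vector of control scores.
#' @return data.frame with one row per comparison: means, t, raw `p_value`,
#'   BH-adjusted `q_value`, `cohens_d`.
#' @export
prs_pairwise <- function(prs, labels, control_prs = NULL) {
  ks <- sort(unique(labels))
  rows <- list()
  for (i in seq_along(ks)) for (j in seq_along(ks)) {
    if (j <= i) next
    rows[[length(rows) + 1L]] <- welch_row(prs[labels == ks[i]],
                                           prs[labels == ks[j]],
                                           as.character(ks[i]),
                                           as.character(ks[j]))
  }
  if (!is.null(control_prs)) {
    for (k in ks)
      rows[[length(rows) + 1L]] <- welch_row(prs[labels == k], control_prs,
                                             as.character(k), "control")
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' One-versus-rest polygenic-score contrasts
#'
#' Each cluster is compared against all remaining clusters pooled, with a
#' Welch two-sided t-test.
#'
#' @inheritParams prs_pairwise
#' @return data.frame with one row per cluster.
#' @export
prs_one_vs_rest <- function(prs, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stopf("one-vs-rest requires K >= 2")
  out <- do.call(rbind, lapply(ks, function(k)
    welch_row(prs[labels == k], prs[labels != k], as.character(k), "rest")))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' SNP dosage association with cluster membership
#'
#' For each SNP and cluster, a logistic regression of the cluster indicator
#' (one versus the other clusters) on additive dosage (0/1/2), adjusted for
#' age, sex and the first three genetic principal components; fitted by
#' iteratively reweighted least squares. Odds ratios with Wald 95% CIs are
#' reported, Bonferroni-corrected over the full SNP x cluster family.
#'
#' @param genetics data.frame with `dosage_*` columns, `age`, `sex`,
#'   `gpc1`..`gpc3` (cases only; see [generate_genetics()]).
#' @param labels cluster labels aligned with `genetics` rows.
#' @param snps dosage column names (default: all `dosage_*`).
#' @return data.frame snp / cluster / or / lower / upper / p_value /
#'   p_bonferroni / converged.
#' @export
snp_logistic <- function(genetics, labels, snps = NULL) {
  snps <- snps %||% grep("^dosage_", names(genetics), value = TRUE)
  if (!length(snps)) stopf("no dosage columns found")
  for (s in snps)
    if (!all(genetics[[s]] %in% 0:2)) stopf("dosages must be 0, 1 or 2 (%s)", s)
  ks <- sort(unique(labels))
  sexn <- if (is.numeric(genetics$sex)) genetics$sex else
    as.numeric(genetics$sex == "M")
  rows <- list()
  for (s in snps) for (k in ks) {
    y <- as.integer(labels == k)
    if (length(unique(y)) < 2L) stopf("cluster indicator has a single class")
    df <- data.frame(y = y, dosage = genetics[[s]], age = genetics$age,
                     sex = sexn, gpc1 = genetics$gpc1, gpc2 = genetics$gpc2,
                     gpc3 = genetics$gpc3)
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ dosage + age + sex + gpc1 + gpc2 + gpc3,
                                  family = stats::binomial, data = df,
                                  control = list(epsilon = 1e-8, maxit = 100L))),
      error = function(e) NULL)
    conv <- !is.null(fit) && fit$converged &&
      is.finite(stats::coef(fit)["dosage"]) &&
      sqrt(diag(stats::vcov(fit)))["dosage"] < 1e3
    if (conv) {
      b <- stats::coef(fit)["dosage"]
      se <- sqrt(diag(stats::vcov(fit)))["dosage"]
      p <- 2 * stats::pnorm(-abs(b / se))
      rows[[length(rows) + 1L]] <- data.frame(
        snp = s, cluster = k, or = exp(b), lower = exp(b - 1.96 * se),
        upper = exp(b + 1.96 * se), p_value = unname(p), converged = TRUE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        snp = s, cluster = k, or = NA_real_, lower = NA_real_,
        upper = NA_real_, p_value = NA_real_, converged = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p_value * m)
  rownames(out) <- NULL
  out
}

#' Pairwise Fisher exact tests of carrier status
#'
#' For every cluster pair, an exact two-sided hypergeometric test (sum of
#' tables with probability at most the observed) of carrier counts, with the
#' sample odds ratio (Haldane 0.5 correction when a cell is zero). No
#' multiple-testing correction is applied, matching the exploratory use.
#'
#' @param carrier logical/0-1 carrier flags (dosage >= 1).
#' @param labels cluster labels aligned with `carrier`.
#' @return data.frame group_a / group_b / carriers and totals / or / p_value.
#' @export
fisher_pairwise <- function(carrier, labels) {
  carrier <- as.logical(carrier)
  ks <- sort(unique(labels))
  rows <- list()
  for (i in seq_along(ks)) for (j in seq_along(ks)) {
    if (j <= i) next
    a <- carrier[labels == ks[i]]; b <- carrier[labels == ks[j]]
    if (!length(a) || !length(b)) next
    tab <- matrix(c(sum(a), sum(!a), sum(b), sum(!b)), 2L, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    t2 <- tab + 0.5 * any(tab == 0)
    or_sample <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = as.character(ks[i]), group_b = as.character(ks[j]),
      carriers_a = sum(a), n_a = length(a),
      carriers_b = sum(b), n_b = length(b),
      or = or_sample, p_value = ft$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Carrier enrichment relative to the population allele frequency
#'
#' Ratio of the cluster-specific carrier prevalence to the population minor
#' allele frequency.
#'
#' @param carrier carrier flags; `labels` cluster labels.
#' @param labels cluster labels aligned with `carrier`.
#' @param population_maf population minor-allele frequency (> 0).
#' @return data.frame cluster / prevalence / enrichment.
#' @export
carrier_enrichment <- function(carrier, labels, population_maf) {
  if (population_maf <= 0) stopf("population_maf must be > 0")
  carrier <- as.logical(carrier)
  ks <- sort(unique(labels))
  do.call(rbind, lapply(ks, function(k) {
    prev <- mean(carrier[labels == k])
    data.frame(cluster = k, prevalence = prev,
               enrichment = prev / population_maf)
  }))
}
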