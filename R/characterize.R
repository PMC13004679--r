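#' Per-cluster prevalence of prediagnostic codes
#'
#' For every code, the proportion of each cluster's patients with at least
#' one prediagnostic record of it.
#'
#' @param cohort an `ehr_cohort`.
#' @param labels integer cluster labels aligned with `cohort$patients` rows.
#' @param codes optional subset of codes (default: all observed).
#' @return object of class `prevalence_table`: list with matrix `p`
#'   (clusters x codes) and `sizes`.
#' @export
prevalence_table <- function(cohort, labels, codes = NULL) {
  p <- cohort$patients
  if (length(labels) != nrow(p))
    stopf("labels must cover all %d patients", nrow(p))
  ks <- sort(unique(labels))
  sizes <- tabulate(match(labels, ks), length(ks))
  if (any(sizes == 0L)) stopf("empty cluster in labels")
  ev <- cohort$events
  if (!is.null(codes)) ev <- ev[ev$code %in% codes, , drop = FALSE]
  codes <- codes %||% sort(unique(ev$code))
  lab_of <- stats::setNames(labels, p$patient_id)
  has <- unique(ev[, c("patient_id", "code")])
  tab <- table(factor(lab_of[as.character(has$patient_id)], levels = ks),
               factor(has$code, levels = codes))
  P <- sweep(matrix(as.numeric(tab), length(ks), length(codes),
                    dimnames = list(ks, codes)), 1L, sizes, "/")
  structure(list(p = P, sizes = sizes, clusters = ks),
            class = "prevalence_table")
}

#' Filter codes by cross-cluster prevalence range
#'
#' Keeps a code iff the difference between its highest and lowest cluster
#' prevalence is at least `min_diff` (boundary included).
#'
#' @param table a [prevalence_table()].
#' @param min_diff minimum max-minus-min prevalence difference.
#' @return character vector of retained codes.
#' @export
variance_filter <- function(table, min_diff = 0.15) {
  rng <- apply(table$p, 2L, function(x) max(x) - min(x))
  # small tolerance so exact-boundary ranges survive floating-point noise
  colnames(table$p)[rng >= min_diff - 1e-9]
}

#' Weighted discriminative scores
#'
#' For cluster k and code c, `WDS_k(c) = p_k(c) * (p_k(c) - mean_{j != k}
#' p_j(c))`: within-cluster prevalence weighted by the between-cluster
#' separation. Zero whenever a code's prevalence is identical across
#' clusters.
#'
#' @param table a [prevalence_table()].
#' @return matrix (clusters x codes) of scores.
#' @export
wds_scores <- function(table) {
  P <- table$p
  K <- nrow(P)
  if (K < 2L) stopf("wds_scores requires K >= 2")
  others <- (matrix(colSums(P), K, ncol(P), byrow = TRUE) - P) / (K - 1)
  W <- P * (P - others)
  dimnames(W) <- dimnames(P)
  W
}

#' Top discriminative codes per cluster
#'
#' @param wds matrix from [wds_scores()].
#' @param n codes per cluster.
#' @return named list (one per cluster) of data frames `code`, `score`,
#'   ranked by descending score with lexical tie-break.
#' @export
top_discriminative <- function(wds, n = 5L) {
  out <- lapply(seq_len(nrow(wds)), function(k) {
    o <- order(-wds[k, ], colnames(wds))
    sel <- o[seq_len(min(n, ncol(wds)))]
    data.frame(code = colnames(wds)[sel], score = unname(wds[k, sel]),
               stringsAsFactors = FALSE)
  })
  names(out) <- rownames(wds)
  out
}

#' Symptom prevalence trajectories around diagnosis
#'
#' Yearly prevalence per cluster of each symptom code over year bins -5..4
#' relative to diagnosis (bin = floor(days from diagnosis / 365.25); the
#' diagnosis day falls in bin 0). Both the prediagnostic events and the
#' post-diagnosis event store contribute. In post-diagnosis bins, only
#' patients who survive into the bin form the denominator.
#'
#' @param cohort an `ehr_cohort` (must carry `post_events`).
#' @param labels cluster labels aligned with `cohort$patients`.
#' @param symptom_codes codes to track; unknown codes are skipped with a
#'   warning.
#' @return data.frame cluster / code / year / prevalence / n_at_risk.
#' @export
symptom_trajectory <- function(cohort, labels, symptom_codes) {
  all_ev <- rbind(cohort$events, cohort$post_events)
  known <- symptom_codes %in% all_ev$code
  if (any(!known)) {
    warnf("unknown symptom codes skipped: %s",
          paste(symptom_codes[!known], collapse = ", "))
    symptom_codes <- symptom_codes[known]
  }
  p <- cohort$patients
  ks <- sort(unique(labels))
  ev <- all_ev[all_ev$code %in% symptom_codes, , drop = FALSE]
  dd <- p$diagnosis_date[match(ev$patient_id, p$patient_id)]
  ev$year <- year_bin(as.numeric(ev$date) - as.numeric(dd))
  rows <- list()
  for (t in -5:4) {
    alive <- if (t > 0) p$death_time > t else rep(TRUE, nrow(p))
    for (k in ks) {
      denom_ids <- p$patient_id[alive & labels == k]
      evt <- ev[ev$year == t & ev$patient_id %in% denom_ids, , drop = FALSE]
      for (s in symptom_codes) {
        hit <- unique(evt$patient_id[evt$code == s])
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = k, code = s, year = t,
          prevalence = if (length(denom_ids)) length(hit) / length(denom_ids) else NA_real_,
          n_at_risk = length(denom_ids))
      }
    }
  }
  do.call(rbind, rows)
}

#' Cognitive-score trends and pairwise post-diagnosis tests
#'
#' Yearly mean and standard error of the mean per cluster, plus two-sided
#' Mann-Whitney tests comparing per-patient mean post-diagnosis scores for
#' every cluster pair (exact when the combined n is at most 20, normal
#' approximation with tie correction otherwise).
#'
#' @param scores data.frame patient_id / year / score (e.g. `cohort$scores`).
#' @param labels cluster labels named by (or aligned with) patient id.
#' @param patient_ids patient ids aligned with `labels`.
#' @return list with data frames `trend` (cluster, year, mean, sem, n) and
#'   `tests` (cluster_a, cluster_b, statistic, p_value).
#' @export
score_trend <- function(scores, labels, patient_ids) {
  lab_of <- stats::setNames(labels, patient_ids)
  scores$cluster <- lab_of[as.character(scores$patient_id)]
  scores <- scores[!is.na(scores$cluster), , drop = FALSE]
  agg <- do.call(rbind, lapply(split(scores, scores[, c("cluster", "year")], drop = TRUE),
    function(g) data.frame(cluster = g$cluster[1L], year = g$year[1L],
                           mean = mean(g$score),
                           sem = stats::sd(g$score) / sqrt(nrow(g)),
                           n = nrow(g))))
  agg <- agg[order(agg$cluster, agg$year), , drop = FALSE]
  rownames(agg) <- NULL

  post <- scores[scores$year >= 0, , drop = FALSE]
  pm <- tapply(post$score, post$patient_id, mean)
  pm_lab <- lab_of[names(pm)]
  ks <- sort(unique(labels))
  tests <- list()
  for (i in seq_along(ks)) for (j in seq_along(ks)) {
    if (j <= i) next
    a <- pm[pm_lab == ks[i]]; b <- pm[pm_lab == ks[j]]
    if (!length(a) || !length(b)) {
      warnf("empty post-diagnosis score group for cluster %s or %s; comparison skipped",
            ks[i], ks[j])
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b,
      exact = (length(a) + length(b)) <= 20L, correct = FALSE))
    tests[[length(tests) + 1L]] <- data.frame(
      cluster_a = ks[i], cluster_b = ks[j],
      statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  list(trend = agg, tests = do.call(rbind, tests))
}

#' Prototype patients nearest each centroid
#'
#' Selects, per cluster, the `ceiling(top_frac * cluster size)` members
#' closest to the centroid and summarizes their demographics and most
#' frequent codes.
#'
#' @param model a `cluster_model`.
#' @param X embedding matrix the model was fitted on.
#' @param cohort the matching `ehr_cohort`.
#' @param top_frac fraction of each cluster selected.
#' @param n_codes frequent codes reported per cluster.
#' @return list per cluster: `patient_ids`, `summary` (n, mean age, share
#'   female, median IMD), `top_codes`.
#' @export
prototype_patients <- function(model, X, cohort, top_frac = 0.01,
                               n_codes = 5L) {
  X <- as.matrix(X)
  lab <- model$assignments
  d <- sqrt(rowdist2(X, model$centroids)[cbind(seq_len(nrow(X)), lab)])
  p <- cohort$patients
  out <- lapply(seq_len(model$K), function(k) {
    idx <- which(lab == k)
    m <- ceiling(top_frac * length(idx))
    sel <- idx[order(d[idx])][seq_len(m)]
    ids <- p$patient_id[sel]
    ev <- cohort$events[cohort$events$patient_id %in% ids, , drop = FALSE]
    tab <- sort(table(ev$code), decreasing = TRUE)
    list(patient_ids = ids,
         summary = data.frame(
           cluster = k, n = m,
           mean_age = mean(p$age_at_diagnosis[sel]),
           share_female = mean(p$sex[sel] == "F"),
           median_imd = stats::median(p$imd[sel])),
         top_codes = utils::head(names(tab), n_codes))
  })
  names(out) <- seq_len(model$K)
  out
}

#' Healthcare-utilization checks across clusters
#'
#' Kruskal-Wallis tests (with tie correction) comparing visit frequency and
#' total record count across clusters, and a practice-level intraclass
#' correlation per cluster indicator from a random-intercept logistic model:
#' `ICC = sigma_b^2 / (sigma_b^2 + pi^2 / 3)`.
#'
#' @param cohort an `ehr_cohort`.
#' @param labels cluster labels aligned with `cohort$patients`.
#' @return list with `kruskal` (data.frame outcome / statistic / df /
#'   p_value) and `icc` (per-cluster data.frame plus `mean_icc`), the latter
#'   NULL (with a warning) when only one practice is present.
#' @export
utilization_tests <- function(cohort, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stopf("utilization_tests: need >= 2 clusters")
  vf <- visit_frequency(cohort)
  nrec <- as.numeric(table(factor(cohort$events$patient_id,
                                  levels = cohort$patients$patient_id)))
  kw <- function(y, nm) {
    t <- stats::kruskal.test(y, factor(labels))
    data.frame(outcome = nm, statistic = unname(t$statistic),
               df = unname(t$parameter), p_value = t$p.value)
  }
  kruskal <- rbind(kw(vf, "visit_frequency"), kw(nrec, "record_count"))

  icc <- NULL
  prac <- factor(cohort$patients$practice_id)
  if (nlevels(prac) < 2L) {
    warnf("single practice: ICC skipped")
  } else {
    icc_rows <- lapply(ks, function(k) {
      y <- as.integer(labels == k)
      fit <- suppressMessages(suppressWarnings(
        lme4::glmer(y ~ 1 + (1 | prac), family = stats::binomial,
                    control = lme4::glmerControl(check.conv.singular = "ignore"))))
      vb <- as.numeric(lme4::VarCorr(fit)$prac[1L])
      data.frame(cluster = k, sigma2_practice = vb,
                 icc = vb / (vb + pi^2 / 3))
    })
    icc <- do.call(rbind, icc_rows)
    icc <- list(per_cluster = icc, mean_icc = mean(icc$icc))
  }
  list(kruskal = kruskal, icc = icc)
}
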