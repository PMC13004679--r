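#' TF-IDF representation of prediagnostic coded events
#'
#' Term frequency is the raw count of a code in a patient's prediagnostic
#' events; inverse document frequency is `ln(N / df)` (natural log, no
#' smoothing) with `df` the number of patients carrying the code. Codes with
#' `df = 0` are excluded.
#'
#' @param cohort an `ehr_cohort`.
#' @param vocab optional `ehr_vocab`; restricts columns to its codes.
#' @return numeric matrix patients x codes with patient ids as row names.
#' @export
tfidf_features <- function(cohort, vocab = NULL) {
  pats <- cohort$patients$patient_id
  if (!length(pats)) stopf("tfidf_features: empty cohort")
  ev <- cohort$events
  codes <- if (!is.null(vocab)) names(vocab$map) else sort(unique(ev$code))
  ev <- ev[ev$code %in% codes, , drop = FALSE]
  tf <- table(factor(ev$patient_id, levels = pats),
              factor(ev$code, levels = codes))
  tf <- matrix(as.numeric(tf), length(pats), length(codes),
               dimnames = list(as.character(pats), codes))
  df <- colSums(tf > 0)
  keep <- df > 0
  tf <- tf[, keep, drop = FALSE]
  idf <- log(length(pats) / df[keep])
  sweep(tf, 2L, idf, "*")
}

observed_lookback_years <- function(cohort) {
  first <- tapply(as.numeric(cohort$events$date), cohort$events$patient_id, min)
  first <- first[as.character(cohort$patients$patient_id)]
  (as.numeric(cohort$patients$diagnosis_date) - first) / DAYS_PER_YEAR
}

visit_frequency <- function(cohort) {
  nd <- tapply(cohort$events$date, cohort$events$patient_id,
               function(d) length(unique(d)))
  nd <- nd[as.character(cohort$patients$patient_id)]
  nd[is.na(nd)] <- 0
  lb <- observed_lookback_years(cohort)
  vf <- ifelse(is.na(lb) | lb <= 0, 0, nd / lb)
  if (any(is.na(lb) | lb <= 0))
    warnf("zero observed lookback for %d patients; visit frequency set to 0",
          sum(is.na(lb) | lb <= 0))
  unname(vf)
}

#' Clinical-variable baseline features
#'
#' Exactly six z-scored columns: age at diagnosis, sex (F = 0, M = 1), IMD
#' quintile, diagnosis calendar year, mean annual visit frequency (distinct
#' event dates per observed lookback year) and the 2-year Charlson
#' comorbidity index.
#'
#' @param cohort an `ehr_cohort`.
#' @param code_map Charlson code map (see [charlson_index()]); default
#'   [default_charlson_map()].
#' @return numeric matrix patients x 6 with patient ids as row names.
#' @export
clinical_features <- function(cohort, code_map = default_charlson_map()) {
  p <- cohort$patients
  cci <- charlson_all(cohort, code_map)
  M <- cbind(
    age = p$age_at_diagnosis,
    sex = as.numeric(p$sex == "M"),
    imd = p$imd,
    dx_year = as.integer(format(p$diagnosis_date, "%Y")),
    visit_freq = visit_frequency(cohort),
    cci2 = cci
  )
  rownames(M) <- as.character(p$patient_id)
  Z <- standardize_embeddings(M)
  colnames(Z) <- colnames(M)
  Z
}

#' Default Charlson comorbidity map for the synthetic vocabulary
#'
#' Reads the packaged two-part map: synthetic codes assigned to the classic
#' 17 Charlson categories, with the original category weights. Entirely
#' synthetic; real SNOMED/ICD-10 Charlson code lists are out of scope.
#'
#' @return data.frame with columns `code`, `category`, `weight`.
#' @export
default_charlson_map <- function() {
  codes <- utils::read.csv(system.file("extdata", "charlson_codes_synthetic.csv",
                                       package = "ehrsubtype"))
  weights <- utils::read.csv(system.file("extdata", "charlson_weights.csv",
                                         package = "ehrsubtype"))
  merge(codes, weights, by = "category")[, c("code", "category", "weight")]
}

#' Charlson comorbidity index over a recent window
#'
#' Sums the Charlson weights of the distinct comorbidity categories recorded
#' within `window_years` before the diagnosis date; each category counts
#' once, unmapped codes are ignored.
#'
#' @param events a patient's event data.frame (date, code).
#' @param code_map data.frame code/category/weight.
#' @param window_years lookback window length.
#' @param diagnosis_date the index date.
#' @return integer-valued nonnegative score.
#' @export
charlson_index <- function(events, code_map, window_years = 2,
                           diagnosis_date) {
  if (is.null(events) || !nrow(events)) return(0)
  lo <- as.numeric(diagnosis_date) - window_years * DAYS_PER_YEAR
  ev <- events[as.numeric(events$date) >= lo &
                 as.numeric(events$date) <= as.numeric(diagnosis_date), , drop = FALSE]
  m <- code_map[match(ev$code, code_map$code), , drop = FALSE]
  m <- m[!is.na(m$category), , drop = FALSE]
  if (!nrow(m)) return(0)
  sum(m$weight[!duplicated(m$category)])
}

# vectorized 2-year Charlson index for every patient in a cohort
charlson_all <- function(cohort, code_map, window_years = 2) {
  p <- cohort$patients
  ev <- cohort$events
  dd <- as.numeric(p$diagnosis_date)[match(ev$patient_id, p$patient_id)]
  inwin <- as.numeric(ev$date) >= dd - window_years * DAYS_PER_YEAR &
    as.numeric(ev$date) <= dd
  ev <- ev[inwin, , drop = FALSE]
  cat_of <- code_map$category[match(ev$code, code_map$code)]
  keep <- !is.na(cat_of)
  pc <- unique(data.frame(patient_id = ev$patient_id[keep], category = cat_of[keep]))
  pc$weight <- code_map$weight[match(pc$category, code_map$category)]
  tot <- tapply(pc$weight, pc$patient_id, sum)
  out <- as.numeric(tot[as.character(p$patient_id)])
  out[is.na(out)] <- 0
  out
}

#' Benchmark baseline representations under the clustering pipeline
#'
#' Runs the K-selection scan (prediction strength over `k_range`) and a
#' silhouette scan for each supplied representation, and reports the best K
#' per criterion with the accompanying stability metrics.
#'
#' @param representations named list of feature matrices (e.g. transformer
#'   embeddings, TF-IDF, clinical variables), all over the same patients.
#' @param k_range candidate K values.
#' @param threshold prediction-strength threshold.
#' @param seed RNG seed.
#' @param n_init,n_repeats,B_bootstrap pipeline settings (see [select_k()]).
#' @return data.frame with one row per (representation, criterion): chosen K,
#'   prediction strength, silhouette, Davies-Bouldin, bootstrap ARI.
#' @export
benchmark_baselines <- function(representations, k_range = 3:8,
                                threshold = 0.95, seed = 1L, n_init = 10L,
                                n_repeats = 5L, B_bootstrap = 10L) {
  rows <- list()
  for (nm in names(representations)) {
    X <- as.matrix(representations[[nm]])
    ps <- vapply(k_range, function(K)
      prediction_strength(X, K, n_repeats = n_repeats, seed = seed + K,
                          n_init = n_init), numeric(1))
    sil <- vapply(k_range, function(K) {
      fit <- kmeans_fit(X, K, seed = seed, n_init = n_init)
      silhouette_score(X, fit$assignments)
    }, numeric(1))
    ok <- which(ps >= threshold)
    k_ps <- if (length(ok)) max(k_range[ok]) else k_range[which.max(ps)]
    k_sil <- k_range[which.max(sil)]
    for (crit in c("prediction_strength", "silhouette")) {
      K <- if (crit == "prediction_strength") k_ps else k_sil
      fit <- kmeans_fit(X, K, seed = seed, n_init = n_init)
      rows[[length(rows) + 1L]] <- data.frame(
        representation = nm, criterion = crit, chosen_k = K,
        prediction_strength = ps[match(K, k_range)],
        silhouette = sil[match(K, k_range)],
        davies_bouldin = davies_bouldin(X, fit$assignments),
        bootstrap_ari = if (B_bootstrap > 0)
          bootstrap_ari(X, fit, B = B_bootstrap, seed = seed, n_init = n_init)
          else NA_real_,
        fallback_used = crit == "prediction_strength" && !length(ok),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
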