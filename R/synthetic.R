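#' Configuration for a synthetic longitudinal EHR cohort
#'
#' Defines the study conditions for a simulated primary-care cohort with
#' planted subtype structure: per-subtype comorbidity-code prevalences over a
#' prediagnostic lookback window, per-subtype visit rates with a
#' practice-level random intercept, logistic symptom-code time trends over the
#' ten years around diagnosis, exponential five-year mortality and
#' hospitalization hazards, a linear cognitive-score decline, and
#' subtype-shifted polygenic scores and SNP minor-allele frequencies.
#'
#' Codes are partitioned into three channels: *signature* codes (any code with
#' a positive entry in `signature_matrix`), emitted only for patients who
#' carry them (carriage is Bernoulli with the planted prevalence, and every
#' carried code is recorded at least once, so planted prevalences are
#' recovered exactly up to carrier sampling); *symptom* codes, emitted per
#' year from the logistic trend; and *background* codes drawn uniformly.
#'
#' @param n_patients number of patients to simulate.
#' @param n_subtypes number of planted subtypes (>= 2).
#' @param subtype_weights mixing proportions over subtypes; must sum to 1.
#' @param vocab_size number of distinct clinical codes (`"C001"...`).
#' @param signature_matrix `n_subtypes x vocab_size` matrix of Bernoulli
#'   carriage prevalences. Default plants `codes_per_subtype` exclusive codes
#'   per subtype at prevalence `signature_prevalence`.
#' @param codes_per_subtype,signature_prevalence shape of the default
#'   signature block when `signature_matrix` is not supplied.
#' @param signature_mix_weight probability that a visit code slot draws from
#'   the patient's carried signature set rather than the background pool.
#' @param visit_rate per-subtype mean visits per year (recycled to
#'   `n_subtypes`).
#' @param lookback_years length of the prediagnostic observation window.
#' @param symptom_codes number of dedicated symptom codes (taken from the top
#'   of the vocabulary).
#' @param symptom_intercept,symptom_slope per-subtype logistic trend
#'   parameters: the probability that a symptom code is recorded in year `t`
#'   relative to diagnosis (`t` in -5..4) is `plogis(intercept + slope * t)`.
#' @param hazard_mortality,hazard_hospital per-subtype exponential event rates
#'   (1/year) for post-diagnosis death and disease-related hospitalization.
#' @param score_baseline,score_baseline_sd,score_slope,score_noise_sd
#'   cognitive-score model: per-patient intercept `Normal(baseline,
#'   baseline_sd)`, per-subtype annual slope, observation noise.
#' @param prs_shift per-subtype mean shift (in s.d. units) of the standardized
#'   polygenic risk score.
#' @param snp_freqs `n_subtypes x n_snps` matrix of minor-allele frequencies,
#'   all in (0, 1); dosages are `Binomial(2, freq)`.
#' @param control_maf population minor-allele frequencies used for simulated
#'   controls (length `n_snps`).
#' @param n_practices number of GP practices.
#' @param practice_sd s.d. of the practice random intercept on the log visit
#'   rate.
#' @param age_mean,age_sd age-at-diagnosis distribution, truncated at 40.
#' @param seed integer seed; the whole cohort is deterministic given it.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [generate_genetics()], [split_by_practice()]
#' @export
cohort_config <- function(n_patients,
                          n_subtypes = 5L,
                          subtype_weights = rep(1 / n_subtypes, n_subtypes),
                          vocab_size = 100L,
                          signature_matrix = NULL,
                          codes_per_subtype = 8L,
                          signature_prevalence = 0.9,
                          signature_mix_weight = 0.3,
                          visit_rate = c(2, 2.5, 3, 3.5, 4),
                          lookback_years = 20,
                          symptom_codes = 5L,
                          symptom_intercept = rep(-2, n_subtypes),
                          symptom_slope = seq(0.25, 0.65, length.out = n_subtypes),
                          hazard_mortality = seq(0.04, 0.18, length.out = n_subtypes),
                          hazard_hospital = seq(0.10, 0.28, length.out = n_subtypes),
                          score_baseline = 27,
                          score_baseline_sd = 1.5,
                          score_slope = seq(-0.8, -2.4, length.out = n_subtypes),
                          score_noise_sd = 1,
                          prs_shift = seq(0.5, -0.5, length.out = n_subtypes),
                          snp_freqs = NULL,
                          control_maf = c(0.15, 0.15, 0.15),
                          n_practices = 50L,
                          practice_sd = 0.2,
                          age_mean = 78,
                          age_sd = 8,
                          seed = 1L) {
  n_patients <- as.integer(n_patients)
  n_subtypes <- as.integer(n_subtypes)
  vocab_size <- as.integer(vocab_size)
  if (n_subtypes < 2L) stopf("invalid config: n_subtypes must be >= 2")
  if (n_patients < n_subtypes)
    stopf("invalid config: n_patients (%d) < n_subtypes (%d)", n_patients, n_subtypes)
  if (length(subtype_weights) != n_subtypes)
    stopf("invalid config: subtype_weights must have length n_subtypes")
  assert_prob(subtype_weights, "subtype_weights")
  if (abs(sum(subtype_weights) - 1) > 1e-9)
    stopf("invalid config: subtype_weights must sum to 1")
  visit_rate <- rep_len(visit_rate, n_subtypes)
  assert_pos(visit_rate, "visit_rate")
  assert_pos(hazard_mortality, "hazard_mortality")
  assert_pos(hazard_hospital, "hazard_hospital")
  hazard_mortality <- rep_len(hazard_mortality, n_subtypes)
  hazard_hospital <- rep_len(hazard_hospital, n_subtypes)
  assert_pos(lookback_years, "lookback_years")
  assert_prob(signature_mix_weight, "signature_mix_weight")
  symptom_codes <- as.integer(symptom_codes)

  if (is.null(signature_matrix)) {
    signature_matrix <- matrix(0, n_subtypes, vocab_size)
    n_sig <- codes_per_subtype * n_subtypes
    if (n_sig + symptom_codes > vocab_size)
      stopf("invalid config: vocab too small for %d signature + %d symptom codes",
            n_sig, symptom_codes)
    for (k in seq_len(n_subtypes)) {
      cols <- ((k - 1L) * codes_per_subtype + 1L):(k * codes_per_subtype)
      signature_matrix[k, cols] <- signature_prevalence
    }
  }
  if (!is.matrix(signature_matrix) ||
      nrow(signature_matrix) != n_subtypes || ncol(signature_matrix) != vocab_size)
    stopf("invalid config: signature_matrix must be n_subtypes x vocab_size")
  assert_prob(signature_matrix, "signature_matrix")

  if (is.null(snp_freqs)) {
    n_snp <- length(control_maf)
    snp_freqs <- matrix(rep(control_maf, each = n_subtypes), n_subtypes, n_snp)
    # plant one enriched and one depleted subtype-SNP pair
    snp_freqs[1L, 1L] <- min(0.99, control_maf[1L] * 2)
    if (n_snp >= 2L) snp_freqs[min(2L, n_subtypes), 2L] <- min(0.99, control_maf[2L] * 1.6)
    if (n_snp >= 3L) snp_freqs[min(4L, n_subtypes), 3L] <- max(0.01, control_maf[3L] / 2)
  }
  if (any(snp_freqs <= 0) || any(snp_freqs >= 1))
    stopf("invalid config: snp_freqs must lie strictly in (0, 1)")
  if (nrow(snp_freqs) != n_subtypes)
    stopf("invalid config: snp_freqs must have one row per subtype")
  if (length(prs_shift) != n_subtypes)
    stopf("invalid config: prs_shift must have length n_subtypes")

  if (symptom_codes > 0L && symptom_codes >= vocab_size)
    stopf("invalid config: symptom_codes must be < vocab_size")
  if (n_practices < 1L) stopf("invalid config: n_practices must be >= 1")

  cfg <- list(
    n_patients = n_patients, n_subtypes = n_subtypes,
    subtype_weights = as.numeric(subtype_weights),
    vocab_size = vocab_size, signature_matrix = signature_matrix,
    signature_mix_weight = signature_mix_weight,
    visit_rate = as.numeric(visit_rate), lookback_years = lookback_years,
    symptom_codes = symptom_codes,
    symptom_intercept = rep_len(symptom_intercept, n_subtypes),
    symptom_slope = rep_len(symptom_slope, n_subtypes),
    hazard_mortality = hazard_mortality, hazard_hospital = hazard_hospital,
    score_baseline = score_baseline, score_baseline_sd = score_baseline_sd,
    score_slope = rep_len(score_slope, n_subtypes),
    score_noise_sd = score_noise_sd,
    prs_shift = as.numeric(prs_shift), snp_freqs = snp_freqs,
    control_maf = as.numeric(control_maf),
    n_practices = as.integer(n_practices), practice_sd = practice_sd,
    age_mean = age_mean, age_sd = age_sd, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

code_label <- function(i) sprintf("C%03d", i)

#' Code channels implied by a cohort configuration
#'
#' @param config a [cohort_config()].
#' @return list with character vectors `signature`, `symptom`, `background`
#'   and per-subtype list `signature_by_subtype`.
#' @export
code_channels <- function(config) {
  all_codes <- code_label(seq_len(config$vocab_size))
  sym_idx <- if (config$symptom_codes > 0L)
    (config$vocab_size - config$symptom_codes + 1L):config$vocab_size else integer(0)
  sig_idx <- setdiff(which(colSums(config$signature_matrix) > 0), sym_idx)
  bg_idx <- setdiff(seq_len(config$vocab_size), c(sym_idx, sig_idx))
  by_subtype <- lapply(seq_len(config$n_subtypes), function(k)
    code_label(intersect(which(config$signature_matrix[k, ] > 0), sig_idx)))
  list(signature = code_label(sig_idx), symptom = code_label(sym_idx),
       background = code_label(bg_idx), signature_by_subtype = by_subtype)
}

#' Simulate a cohort of patients with planted subtype structure
#'
#' Draws, per patient: a hidden subtype, a GP practice, an age at diagnosis
#' (Normal truncated at 40) and a diagnosis date uniform over 2005-2018; a
#' homogeneous-Poisson stream of prediagnostic visits whose log rate carries
#' the practice random intercept; 1-3 codes per visit from a mixture of the
#' background pool and the patient's carried signature codes; pre-diagnosis
#' symptom events from the per-subtype logistic year trend; exponential death
#' and hospitalization times; and yearly cognitive-score observations.
#' Post-diagnosis symptom events are kept in a separate `post_events` store so
#' that `events` remains strictly prediagnostic.
#'
#' @param config a [cohort_config()].
#' @return An object of class `ehr_cohort`: list with data frames `patients`
#'   (one row per patient; includes the hidden `true_subtype`), `events`
#'   (patient_id, date, code, domain), `post_events`, `scores`
#'   (patient_id, year, score) and the `config`. Dates are `Date`s.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stopf("config must be a cohort_config")
  set.seed(config$seed)
  n <- config$n_patients
  K <- config$n_subtypes
  ch <- code_channels(config)

  subtype <- sample.int(K, n, replace = TRUE, prob = config$subtype_weights)
  practice <- sample.int(config$n_practices, n, replace = TRUE)
  practice_eff <- stats::rnorm(config$n_practices, 0, config$practice_sd)

  age_dx <- stats::rnorm(n, config$age_mean, config$age_sd)
  while (any(age_dx < 40)) {
    i <- age_dx < 40
    age_dx[i] <- stats::rnorm(sum(i), config$age_mean, config$age_sd)
  }
  dx_date <- as.Date("2005-01-01") +
    floor(stats::runif(n) * as.numeric(as.Date("2018-01-01") - as.Date("2005-01-01")))
  birth_year <- as.integer(format(dx_date, "%Y")) - as.integer(floor(age_dx))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  imd <- sample.int(5L, n, replace = TRUE)

  lb_days <- config$lookback_years * DAYS_PER_YEAR
  rate <- config$visit_rate[subtype] * exp(practice_eff[practice])
  n_visits <- pmax(1L, stats::rpois(n, rate * config$lookback_years))

  # visit dates, strictly before diagnosis
  pid_v <- rep.int(seq_len(n), n_visits)
  offs <- floor(stats::runif(sum(n_visits)) * (lb_days - 1)) + 1
  vdate <- as.numeric(dx_date[pid_v]) - offs

  # carried signature codes per patient
  sig_idx <- match(ch$signature, code_label(seq_len(config$vocab_size)))
  carried <- vector("list", n)
  if (length(sig_idx)) {
    prev <- config$signature_matrix[, sig_idx, drop = FALSE]
    U <- matrix(stats::runif(n * length(sig_idx)), n)
    for (i in seq_len(n)) carried[[i]] <- ch$signature[U[i, ] < prev[subtype[i], ]]
  }

  # per-visit code slots: mixture of carried signature set and background pool
  n_codes <- sample(1:3, length(pid_v), replace = TRUE)
  pid_c <- rep.int(pid_v, n_codes)
  date_c <- rep.int(vdate, n_codes)
  use_sig <- stats::runif(length(pid_c)) < config$signature_mix_weight
  code_c <- character(length(pid_c))
  bg <- ch$background
  code_c[!use_sig] <- bg[sample.int(length(bg), sum(!use_sig), replace = TRUE)]
  si <- which(use_sig)
  if (length(si)) {
    n_car <- lengths(carried)[pid_c[si]]
    empty <- n_car == 0L
    if (any(empty)) {
      code_c[si[empty]] <- bg[sample.int(length(bg), sum(empty), replace = TRUE)]
      si <- si[!empty]; n_car <- n_car[!empty]
    }
    pick <- floor(stats::runif(length(si)) * n_car) + 1L
    code_c[si] <- mapply(function(p, j) carried[[p]][j], pid_c[si], pick)
  }

  # forced first emission: every carried code is recorded at least once
  vis_by_pat <- split(vdate, pid_v)
  extra_pid <- rep.int(seq_len(n), lengths(carried))
  extra_code <- unlist(carried, use.names = FALSE)
  extra_date <- vapply(extra_pid, function(p) {
    v <- vis_by_pat[[p]]; v[sample.int(length(v), 1L)]
  }, numeric(1))

  # pre-diagnosis symptom events from the logistic year trend (years -5..-1)
  sym_pid <- integer(0); sym_date <- numeric(0); sym_code <- character(0)
  post_pid <- integer(0); post_date <- numeric(0); post_code <- character(0)
  death_time <- stats::rexp(n, config$hazard_mortality[subtype])
  hospital_time <- stats::rexp(n, config$hazard_hospital[subtype])
  if (config$symptom_codes > 0L) {
    for (t in -5:4) {
      p_t <- stats::plogis(config$symptom_intercept[subtype] +
                             config$symptom_slope[subtype] * t)
      for (s in ch$symptom) {
        hit <- stats::runif(n) < p_t
        if (t >= 0) hit <- hit & (death_time > t)  # must survive into the bin
        idx <- which(hit)
        if (!length(idx)) next
        day <- floor(t * DAYS_PER_YEAR + stats::runif(length(idx)) * DAYS_PER_YEAR)
        if (t < 0) {
          sym_pid <- c(sym_pid, idx)
          sym_date <- c(sym_date, as.numeric(dx_date[idx]) + day)
          sym_code <- c(sym_code, rep(s, length(idx)))
        } else {
          post_pid <- c(post_pid, idx)
          post_date <- c(post_date, as.numeric(dx_date[idx]) + day)
          post_code <- c(post_code, rep(s, length(idx)))
        }
      }
    }
  }

  domains <- c("diagnosis", "medication", "procedure", "test")
  ev_pid <- c(pid_c, extra_pid, sym_pid)
  ev_date <- c(date_c, extra_date, sym_date)
  ev_code <- c(code_c, extra_code, sym_code)
  # clamp any symptom day that fell on/after diagnosis into the prior day
  ev_date <- pmin(ev_date, as.numeric(dx_date[ev_pid]) - 1)
  ev_dom <- domains[(as.integer(factor(ev_code, levels = code_label(seq_len(config$vocab_size)))) %% 4L) + 1L]
  o <- order(ev_pid, ev_date, ev_code)
  events <- data.frame(
    patient_id = ev_pid[o],
    date = as.Date(ev_date[o], origin = "1970-01-01"),
    code = ev_code[o],
    domain = ev_dom[o],
    stringsAsFactors = FALSE
  )
  post_events <- data.frame(
    patient_id = post_pid, date = as.Date(post_date, origin = "1970-01-01"),
    code = post_code, domain = "diagnosis", stringsAsFactors = FALSE
  )
  post_events <- post_events[order(post_events$patient_id, post_events$date), ,
                             drop = FALSE]
  rownames(post_events) <- NULL

  # cognitive-score observations at integer years -5..5
  sc_pid <- integer(0); sc_year <- integer(0); sc_val <- numeric(0)
  intercept_i <- stats::rnorm(n, config$score_baseline, config$score_baseline_sd)
  for (t in -5:5) {
    alive <- if (t > 0) death_time > t else rep(TRUE, n)
    obs <- alive & stats::runif(n) < 0.8
    idx <- which(obs)
    if (!length(idx)) next
    sc_pid <- c(sc_pid, idx); sc_year <- c(sc_year, rep(t, length(idx)))
    sc_val <- c(sc_val, intercept_i[idx] + config$score_slope[subtype[idx]] * t +
                  stats::rnorm(length(idx), 0, config$score_noise_sd))
  }
  scores <- data.frame(patient_id = sc_pid, year = sc_year, score = sc_val)
  scores <- scores[order(scores$patient_id, scores$year), , drop = FALSE]
  rownames(scores) <- NULL

  patients <- data.frame(
    patient_id = seq_len(n),
    practice_id = practice,
    sex = sex,
    birth_year = birth_year,
    imd = imd,
    diagnosis_date = dx_date,
    age_at_diagnosis = floor(age_dx),
    death_time = death_time,
    hospital_time = hospital_time,
    true_subtype = subtype,
    stringsAsFactors = FALSE
  )

  structure(list(patients = patients, events = events,
                 post_events = post_events, scores = scores, config = config),
            class = "ehr_cohort")
}

#' @exportS3Method print ehr_cohort
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("Synthetic EHR cohort: %d patients, %d events (%d post-diagnosis)\n",
              nrow(x$patients), nrow(x$events), nrow(x$post_events)))
  cat(sprintf("  practices: %d  planted subtypes: %d  vocab: %d codes\n",
              length(unique(x$patients$practice_id)), x$config$n_subtypes,
              x$config$vocab_size))
  invisible(x)
}

#' Simulate genetics records for a cohort plus population controls
#'
#' Cases get a standardized polygenic risk score `Normal(prs_shift[subtype],
#' 1)` and additive SNP dosages `Binomial(2, snp_freqs[subtype, snp])`;
#' controls get `Normal(0, 1)` scores and dosages from the population
#' minor-allele frequencies. The first three genetic principal components are
#' standard normal for everyone.
#'
#' @param cohort an `ehr_cohort`.
#' @param config the [cohort_config()] used to build it.
#' @param n_controls number of control records (default: `n_patients`).
#' @param seed RNG seed (default derived from the config seed).
#' @return data.frame with columns patient_id, prs, dosage_SNP*, age, sex,
#'   gpc1-3, is_control (and the hidden subtype for cases).
#' @export
generate_genetics <- function(cohort, config = cohort$config,
                              n_controls = config$n_patients,
                              seed = config$seed + 1L) {
  if (!nrow(cohort$patients)) stopf("cohort is empty")
  subtype <- cohort$patients$true_subtype
  if (any(is.na(subtype))) stopf("missing subtype label in cohort")
  set.seed(seed)
  n <- nrow(cohort$patients)
  n_snp <- ncol(config$snp_freqs)

  prs_case <- stats::rnorm(n, config$prs_shift[subtype], 1)
  prs_ctrl <- stats::rnorm(n_controls, 0, 1)
  dos_case <- sapply(seq_len(n_snp), function(j)
    stats::rbinom(n, 2L, config$snp_freqs[subtype, j]))
  dos_ctrl <- sapply(seq_len(n_snp), function(j)
    stats::rbinom(n_controls, 2L, config$control_maf[j]))
  dos <- rbind(matrix(dos_case, n), matrix(dos_ctrl, n_controls))
  colnames(dos) <- sprintf("dosage_SNP%d", seq_len(n_snp))

  out <- data.frame(
    patient_id = c(cohort$patients$patient_id, -seq_len(n_controls)),
    prs = c(prs_case, prs_ctrl),
    age = c(cohort$patients$age_at_diagnosis,
            round(stats::rnorm(n_controls, config$age_mean - 10, config$age_sd))),
    sex = c(cohort$patients$sex, sample(c("F", "M"), n_controls, replace = TRUE)),
    gpc1 = stats::rnorm(n + n_controls),
    gpc2 = stats::rnorm(n + n_controls),
    gpc3 = stats::rnorm(n + n_controls),
    is_control = rep(c(FALSE, TRUE), c(n, n_controls)),
    true_subtype = c(subtype, rep(NA_integer_, n_controls)),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(dos))
}

#' Split a cohort into derivation and validation sets by GP practice
#'
#' Practices, not patients, are randomly partitioned so that no practice
#' contributes to both sets; the derivation set receives
#' `round(derivation_fraction * n_practices)` practices.
#'
#' @param cohort an `ehr_cohort`.
#' @param derivation_fraction fraction of practices in the derivation set.
#' @param seed RNG seed for the practice permutation.
#' @return list with `ehr_cohort`s `derivation` and `validation`.
#' @export
split_by_practice <- function(cohort, derivation_fraction = 0.8,
                              seed = cohort$config$seed + 2L) {
  prac <- sort(unique(cohort$patients$practice_id))
  if (length(prac) < 2L) stopf("cannot split by practice: only one practice")
  set.seed(seed)
  n_der <- round(derivation_fraction * length(prac))
  n_der <- min(max(n_der, 1L), length(prac) - 1L)
  der_prac <- sample(prac, n_der)
  subset_cohort <- function(keep) {
    ids <- cohort$patients$patient_id[cohort$patients$practice_id %in% keep]
    out <- list(
      patients = cohort$patients[cohort$patients$patient_id %in% ids, , drop = FALSE],
      events = cohort$events[cohort$events$patient_id %in% ids, , drop = FALSE],
      post_events = cohort$post_events[cohort$post_events$patient_id %in% ids, , drop = FALSE],
      scores = cohort$scores[cohort$scores$patient_id %in% ids, , drop = FALSE],
      config = cohort$config
    )
    rownames(out$patients) <- rownames(out$events) <- NULL
    structure(out, class = "ehr_cohort")
  }
  list(derivation = subset_cohort(der_prac),
       validation = subset_cohort(setdiff(prac, der_prac)))
}
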