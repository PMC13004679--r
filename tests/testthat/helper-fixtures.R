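# shared fixtures, all generated in code

small_cohort <- function(n = 200, seed = 7, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}

# a hand-built two-cluster cohort for counting oracles: 6 patients,
# cluster 1 = patients 1-3, cluster 2 = patients 4-6
hand_cohort <- function() {
  patients <- data.frame(
    patient_id = 1:6,
    practice_id = c(1, 1, 2, 2, 3, 3),
    sex = c("F", "M", "F", "M", "F", "M"),
    birth_year = rep(1940L, 6),
    imd = c(1, 2, 3, 4, 5, 1),
    diagnosis_date = as.Date("2010-01-01"),
    age_at_diagnosis = rep(70, 6),
    death_time = c(1, 2, 3, 4, 5, 6),
    hospital_time = rep(2, 6),
    true_subtype = c(1, 1, 1, 2, 2, 2)
  )
  ev <- function(pid, days_before, code)
    data.frame(patient_id = pid, date = as.Date("2010-01-01") - days_before,
               code = code, domain = "diagnosis")
  events <- rbind(
    ev(1, 100, "A"), ev(1, 90, "B"),
    ev(2, 80, "A"),
    ev(3, 70, "A"), ev(3, 60, "C"),
    ev(4, 50, "B"),
    ev(5, 40, "B"), ev(5, 30, "C"),
    ev(6, 20, "B")
  )
  structure(list(patients = patients, events = events,
                 post_events = events[0, ], scores = NULL, config = NULL),
            class = "ehr_cohort")
}

# well-separated Gaussian blobs
make_blobs <- function(n_per = 100, centers, sd = 0.1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    matrix(stats::rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

toy_sequence <- function(tokens, patient_id = 1) {
  n <- length(tokens)
  structure(list(tokens = as.integer(tokens), ages = rep(70L, n),
                 years = rep(2010L, n), visit_index = rep(1L, n),
                 patient_id = patient_id), class = "token_sequence")
}
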