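test_that("TF-IDF follows the ln(N/df) construction", {
  co <- hand_cohort()
  # restrict to two patients: code A in both, B only in patient 4 (count 1)
  sub <- co
  sub$patients <- co$patients[c(1, 4), ]
  sub$events <- co$events[co$events$patient_id %in% c(1, 4), ]
  M <- tfidf_features(sub)
  expect_equal(unname(M[, "A"]), c(1 * log(2 / 1), 0))
  expect_true(all(M[, "B"] == 0))          # B carried by both patients: idf 0
  # a code present in every patient has idf = ln(1) = 0
  co2 <- sub
  co2$events <- rbind(sub$events,
                      data.frame(patient_id = 4, date = as.Date("2009-01-01"),
                                 code = "A", domain = "diagnosis"))
  expect_true(all(tfidf_features(co2)[, "A"] == 0))
  # counts scale the tf term: 3 occurrences of B in patient 2 of 2
  co3 <- sub
  co3$events <- rbind(sub$events[sub$events$code == "A", ],
                      data.frame(patient_id = 4,
                                 date = as.Date("2009-01-01") + 0:2,
                                 code = "B", domain = "diagnosis"))
  expect_equal(unname(tfidf_features(co3)["4", "B"]), 3 * log(2))
  expect_true(all(tfidf_features(co) >= 0))
})

test_that("a patient with no events gets a zero TF-IDF row", {
  co <- hand_cohort()
  co$events <- co$events[co$events$patient_id != 2, ]
  M <- tfidf_features(co)
  expect_true(all(M["2", ] == 0))
})

test_that("clinical features are exactly six z-scored columns", {
  co <- small_cohort(n = 80, seed = 21)
  M <- clinical_features(co)
  expect_identical(colnames(M),
                   c("age", "sex", "imd", "dx_year", "visit_freq", "cci2"))
  expect_lt(max(abs(colMeans(M))), 1e-10)
  expect_true(all(is.finite(M)))
})

test_that("visit frequency is distinct dates over observed lookback", {
  # 40 distinct visit dates spread over 20 years
  dates <- as.Date("1990-01-01") + round(seq(0, 20 * 365.25 - 400, length.out = 40))
  co <- list(
    patients = data.frame(patient_id = 1, practice_id = 1, sex = "F",
                          birth_year = 1930L, imd = 3,
                          diagnosis_date = dates[1] + round(20 * 365.25),
                          age_at_diagnosis = 70, death_time = 1,
                          hospital_time = 1, true_subtype = 1),
    events = data.frame(patient_id = 1, date = dates, code = "C001",
                        domain = "diagnosis"),
    post_events = NULL, scores = NULL, config = NULL)
  class(co) <- "ehr_cohort"
  vf <- ehrsubtype:::visit_frequency(co)
  lb <- as.numeric(co$patients$diagnosis_date - dates[1]) / 365.25
  expect_equal(vf, 40 / lb)
  expect_equal(vf, 2.0, tolerance = 0.15)
})

test_that("Charlson index counts distinct categories in the window once", {
  cm <- default_charlson_map()
  expect_equal(nrow(cm), 17)
  dx <- as.Date("2010-01-01")
  ev <- function(code, days_before)
    data.frame(patient_id = 1, date = dx - days_before, code = code,
               domain = "diagnosis")
  # no mapped codes
  expect_equal(charlson_index(ev("C099", 100), cm, diagnosis_date = dx), 0)
  # one weight-1 (myocardial infarction) + one weight-2 (renal) category
  e2 <- rbind(ev("C041", 100), ev("C053", 200))
  expect_equal(charlson_index(e2, cm, diagnosis_date = dx), 3)
  # repeat codes in one category count once
  e3 <- rbind(e2, ev("C041", 50))
  expect_equal(charlson_index(e3, cm, diagnosis_date = dx), 3)
  # events outside the 2-year window are excluded
  e4 <- ev("C041", round(3 * 365.25))
  expect_equal(charlson_index(e4, cm, diagnosis_date = dx), 0)
  # monotone: adding a mapped event never decreases the index
  e5 <- rbind(e2, ev("C056", 10))   # metastatic, weight 6
  expect_gte(charlson_index(e5, cm, diagnosis_date = dx),
             charlson_index(e2, cm, diagnosis_date = dx))
  expect_equal(charlson_index(e5, cm, diagnosis_date = dx), 9)
})

test_that("vectorized cohort-level Charlson agrees with the per-patient form", {
  co <- small_cohort(n = 60, seed = 31)
  cm <- default_charlson_map()
  all_cci <- ehrsubtype:::charlson_all(co, cm)
  per <- vapply(seq_len(60), function(i) {
    ev <- co$events[co$events$patient_id == co$patients$patient_id[i], ]
    charlson_index(ev, cm, diagnosis_date = co$patients$diagnosis_date[i])
  }, numeric(1))
  expect_equal(all_cci, per)
})

test_that("benchmark table has one row per representation and criterion", {
  co <- small_cohort(n = 150, seed = 41)
  reps <- list(tfidf = standardize_embeddings(tfidf_features(co)),
               clinical = clinical_features(co))
  tab <- benchmark_baselines(reps, k_range = 3:5, seed = 1, n_repeats = 2,
                             n_init = 4, B_bootstrap = 3)
  expect_equal(nrow(tab), 4)
  expect_setequal(unique(tab$representation), c("tfidf", "clinical"))
  expect_setequal(unique(tab$criterion), c("prediction_strength", "silhouette"))
  expect_true(all(tab$chosen_k %in% 3:5))
})

test_that("clinical baseline ignores code identities", {
  co <- small_cohort(n = 120, seed = 51)
  M1 <- clinical_features(co, code_map = data.frame(code = character(0),
                                                    category = character(0),
                                                    weight = numeric(0)))
  shuf <- co
  set.seed(1)
  perm <- sample(unique(co$events$code))
  names(perm) <- unique(co$events$code)
  shuf$events$code <- unname(perm[co$events$code])
  M2 <- clinical_features(shuf, code_map = data.frame(code = character(0),
                                                      category = character(0),
                                                      weight = numeric(0)))
  expect_equal(M1, M2)
  k1 <- kmeans_fit(M1, 3, seed = 5)
  k2 <- kmeans_fit(M2, 3, seed = 5)
  expect_identical(k1$assignments, k2$assignments)
})
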