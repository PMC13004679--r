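test_that("cohort generation is deterministic given the seed", {
  a <- small_cohort(n = 300, seed = 7)
  b <- small_cohort(n = 300, seed = 7)
  expect_identical(a$patients, b$patients)
  expect_identical(a$events, b$events)
  expect_identical(a$post_events, b$post_events)
  expect_identical(a$scores, b$scores)
  d <- small_cohort(n = 300, seed = 8)
  expect_false(identical(a$events, d$events))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 3, n_subtypes = 5), "n_patients")
  expect_error(cohort_config(100, subtype_weights = c(0.7, 0.2, 0.05, 0.03, 0.03)),
               "sum to 1")
  expect_error(cohort_config(100, subtype_weights = c(1.2, -0.2, 0, 0, 0) + 0.2),
               "\\[0, 1\\]")
  expect_error(cohort_config(100, hazard_mortality = c(-0.1, 0.1, 0.1, 0.1, 0.1)),
               "hazard")
  expect_error(cohort_config(100, n_subtypes = 1), "n_subtypes")
  expect_error(cohort_config(100, signature_prevalence = 1.3), "signature_matrix")
})

test_that("planted signature prevalences are recovered by direct counting", {
  cfg <- cohort_config(n_patients = 5000, seed = 3)
  co <- generate_cohort(cfg)
  ch <- code_channels(cfg)
  # spot-check one planted 0.90 cell per subtype against the counting oracle
  for (k in seq_len(cfg$n_subtypes)) {
    code <- ch$signature_by_subtype[[k]][1L]
    ids_k <- co$patients$patient_id[co$patients$true_subtype == k]
    carriers <- unique(co$events$patient_id[co$events$code == code])
    emp <- mean(ids_k %in% carriers)
    expect_lt(abs(emp - 0.90), 0.03)
    # a code planted only in subtype k never appears elsewhere
    other <- co$patients$patient_id[co$patients$true_subtype != k]
    expect_length(intersect(other, carriers), 0)
  }
  # generic 4-standard-error envelope over every planted cell
  for (k in seq_len(cfg$n_subtypes)) {
    ids_k <- co$patients$patient_id[co$patients$true_subtype == k]
    nk <- length(ids_k)
    for (code in ch$signature_by_subtype[[k]]) {
      emp <- mean(ids_k %in% co$events$patient_id[co$events$code == code])
      se <- sqrt(0.9 * 0.1 / nk)
      expect_lt(abs(emp - 0.9), 4 * se)
    }
  }
})

test_that("degenerate subtype weights put everyone in one subtype", {
  cfg <- cohort_config(n_patients = 100, subtype_weights = c(1, 0, 0, 0, 0),
                       seed = 1)
  co <- generate_cohort(cfg)
  expect_true(all(co$patients$true_subtype == 1L))
})

test_that("events are strictly prediagnostic and sorted; ages at least 40", {
  co <- small_cohort(n = 400, seed = 5)
  dd <- co$patients$diagnosis_date[match(co$events$patient_id,
                                         co$patients$patient_id)]
  expect_true(all(co$events$date < dd))
  by_pat <- split(as.numeric(co$events$date), co$events$patient_id)
  expect_true(all(vapply(by_pat, function(x) !is.unsorted(x), logical(1))))
  expect_true(all(co$patients$age_at_diagnosis >= 40))
  # post-diagnosis symptom store is disjoint from the prediagnostic events
  if (nrow(co$post_events)) {
    dd2 <- co$patients$diagnosis_date[match(co$post_events$patient_id,
                                            co$patients$patient_id)]
    expect_true(all(co$post_events$date >= dd2))
  }
})

test_that("higher planted mortality hazard gives shorter survival", {
  cfg <- cohort_config(n_patients = 2000, seed = 11)
  co <- generate_cohort(cfg)
  mean_surv <- tapply(co$patients$death_time, co$patients$true_subtype, mean)
  expect_equal(unname(which.min(mean_surv)), which.max(cfg$hazard_mortality))
  expect_equal(unname(which.max(mean_surv)), which.min(cfg$hazard_mortality))
})

test_that("genetics tables have planted structure and are reproducible", {
  cfg <- cohort_config(n_patients = 5000, prs_shift = rep(0, 5), seed = 2)
  co <- generate_cohort(cfg)
  g1 <- generate_genetics(co, cfg)
  g2 <- generate_genetics(co, cfg)
  expect_identical(g1, g2)
  expect_true(all(unlist(g1[grep("^dosage_", names(g1))]) %in% 0:2))
  expect_true(all(is.finite(g1$prs)))
  # no planted shift: case and control means agree closely at n = 5000
  expect_lt(abs(mean(g1$prs[!g1$is_control]) - mean(g1$prs[g1$is_control])), 0.1)
})

test_that("near-zero allele frequency gives near-zero dosages in that subtype", {
  freqs <- matrix(0.2, 5, 1)
  freqs[3, 1] <- 1e-9
  cfg <- cohort_config(n_patients = 500, snp_freqs = freqs, control_maf = 0.2,
                       seed = 4)
  co <- generate_cohort(cfg)
  g <- generate_genetics(co, cfg)
  in3 <- !g$is_control & g$true_subtype == 3
  expect_true(all(g$dosage_SNP1[in3] == 0))
})

test_that("practice split separates practices 80/20 and is seed-stable", {
  co <- small_cohort(n = 300, seed = 9, n_practices = 10)
  sp1 <- split_by_practice(co, seed = 42)
  sp2 <- split_by_practice(co, seed = 42)
  der_p <- unique(sp1$derivation$patients$practice_id)
  val_p <- unique(sp1$validation$patients$practice_id)
  expect_length(der_p, 8)
  expect_length(val_p, 2)
  expect_length(intersect(der_p, val_p), 0)
  expect_identical(sp1$derivation$patients$patient_id,
                   sp2$derivation$patients$patient_id)
  expect_setequal(c(sp1$derivation$patients$patient_id,
                    sp1$validation$patients$patient_id),
                  co$patients$patient_id)
  # events follow their patients
  expect_true(all(sp1$validation$events$patient_id %in%
                    sp1$validation$patients$patient_id))

  one <- co
  one$patients$practice_id <- 1L
  expect_error(split_by_practice(one), "one practice")
})
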