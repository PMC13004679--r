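test_that("prevalence table matches direct counting on the hand fixture", {
  co <- hand_cohort()
  labels <- co$patients$true_subtype
  pt <- prevalence_table(co, labels)
  # cluster 1 = patients 1-3: A in all, B in 1, C in 1 of 3
  expect_equal(unname(pt$p["1", c("A", "B", "C")]), c(1, 1 / 3, 1 / 3))
  # cluster 2 = patients 4-6: B in all, C in 1, A never
  expect_equal(unname(pt$p["2", c("A", "B", "C")]), c(0, 1, 1 / 3))
  expect_true(all(pt$p >= 0 & pt$p <= 1))
  # a never-recorded code is zero everywhere
  pt2 <- prevalence_table(co, labels, codes = c("A", "ZZZ"))
  expect_true(all(pt2$p[, "ZZZ"] == 0))
  expect_error(prevalence_table(co, labels[-1]), "cover")
})

test_that("variance filter keeps codes with range >= 0.15, boundary included", {
  tab <- structure(list(p = cbind(keep = c(0.50, 0.30),
                                  drop = c(0.40, 0.30),
                                  boundary = c(0.45, 0.30)),
                        sizes = c(10, 10), clusters = 1:2),
                   class = "prevalence_table")
  expect_setequal(variance_filter(tab), c("keep", "boundary"))
  expect_identical(variance_filter(tab, min_diff = 0.20), "keep")
  # invariant to cluster relabeling
  tab2 <- tab; tab2$p <- tab$p[2:1, ]
  expect_setequal(variance_filter(tab2), variance_filter(tab))
})

test_that("WDS matches the plug-in formula and vanishes under uniform prevalence", {
  p_uniform <- matrix(0.4, 5, 3, dimnames = list(1:5, c("a", "b", "c")))
  tab <- structure(list(p = p_uniform, sizes = rep(10, 5), clusters = 1:5),
                   class = "prevalence_table")
  expect_true(all(wds_scores(tab) == 0))

  p2 <- matrix(0.1, 5, 1, dimnames = list(1:5, "sig"))
  p2[1, 1] <- 0.9
  tab2 <- structure(list(p = p2, sizes = rep(10, 5), clusters = 1:5),
                    class = "prevalence_table")
  w <- wds_scores(tab2)
  expect_equal(unname(w[1, "sig"]), 0.9 * (0.9 - 0.1))
  # a code absent everywhere scores 0; rankings ignore added codes
  p3 <- cbind(p2, none = 0)
  tab3 <- structure(list(p = p3, sizes = rep(10, 5), clusters = 1:5),
                    class = "prevalence_table")
  w3 <- wds_scores(tab3)
  expect_true(all(w3[, "none"] == 0))
  expect_identical(top_discriminative(w3, 1)[["1"]]$code, "sig")
})

test_that("planted signature codes rank top by WDS in their own subtype", {
  cfg <- cohort_config(n_patients = 600, seed = 17)
  co <- generate_cohort(cfg)
  ch <- code_channels(cfg)
  pt <- prevalence_table(co, co$patients$true_subtype)
  w <- wds_scores(pt)
  tops <- top_discriminative(w, 5)
  for (k in seq_len(cfg$n_subtypes)) {
    expect_true(tops[[as.character(k)]]$code[1] %in% ch$signature_by_subtype[[k]])
  }
})

test_that("symptom trajectories bin by floor(days/365.25) and respect censoring", {
  co <- hand_cohort()
  dx <- co$patients$diagnosis_date[1]
  co$events <- rbind(co$events,
                     data.frame(patient_id = 1:3, date = dx - 100, code = "S1",
                                domain = "diagnosis"))
  # event 400 days post-diagnosis falls in bin +1
  co$post_events <- data.frame(patient_id = c(1, 2, 3), date = dx + 400,
                               code = "S1", domain = "diagnosis")
  labels <- co$patients$true_subtype
  tr <- symptom_trajectory(co, labels, "S1")
  expect_equal(tr$prevalence[tr$cluster == 1 & tr$year == -1 & tr$code == "S1"], 1)
  # death times 1,2,3y: only patient 3 (death 3y) survives into bin +1's start?
  # bin +1 needs death_time > 1: patients 2 (2y) and 3 (3y) are at risk
  row1 <- tr[tr$cluster == 1 & tr$year == 1, ]
  expect_equal(row1$n_at_risk, 2)
  expect_equal(row1$prevalence, 1)       # both at-risk patients have the event
  expect_warning(symptom_trajectory(co, labels, c("S1", "NOPE")), "unknown")
})

test_that("planted logistic symptom trends are recovered within sampling error", {
  cfg <- cohort_config(n_patients = 1500, seed = 23)
  co <- generate_cohort(cfg)
  ch <- code_channels(cfg)
  tr <- symptom_trajectory(co, co$patients$true_subtype, ch$symptom[1])
  for (k in c(1, cfg$n_subtypes)) {
    sub <- tr[tr$cluster == k & tr$code == ch$symptom[1], ]
    expected <- stats::plogis(cfg$symptom_intercept[k] +
                                cfg$symptom_slope[k] * sub$year)
    se <- sqrt(expected * (1 - expected) / sub$n_at_risk)
    expect_true(all(abs(sub$prevalence - expected) < 4 * se + 1e-9))
  }
})

test_that("Mann-Whitney score comparisons match the exact small-sample case", {
  scores <- data.frame(patient_id = 1:4, year = 1,
                       score = c(1, 2, 3, 4))
  st <- score_trend(scores, labels = c(1, 1, 2, 2), patient_ids = 1:4)
  expect_equal(st$tests$statistic, 0)
  expect_equal(st$tests$p_value, 1 / 3, tolerance = 1e-12)
  expect_named(st$trend, c("cluster", "year", "mean", "sem", "n"))
  # identical distributions: p well away from significance at moderate n
  set.seed(7)
  sc2 <- data.frame(patient_id = 1:200, year = 1, score = rnorm(200))
  st2 <- score_trend(sc2, labels = rep(1:2, each = 100), patient_ids = 1:200)
  expect_gt(st2$tests$p_value, 0.05)
})

test_that("planted cognitive-decline differences are detected post-diagnosis", {
  cfg <- cohort_config(n_patients = 800, seed = 29)
  co <- generate_cohort(cfg)
  st <- score_trend(co$scores, co$patients$true_subtype,
                    co$patients$patient_id)
  # fastest vs slowest declining subtype differ strongly
  p15 <- st$tests$p_value[st$tests$cluster_a == 1 & st$tests$cluster_b == 5]
  expect_lt(p15, 0.001)
  # yearly means decrease with year within the steepest subtype
  tr5 <- st$trend[st$trend$cluster == 5, ]
  expect_lt(stats::cor(tr5$year, tr5$mean), -0.9)
})

test_that("prototype selection takes the ceiling of 1% nearest the centroid", {
  set.seed(2)
  X <- rbind(matrix(rnorm(100 * 2, 0, 0.5), 100),
             matrix(rnorm(50 * 2, 8, 0.5), 50))
  co <- small_cohort(n = 150, seed = 61)
  fit <- kmeans_fit(X, 2, seed = 1)
  pr <- prototype_patients(fit, X, co, top_frac = 0.01)
  sizes <- tabulate(fit$assignments, 2)
  for (k in 1:2) {
    expect_equal(length(pr[[k]]$patient_ids), ceiling(0.01 * sizes[k]))
    # the selected member is the minimum-distance one
    idx <- which(fit$assignments == k)
    d <- sqrt(rowSums((X[idx, , drop = FALSE] -
                         matrix(fit$centroids[k, ], length(idx), 2,
                                byrow = TRUE))^2))
    expect_equal(pr[[k]]$patient_ids[1],
                 co$patients$patient_id[idx[which.min(d)]])
  }
  # a point exactly on the centroid is always selected
  X2 <- X; X2[5, ] <- fit$centroids[fit$assignments[5], ]
  fit2 <- fit
  pr2 <- prototype_patients(fit2, X2, co, top_frac = 0.01)
  expect_true(co$patients$patient_id[5] %in%
                unlist(lapply(pr2, `[[`, "patient_ids")))
})

test_that("Kruskal-Wallis utilization checks match hand rank arithmetic", {
  # groups {1,2} and {3,4}: H = 2.4
  kw <- stats::kruskal.test(c(1, 2, 3, 4), factor(c(1, 1, 2, 2)))
  expect_equal(unname(kw$statistic), 2.4)
  co <- hand_cohort()
  co$events <- rbind(co$events, data.frame(patient_id = rep(4:6, each = 3),
                                           date = as.Date("2009-06-01") + 1:9,
                                           code = "B", domain = "diagnosis"))
  ut <- utilization_tests(co, co$patients$true_subtype)
  expect_identical(ut$kruskal$outcome, c("visit_frequency", "record_count"))
  expect_true(all(is.finite(ut$kruskal$statistic)))
  expect_equal(nrow(ut$icc$per_cluster), 2)
  expect_true(all(ut$icc$per_cluster$icc >= 0 & ut$icc$per_cluster$icc <= 1))

  one <- co; one$patients$practice_id <- 1L
  expect_warning(ut1 <- utilization_tests(one, co$patients$true_subtype),
                 "single practice")
  expect_null(ut1$icc)
})
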