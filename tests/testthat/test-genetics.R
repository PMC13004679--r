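test_that("PRS pairwise contrasts follow Welch + BH + Cohen's d", {
  x <- c(1, 2, 3, 4, 5)
  out <- prs_pairwise(c(x, x), rep(1:2, each = 5))
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$cohens_d, 0)

  # exact d = 1: means 1 vs 0, both s.d. exactly 1
  a <- as.numeric(scale(rnorm(50))) + 1
  b <- as.numeric(scale(rnorm(50)))
  out2 <- prs_pairwise(c(a, b), rep(1:2, each = 50))
  expect_equal(out2$cohens_d, 1, tolerance = 1e-12)

  # q-values are BH over the whole family and never below p
  set.seed(5)
  prs <- rnorm(200)
  lab <- rep(1:4, each = 50)
  out3 <- prs_pairwise(prs, lab, control_prs = rnorm(100))
  expect_equal(nrow(out3), choose(4, 2) + 4)
  expect_true(all(out3$q_value >= out3$p_value - 1e-12))
  expect_equal(out3$q_value,
               stats::p.adjust(out3$p_value, method = "BH"))

  expect_error(prs_pairwise(rep(c(0, 1), each = 3), rep(1:2, each = 3)),
               "zero-variance")
})

test_that("BH step-up on the worked p-values gives 0.04 throughout", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # monotone and idempotent
  p <- sort(runif(20))
  q <- stats::p.adjust(p, method = "BH")
  expect_true(all(diff(q) >= -1e-12))
  expect_equal(stats::p.adjust(q, method = "BH"), q, tolerance = 1e-12)
})

test_that("one-vs-rest with K=2 reduces to the single pairwise test", {
  set.seed(7)
  prs <- rnorm(80)
  lab <- rep(1:2, each = 40)
  ovr <- prs_one_vs_rest(prs, lab)
  pw <- prs_pairwise(prs, lab)
  expect_equal(nrow(ovr), 2)
  expect_equal(ovr$p_value[1], pw$p_value[1], tolerance = 1e-12)
  # planted shift in one of four clusters is flagged
  prs2 <- rnorm(400) + rep(c(0.5, 0, 0, 0), each = 100)
  ovr2 <- prs_one_vs_rest(prs2, rep(1:4, each = 100))
  expect_lt(ovr2$p_value[1], 0.001)
})

test_that("dosage logistic regression matches a hand-rolled IRLS oracle", {
  set.seed(9)
  n <- 300
  g <- data.frame(dosage_SNP1 = rbinom(n, 2, 0.3), age = rnorm(n, 70, 5),
                  sex = rbinom(n, 1, 0.5), gpc1 = rnorm(n), gpc2 = rnorm(n),
                  gpc3 = rnorm(n))
  eta <- -1 + 0.6 * g$dosage_SNP1 + 0.3 * g$gpc1
  lab <- ifelse(runif(n) < plogis(eta), 1L, 2L)
  res <- snp_logistic(g, lab)
  expect_equal(nrow(res), 2)

  # IRLS oracle for the cluster-1 indicator
  X <- cbind(1, g$dosage_SNP1, g$age, g$sex, g$gpc1, g$gpc2, g$gpc3)
  y <- as.integer(lab == 1L)
  beta <- rep(0, ncol(X))
  for (it in 1:50) {
    mu <- plogis(X %*% beta)
    W <- as.numeric(mu * (1 - mu))
    z <- X %*% beta + (y - mu) / W
    beta <- solve(t(X) %*% (X * W), t(X) %*% (z * W))
  }
  expect_equal(log(res$or[res$cluster == 1]), beta[2], tolerance = 1e-6)
  expect_true(all(res$p_bonferroni >= res$p_value - 1e-12))
  expect_true(all(res$p_bonferroni <= 1))
  expect_true(all(res$lower <= res$or & res$or <= res$upper))

  g$dosage_SNP1[1] <- 3
  expect_error(snp_logistic(g, lab), "0, 1 or 2")
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  # [[2,0],[0,2]]: two-sided p = 1/3
  out <- fisher_pairwise(c(TRUE, TRUE, FALSE, FALSE), c(1, 1, 2, 2))
  expect_equal(out$p_value, 1 / 3, tolerance = 1e-12)
  # balanced null table: p = 1
  out2 <- fisher_pairwise(rep(c(TRUE, FALSE), 10), rep(1:2, each = 10))
  expect_equal(out2$p_value, 1)

  # enumeration oracle over random tables with n <= 40
  enum_fisher <- function(tab) {
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    amin <- max(0, k - n2); amax <- min(k, m)
    probs <- stats::dhyper(amin:amax, m, n2, k)
    p_obs <- stats::dhyper(tab[1, 1], m, n2, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(11)
  for (rep in 1:25) {
    na <- sample(2:20, 1); nb <- sample(2:20, 1)
    ca <- rbinom(1, na, 0.4); cb <- rbinom(1, nb, 0.4)
    carrier <- c(rep(TRUE, ca), rep(FALSE, na - ca),
                 rep(TRUE, cb), rep(FALSE, nb - cb))
    lab <- rep(1:2, c(na, nb))
    got <- fisher_pairwise(carrier, lab)
    tab <- matrix(c(ca, na - ca, cb, nb - cb), 2, byrow = TRUE)
    expect_equal(got$p_value, enum_fisher(tab), tolerance = 1e-7)
  }
  # Haldane-corrected sample OR for zero cells is finite
  expect_true(is.finite(out$or))
  expect_gt(out$or, 1)
})

test_that("carrier enrichment is prevalence over population MAF", {
  carrier <- rep(c(TRUE, FALSE), c(30, 70))
  ce <- carrier_enrichment(carrier, rep(1, 100), population_maf = 0.15)
  expect_equal(ce$enrichment, 2.0)
  ce0 <- carrier_enrichment(rep(FALSE, 50), rep(1, 50), population_maf = 0.2)
  expect_equal(ce0$enrichment, 0)
  expect_error(carrier_enrichment(carrier, rep(1, 100), population_maf = 0),
               "> 0")
})

test_that("planted genetic structure is recovered end to end", {
  cfg <- cohort_config(n_patients = 2000, seed = 37)
  co <- generate_cohort(cfg)
  g <- generate_genetics(co, cfg)
  cases <- g[!g$is_control, ]
  # PRS one-vs-rest flags the extreme subtypes (shifts +0.5 and -0.5)
  ovr <- prs_one_vs_rest(cases$prs, cases$true_subtype)
  expect_lt(ovr$p_value[1], 1e-4)
  expect_lt(ovr$p_value[5], 1e-4)
  # SNP1 frequency doubled in subtype 1: positive dosage association
  res <- snp_logistic(cases, cases$true_subtype, snps = "dosage_SNP1")
  r1 <- res[res$cluster == 1, ]
  expect_true(r1$converged)
  expect_gt(r1$or, 1)
  expect_lt(r1$p_value, 0.01)
  # carrier enrichment reflects the planted MAF ratio
  ce <- carrier_enrichment(cases$dosage_SNP1 >= 1, cases$true_subtype,
                           population_maf = cfg$control_maf[1])
  expect_gt(ce$enrichment[1], max(ce$enrichment[3:5]))
})
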