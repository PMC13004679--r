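#' Build a five-year survival table for a cohort
#'
#' Event times beyond the horizon are administratively censored at the
#' horizon (so no event beyond five years contributes an event); covariates
#' are age, sex, IMD, diagnosis calendar year, mean annual visit frequency
#' and the 2-year Charlson index.
#'
#' @param cohort an `ehr_cohort`.
#' @param labels cluster labels aligned with `cohort$patients`.
#' @param outcome `"mortality"` or `"hospitalization"`.
#' @param horizon administrative censoring time in years.
#' @param code_map Charlson map for the CCI covariate.
#' @return data.frame patient_id / time / event / group / covariates.
#' @export
survival_data <- function(cohort, labels,
                          outcome = c("mortality", "hospitalization"),
                          horizon = 5, code_map = default_charlson_map()) {
  outcome <- match.arg(outcome)
  p <- cohort$patients
  raw <- if (outcome == "mortality") p$death_time else p$hospital_time
  if (any(raw < 0, na.rm = TRUE)) stopf("negative event time")
  time <- pmin(raw, horizon)
  event <- as.integer(!is.na(raw) & raw <= horizon)
  time[is.na(time)] <- horizon
  time <- pmax(time, 1e-6)
  cci <- charlson_all(cohort, code_map)
  data.frame(
    patient_id = p$patient_id, time = time, event = event,
    group = factor(labels),
    age = p$age_at_diagnosis, sex = as.numeric(p$sex == "M"), imd = p$imd,
    dx_year = as.integer(format(p$diagnosis_date, "%Y")),
    visit_freq = visit_frequency(cohort), cci2 = cci)
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate with Greenwood variance and log-log 95% confidence
#' limits.
#'
#' @param times nonnegative follow-up times.
#' @param events 0/1 event indicators.
#' @return object of class `km_curve`: data.frame time / n_risk / n_event /
#'   surv / lower / upper.
#' @export
kaplan_meier <- function(times, events) {
  if (any(times < 0)) stopf("negative time in Kaplan-Meier input")
  if (!length(times)) stopf("empty survival input")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    lower = fit$lower, upper = fit$upper)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Global and pairwise log-rank tests
#'
#' Standard log-rank with hypergeometric variance; the global statistic has
#' `G - 1` degrees of freedom. Pairwise p-values are reported unadjusted,
#' with a BH-adjusted column alongside.
#'
#' @param times,events follow-up times and 0/1 indicators.
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with `statistic`, `df`, `p_value` and data.frame `pairwise`
#'   (group_a, group_b, statistic, p_value, p_bh).
#' @export
logrank <- function(times, events, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stopf("log-rank requires at least 2 groups")
  groups <- droplevels(groups)
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd_fit$n) - 1L
  p_global <- stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE)
  lv <- levels(groups)
  pw <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    sel <- groups %in% c(lv[i], lv[j])
    sij <- survival::survdiff(survival::Surv(times[sel], events[sel]) ~
                                droplevels(groups[sel]))
    pw[[length(pw) + 1L]] <- data.frame(
      group_a = lv[i], group_b = lv[j], statistic = sij$chisq,
      p_value = stats::pchisq(sij$chisq, 1L, lower.tail = FALSE))
  }
  pw <- do.call(rbind, pw)
  pw$p_bh <- stats::p.adjust(pw$p_value, method = "BH")
  list(statistic = unname(sd_fit$chisq), df = df, p_value = p_global,
       pairwise = pw)
}

#' Adjusted Cox proportional-hazards model across clusters
#'
#' Partial-likelihood fit with Efron tie handling; cluster 1 is the
#' reference, covariates enter additively, and Wald 95% confidence intervals
#' are reported on the hazard-ratio scale.
#'
#' @param data a [survival_data()] table.
#' @param covariates covariate column names to adjust for.
#' @return object of class `cox_fit`: list with the coefficient `table`
#'   (term, coef, hr, lower, upper, p_value) and the underlying
#'   `survival::coxph` fit.
#' @export
cox_fit <- function(data, covariates = c("age", "sex", "imd", "dx_year",
                                         "visit_freq", "cci2")) {
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(data[[v]])) > 1L, logical(1))]
  if (sum(data$event) < nlevels(data$group) - 1L + length(covariates))
    stopf("too few events for the number of parameters")
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ group",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- survival::coxph(fml, data = data, ties = "efron",
                         control = survival::coxph.control(iter.max = 100L))
  if (any(!is.finite(stats::coef(fit))) || any(sqrt(diag(fit$var)) > 1e3))
    stopf("Cox model did not converge (possible separation)")
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    lower = s$conf.int[, "lower .95"],
    upper = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL)
  structure(list(table = tab, fit = fit), class = "cox_fit")
}

#' @exportS3Method print cox_fit
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties)\n")
  print(within(x$table, {
    hr <- round(hr, 3); lower <- round(lower, 3); upper <- round(upper, 3)
    coef <- round(coef, 3); p_value <- signif(p_value, 3)
  }), row.names = FALSE)
  invisible(x)
}

#' Proportional-hazards diagnostics
#'
#' Scaled Schoenfeld-residual correlation-with-time test per covariate.
#'
#' @param fit a [cox_fit()].
#' @return data.frame term / chisq / df / p_value (one row per model term
#'   plus GLOBAL).
#' @export
proportional_hazards_check <- function(fit) {
  z <- survival::cox.zph(fit$fit)
  data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
             df = z$table[, "df"], p_value = z$table[, "p"],
             row.names = NULL)
}
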