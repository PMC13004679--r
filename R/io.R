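#' Write a cohort to a directory of flat tables
#'
#' Emits `patients`, `events`, `post_events` and `scores` tables plus a
#' separate `truth` table holding the hidden subtype labels (the pipeline
#' never reads it), and the generating configuration as YAML. Format is CSV
#' (`"parquet"` also supported when the arrow package is installed).
#'
#' @param cohort an `ehr_cohort`.
#' @param dir output directory (created if absent).
#' @param format `"csv"` or `"parquet"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (format == "csv")
      utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
    else {
      if (!requireNamespace("arrow", quietly = TRUE))
        stopf("parquet output requires the arrow package")
      arrow::write_parquet(df, file.path(dir, paste0(name, ".parquet")))
    }
  }
  pats <- cohort$patients
  truth <- pats[, c("patient_id", "true_subtype")]
  pats$true_subtype <- NULL
  wr(pats, "patients"); wr(cohort$events, "events")
  wr(cohort$post_events, "post_events"); wr(cohort$scores, "scores")
  wr(truth, "truth")
  cfg <- cohort$config
  cfg$signature_matrix <- apply(cfg$signature_matrix, 1L, identity, simplify = FALSE)
  cfg$snp_freqs <- apply(cfg$snp_freqs, 1L, identity, simplify = FALSE)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("schema error in %s: missing required column(s) %s",
          what, paste(miss, collapse = ", "))
  invisible(df)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' Validates the schemas (missing required columns raise a named error),
#' restores date columns, and re-sorts events by patient and date with a
#' warning if they arrive unsorted. The `truth` table is not read.
#'
#' @param dir directory containing the tables.
#' @return an `ehr_cohort` (without hidden labels or config unless present).
#' @export
read_cohort <- function(dir) {
  rd <- function(name, required = TRUE) {
    f <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(f)) {
      if (required) stopf("missing table: %s", f)
      return(NULL)
    }
    utils::read.csv(f, stringsAsFactors = FALSE)
  }
  patients <- check_columns(rd("patients"),
                            c("patient_id", "practice_id", "sex", "birth_year",
                              "diagnosis_date"), "patients")
  events <- check_columns(rd("events"), c("patient_id", "date", "code"),
                          "events")
  patients$diagnosis_date <- as.Date(patients$diagnosis_date)
  events$date <- as.Date(events$date)
  o <- order(events$patient_id, events$date, events$code)
  if (any(o != seq_along(o))) {
    warnf("events arrived unsorted; sorting by patient and date")
    events <- events[o, , drop = FALSE]
    rownames(events) <- NULL
  }
  post_events <- rd("post_events", required = FALSE)
  if (!is.null(post_events) && nrow(post_events))
    post_events$date <- as.Date(post_events$date)
  scores <- rd("scores", required = FALSE)
  cfg_file <- file.path(dir, "config.yaml")
  config <- if (file.exists(cfg_file)) yaml::read_yaml(cfg_file) else NULL
  structure(list(patients = patients, events = events,
                 post_events = post_events %||%
                   data.frame(patient_id = integer(0), date = as.Date(character(0)),
                              code = character(0), domain = character(0)),
                 scores = scores, config = config),
            class = "ehr_cohort")
}

#' Serialize a selection report (and other results) to JSON
#'
#' @param fit an `ehr_subtype` fit.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(fit, path) {
  rep <- fit$report
  out <- list(
    chosen_k = fit$chosen_k,
    fallback_used = rep$fallback_used,
    threshold = rep$threshold,
    ps_by_k = as.list(rep$ps_by_k),
    silhouette = rep$silhouette,
    davies_bouldin = rep$davies_bouldin,
    bootstrap_ari = rep$bootstrap_ari,
    pac = rep$pac,
    masked_loss = fit$masked_loss,
    contrastive_loss = fit$contrastive_loss,
    cluster_sizes = as.list(tabulate(fit$labels, fit$chosen_k)),
    confidence_summary = rep$confidence_summary,
    seed = fit$seed,
    elapsed_seconds = fit$elapsed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Plot Kaplan-Meier curves per group with confidence bands
#'
#' @param data a [survival_data()] table.
#' @param main plot title.
#' @return invisibly, the list of per-group [kaplan_meier()] curves.
#' @export
plot_km_curves <- function(data, main = "5-year outcome by subtype") {
  grs <- levels(data$group)
  cols <- grDevices::hcl.colors(length(grs), "Dark 3")
  graphics::plot(NULL, xlim = c(0, max(data$time)), ylim = c(0, 1),
                 xlab = "years since diagnosis", ylab = "survival", main = main)
  curves <- list()
  for (i in seq_along(grs)) {
    sel <- data$group == grs[i]
    km <- kaplan_meier(data$time[sel], data$event[sel])
    xs <- c(0, rep(km$time, each = 2))
    ys <- c(1, 1, rep(km$surv[-nrow(km)], each = 2), km$surv[nrow(km)])
    ok <- !is.na(km$lower)
    graphics::polygon(c(km$time[ok], rev(km$time[ok])),
                      c(km$lower[ok], rev(km$upper[ok])),
                      col = grDevices::adjustcolor(cols[i], 0.15), border = NA)
    graphics::lines(xs, ys, col = cols[i], lwd = 2)
    curves[[grs[i]]] <- km
  }
  graphics::legend("bottomleft", legend = grs, col = cols, lwd = 2, bty = "n")
  invisible(curves)
}

#' Heatmap of per-cluster code prevalence
#'
#' @param table a [prevalence_table()] (typically after [variance_filter()]).
#' @param codes optional code subset to display.
#' @return invisibly, the plotted matrix.
#' @export
plot_prevalence_heatmap <- function(table, codes = NULL) {
  P <- table$p
  if (!is.null(codes)) P <- P[, codes, drop = FALSE]
  op <- graphics::par(mar = c(6, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(P)), seq_len(nrow(P)), t(P), zlim = c(0, 1),
                  col = grDevices::hcl.colors(50, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "cluster",
                  main = "comorbidity prevalence by cluster")
  graphics::axis(1, seq_len(ncol(P)), colnames(P), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(P)), rownames(P))
  invisible(P)
}
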