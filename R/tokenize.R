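#' Build a code vocabulary from a cohort
#'
#' Token ids are dense and 0-based with five fixed special tokens:
#' PAD = 0, MASK = 1, UNK = 2, CLS = 3, SEP = 4; clinical codes start at id 5,
#' ordered by corpus frequency (descending) with lexical tie-break, so the
#' mapping is deterministic for a given cohort.
#'
#' @param cohort an `ehr_cohort` (or anything with an `events` data frame).
#' @param min_count codes seen fewer than `min_count` times map to UNK.
#' @return object of class `ehr_vocab`: list with `map` (named integer vector
#'   code -> id), `specials`, `size`.
#' @export
build_vocabulary <- function(cohort, min_count = 1L) {
  events <- if (is.data.frame(cohort)) cohort else cohort$events
  if (is.null(events) || !nrow(events)) stopf("cannot build vocabulary: empty cohort")
  tab <- table(events$code)
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab))
  codes <- names(tab)[ord]
  specials <- c(PAD = 0L, MASK = 1L, UNK = 2L, CLS = 3L, SEP = 4L)
  map <- if (length(codes)) stats::setNames(seq_along(codes) + 4L, codes) else integer(0)
  structure(list(map = map, specials = specials, size = length(map) + 5L),
            class = "ehr_vocab")
}

#' @exportS3Method print ehr_vocab
print.ehr_vocab <- function(x, ...) {
  cat(sprintf("EHR vocabulary: %d code tokens + 5 specials (size %d)\n",
              length(x$map), x$size))
  invisible(x)
}

vocab_lookup <- function(vocab, codes) {
  id <- unname(vocab$map[codes])
  id[is.na(id)] <- vocab$specials[["UNK"]]
  id
}

#' Encode one patient's events as a token sequence
#'
#' Events sharing a calendar date form one visit. The sequence is
#' `CLS, codes(visit 1), SEP, codes(visit 2), SEP, ...` with parallel streams:
#' integer age at the visit (floor of fractional years since birth), calendar
#' year, and the visit ordinal. If the sequence exceeds `max_len` it is
#' truncated from the left (oldest tokens dropped, CLS re-prepended), keeping
#' the most recent, diagnosis-proximal history.
#'
#' @param record one-row slice of `cohort$patients`.
#' @param events that patient's events (data.frame with date, code).
#' @param vocab an `ehr_vocab`; unknown codes map to UNK.
#' @param max_len maximum sequence length.
#' @return object of class `token_sequence`: list with integer vectors
#'   `tokens`, `ages`, `years`, `visit_index` (equal length <= max_len) and
#'   `patient_id`.
#' @export
encode_patient <- function(record, events, vocab, max_len = 256L) {
  if (is.null(events) || !nrow(events)) stopf("patient has no events to encode")
  events <- events[order(events$date, events$code), , drop = FALSE]
  birth <- as.Date(sprintf("%d-01-01", record$birth_year))
  sp <- vocab$specials

  dnum <- as.numeric(events$date)
  rl <- rle(dnum)
  n_vis <- length(rl$values)
  vis_of_event <- rep.int(seq_len(n_vis), rl$lengths)
  # event ids with a SEP appended at the end of each visit
  ins <- cumsum(rl$lengths)                 # positions after which SEP goes
  m <- length(dnum) + n_vis
  is_sep <- logical(m); is_sep[ins + seq_len(n_vis)] <- TRUE
  toks <- integer(m)
  toks[!is_sep] <- vocab_lookup(vocab, events$code)
  toks[is_sep] <- sp[["SEP"]]
  vis <- integer(m)
  vis[!is_sep] <- vis_of_event
  vis[is_sep] <- seq_len(n_vis)
  vdates <- rl$values
  age_by_vis <- as.integer(floor((vdates - as.numeric(birth)) / DAYS_PER_YEAR))
  yr_by_vis <- as.integer(format(as.Date(vdates, origin = "1970-01-01"), "%Y"))
  ages <- age_by_vis[vis]
  yrs <- yr_by_vis[vis]
  if (length(toks) > max_len - 1L) {
    keep <- (length(toks) - (max_len - 2L)):length(toks)
    toks <- toks[keep]; ages <- ages[keep]; yrs <- yrs[keep]; vis <- vis[keep]
  }
  structure(list(
    tokens = c(sp[["CLS"]], toks),
    ages = c(ages[1L], ages),
    years = c(yrs[1L], yrs),
    visit_index = c(vis[1L], vis),
    patient_id = record$patient_id
  ), class = "token_sequence")
}

#' Encode every patient in a cohort
#'
#' @inheritParams encode_patient
#' @param cohort an `ehr_cohort`.
#' @return list of `token_sequence`, one per patient with >= 1 event,
#'   in `cohort$patients` row order.
#' @export
encode_cohort <- function(cohort, vocab, max_len = 256L) {
  ev_split <- split(cohort$events, cohort$events$patient_id)
  out <- vector("list", nrow(cohort$patients))
  for (i in seq_len(nrow(cohort$patients))) {
    rec <- cohort$patients[i, ]
    ev <- ev_split[[as.character(rec$patient_id)]]
    if (is.null(ev) || !nrow(ev)) stopf("patient %s has no events", rec$patient_id)
    out[[i]] <- encode_patient(rec, ev, vocab, max_len)
  }
  out
}

#' Decode a token sequence back to code labels
#'
#' Drops special tokens; the result is the retained event codes in order.
#' @param seq a `token_sequence`.
#' @param vocab the `ehr_vocab` used to encode it.
#' @return character vector of codes (`"<UNK>"` for unknown-code tokens).
#' @export
decode_tokens <- function(seq, vocab) {
  rev_map <- stats::setNames(names(vocab$map), vocab$map)
  ids <- seq$tokens[seq$tokens >= 5L]
  unname(rev_map[as.character(ids)])
}

#' Pad token sequences into a rectangular integer matrix
#'
#' PAD (id 0) is appended only as a suffix; used for serialization.
#' @param sequences list of `token_sequence`.
#' @param max_len pad/truncate width (default: longest sequence).
#' @return list of integer matrices `tokens`, `ages`, `years`, `visit_index`
#'   (n x max_len) plus `lengths` and `patient_ids`.
#' @export
pad_sequences <- function(sequences, max_len = NULL) {
  lens <- vapply(sequences, function(s) length(s$tokens), integer(1))
  L <- max_len %||% max(lens)
  pack <- function(field, fill = 0L) {
    m <- matrix(fill, length(sequences), L)
    for (i in seq_along(sequences)) {
      v <- sequences[[i]][[field]][seq_len(min(lens[i], L))]
      m[i, seq_along(v)] <- v
    }
    m
  }
  list(tokens = pack("tokens"), ages = pack("ages"), years = pack("years"),
       visit_index = pack("visit_index"), lengths = pmin(lens, L),
       patient_ids = vapply(sequences, function(s) s$patient_id, numeric(1)))
}

#' Write / read a vocabulary as JSON
#' @param vocab an `ehr_vocab`; `path` a file path.
#' @return `read_vocabulary` returns an `ehr_vocab`.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(list(map = as.list(vocab$map),
                            specials = as.list(vocab$specials)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path)
  map <- stats::setNames(as.integer(unlist(x$map)), names(x$map))
  structure(list(map = map,
                 specials = stats::setNames(as.integer(unlist(x$specials)),
                                            names(x$specials)),
                 size = length(map) + 5L),
            class = "ehr_vocab")
}
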