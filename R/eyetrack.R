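# Interest-area fixation report ingestion, outlier filtering, and
# dependent-variable derivation for word-level reading measures.

.IA_REQUIRED <- c("subject", "language", "trial", "ia_index", "word",
                  "ffd", "gaze", "tfd", "nfix_firstrun", "nfix_total")

#' Read an interest-area fixation report
#'
#' Reads a MECO-style word-level fixation report (CSV or TSV by extension).
#' Required columns: `subject`, `language`, `trial`, `ia_index` (0-based word
#' position), `word`, `ffd`, `gaze`, `tfd` (durations in milliseconds; blank
#' or NA when the word received no such fixation), `nfix_firstrun`,
#' `nfix_total`. Derives `skipped_first_run` (no first-pass fixation) and
#' `reread` (gaze returned after the first pass: total time exceeds gaze, or
#' the word was fixated only after the first pass).
#'
#' @param path File path (`.csv` or `.tsv`).
#' @return Tibble of interest-area records.
#' @export
read_ia_report <- function(path) {
  if (!file.exists(path)) wi_abort(sprintf("No such file: %s", path), "wordinfo_io_error")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(.IA_REQUIRED, names(raw))
  if (length(missing_cols)) {
    wi_abort(sprintf("IA report lacks required column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "wordinfo_schema_error")
  }
  num_cols <- c("ffd", "gaze", "tfd", "nfix_firstrun", "nfix_total")
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(vals))
    if (length(bad)) {
      wi_abort(sprintf("Non-numeric %s value '%s' at row %d.",
                       col, raw[[col]][bad[1]], bad[1]),
               "wordinfo_parse_error")
    }
    raw[[col]] <- vals
  }
  raw$ia_index <- as.integer(raw$ia_index)
  out <- tibble::as_tibble(raw)
  as_ia_records(out)
}

#' Normalize a data frame into interest-area records
#'
#' Checks duration ordering (`ffd <= gaze <= tfd` where present) and derives
#' `skipped_first_run` and `reread`. Exposed so programmatically built data
#' (e.g. from the synthetic generator) goes through the same contract as
#' files.
#'
#' @param df Data frame with the [read_ia_report()] column contract.
#' @return Tibble of interest-area records.
#' @export
as_ia_records <- function(df) {
  df <- tibble::as_tibble(df)
  ok <- is.na(df$tfd) |
    ((is.na(df$ffd) | is.na(df$gaze) | df$ffd <= df$gaze) &
       (is.na(df$gaze) | df$gaze <= df$tfd))
  if (any(!ok)) {
    wi_abort(sprintf("Duration ordering ffd <= gaze <= tfd violated at row %d.",
                     which(!ok)[1]),
             "wordinfo_schema_error")
  }
  df$skipped_first_run <- df$nfix_firstrun == 0 | is.na(df$ffd)
  df$reread <- !is.na(df$tfd) & (is.na(df$gaze) | df$tfd > df$gaze)
  df
}

#' Filter interest areas with implausible fixation times
#'
#' Removes fixated interest areas with total fixation time shorter than 80 ms
#' or longer than 2000 ms, first fixation duration longer than 800 ms, or
#' gaze duration longer than 1000 ms — values that plausibly reflect tracker
#' failure rather than reading. All comparisons are strict, exactly as worded
#' (80 ms itself is kept, 2000 ms itself is kept). Skipped words (no
#' fixations at all) carry no durations and are always retained.
#'
#' @param records Interest-area tibble (see [read_ia_report()]).
#' @return A list: `kept` (retained records) and `log`, a tibble of per-rule
#'   removal counts plus the overall proportion removed.
#' @export
filter_ia <- function(records) {
  tfd_short <- !is.na(records$tfd) & records$tfd < 80
  tfd_long  <- !is.na(records$tfd) & records$tfd > 2000
  ffd_long  <- !is.na(records$ffd) & records$ffd > 800
  gaze_long <- !is.na(records$gaze) & records$gaze > 1000
  drop <- tfd_short | tfd_long | ffd_long | gaze_long
  log <- tibble::tibble(
    rule = c("tfd < 80 ms", "tfd > 2000 ms", "ffd > 800 ms", "gaze > 1000 ms", "total"),
    n_removed = c(sum(tfd_short), sum(tfd_long), sum(ffd_long), sum(gaze_long), sum(drop)),
    proportion = c(rep(NA_real_, 4), if (nrow(records)) sum(drop) / nrow(records) else 0)
  )
  list(kept = records[!drop, , drop = FALSE], log = log)
}

#' Derive the five dependent variables
#'
#' Adds to filtered records: `skip` (first-run skipping, 0/1, defined for all
#' words), and — for words fixated at least once — `log_ffd`, `log_gaze`,
#' `log_tfd` (natural logs of the millisecond durations) and `reread` (0/1,
#' total time exceeding gaze duration). Durational measures stay `NA` for
#' never-fixated words.
#'
#' @param records Filtered interest-area tibble.
#' @return The tibble with DV columns appended.
#' @export
derive_dvs <- function(records) {
  fixated <- !is.na(records$tfd)
  records$skip <- as.integer(records$skipped_first_run)
  records$log_ffd <- ifelse(!is.na(records$ffd), log(records$ffd), NA_real_)
  records$log_gaze <- ifelse(!is.na(records$gaze), log(records$gaze), NA_real_)
  records$log_tfd <- ifelse(fixated, log(records$tfd), NA_real_)
  records$reread <- ifelse(fixated, as.integer(records$reread), NA_integer_)
  records
}

#' Composite reading-skill score
#'
#' Standardizes each individual-differences test over the analysis sample and
#' averages the z-scores into one composite per subject (tests the subject is
#' missing are dropped from that subject's mean, with the count recorded).
#' The canonical battery is five English tests — timed word naming, timed
#' nonword naming, spelling, lexical decision accuracy, vocabulary — but any
#' numeric test columns work.
#'
#' @param scores Tibble with `subject` plus one numeric column per test.
#' @param tests Character vector of test column names (default: all numeric
#'   columns except `subject`).
#' @return `scores` with `z_<test>` columns, `n_tests` and `composite`.
#' @export
composite_skill <- function(scores, tests = NULL) {
  stopifnot("subject" %in% names(scores))
  if (nrow(scores) < 2L) {
    wi_abort("Z-standardization needs at least 2 subjects.", "wordinfo_domain_error")
  }
  if (is.null(tests)) {
    tests <- names(scores)[vapply(scores, is.numeric, logical(1))]
    tests <- setdiff(tests, "subject")
  }
  zmat <- sapply(tests, function(t) {
    x <- scores[[t]]
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      wi_warn(sprintf("Test '%s' is constant across subjects; its z-score is undefined.", t),
              "wordinfo_undefined_z")
      return(rep(NA_real_, length(x)))
    }
    (x - mean(x, na.rm = TRUE)) / s
  })
  zmat <- matrix(zmat, nrow = nrow(scores),
                 dimnames = list(NULL, paste0("z_", tests)))
  out <- dplyr::bind_cols(scores, tibble::as_tibble(zmat))
  out$n_tests <- rowSums(!is.na(zmat))
  out$composite <- rowMeans(zmat, na.rm = TRUE)
  out$composite[out$n_tests == 0] <- NA_real_
  out
}
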