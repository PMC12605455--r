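# Frequency transforms and per-language descriptive analytics.

#' Construct a word-frequency table
#'
#' @param counts Named integer vector (word -> count).
#' @param total_tokens Corpus size in tokens; may exceed the sum of listed
#'   counts (totals can include unlisted tokens).
#' @param language Language code.
#' @return An object of class `wi_freq_table`.
#' @export
freq_table <- function(counts, total_tokens = sum(counts), language = "und") {
  stopifnot(!is.null(names(counts)), all(counts >= 0), total_tokens > 0)
  structure(list(language = language, counts = counts,
                 total_tokens = as.numeric(total_tokens)),
            class = "wi_freq_table")
}

#' Read a frequency table from TSV
#'
#' Two columns (word, count), with an optional header comment line
#' `#total_tokens=N`; without it the total defaults to the sum of counts.
#'
#' @param path File path.
#' @param language Language code to attach.
#' @return A [freq_table()].
#' @export
read_freq_table <- function(path, language = "und") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  total <- NA_real_
  meta <- grep("^#total_tokens=", lines, value = TRUE)
  if (length(meta)) total <- as.numeric(sub("^#total_tokens=", "", meta[1]))
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  counts <- as.integer(vapply(parts, `[[`, character(1), 2L))
  names(counts) <- vapply(parts, `[[`, character(1), 1L)
  freq_table(counts, total_tokens = if (is.na(total)) sum(counts) else total,
             language = language)
}

#' Write a frequency table to TSV
#' @param table A [freq_table()].
#' @param path Output path.
#' @export
write_freq_table <- function(table, path) {
  stopifnot(inherits(table, "wi_freq_table"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#total_tokens=%s", format(table$total_tokens, scientific = FALSE)), con)
  writeLines(paste(names(table$counts), table$counts, sep = "\t"), con)
  invisible(path)
}

#' Zipf-transformed word frequency
#'
#' `log10` of frequency per billion tokens. With Laplace smoothing
#' (`smoothing = 1`, the default) out-of-vocabulary words get a finite value:
#' `log10((count + s) / (total_tokens + s * V) * 1e9)` with `V` the listed
#' vocabulary size. Set `smoothing = 0` for the plain per-billion transform
#' (a word occurring once per million tokens then scores 3.0).
#'
#' @param word_core Word (vectorized); looked up exactly, then case-folded.
#' @param table A [freq_table()].
#' @param smoothing Laplace pseudo-count `s` (default 1).
#' @return Numeric Zipf value(s).
#' @export
zipf <- function(word_core, table, smoothing = 1) {
  stopifnot(inherits(table, "wi_freq_table"), table$total_tokens > 0)
  idx <- match(word_core, names(table$counts))
  miss <- is.na(idx)
  idx[miss] <- match(tolower(word_core[miss]), names(table$counts))
  count <- ifelse(is.na(idx), 0, table$counts[replace(idx, is.na(idx), 1L)])
  v <- length(table$counts)
  log10((count + smoothing) / (table$total_tokens + smoothing * v) * 1e9)
}

#' Correlate informativeness with a covariate
#'
#' Pearson (default) or Spearman correlation between the informativeness of
#' the retained (non-outlier) records and a per-word covariate. Pairs with a
#' missing covariate are dropped. Correlations are meant to be computed
#' within a language, never pooled across languages.
#'
#' @param records An [score_sentence()]-shaped tibble (the `outlier` column
#'   is honoured: flagged rows are excluded first).
#' @param covariate Numeric vector aligned with `records` rows.
#' @param method `"pearson"` or `"spearman"`.
#' @return The correlation, or `NA` (with a `wordinfo_undefined_correlation`
#'   warning) when fewer than 3 complete pairs remain or either side has zero
#'   variance.
#' @export
correlate <- function(records, covariate, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(nrow(records) == length(covariate))
  keep <- !records$outlier & !is.na(covariate) & !is.na(records$informativeness)
  x <- records$informativeness[keep]
  y <- covariate[keep]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    wi_warn("Correlation undefined: fewer than 3 complete pairs or zero variance.",
            "wordinfo_undefined_correlation")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' Per-language descriptive summary
#'
#' Means and correlations of the kind plotted in cross-linguistic analyses:
#' mean informativeness, mean word length (printed characters of the token
#' core), mean passage length in words, and the correlations of
#' informativeness with length, Zipf frequency and predictability. All
#' statistics are computed after outlier exclusion.
#'
#' @param scores Scored records for one language ([score_corpus()] output).
#' @param sentences Tibble with `sentence_id`, `language` and optionally
#'   `passage_id`; when `passage_id` is absent each sentence counts as its
#'   own passage.
#' @param covariates Optional tibble keyed by `(sentence_id, token_index)`
#'   with `zipf` and/or `predictability` columns; without it the
#'   corresponding correlations are `NA`.
#' @param method Correlation method, see [correlate()].
#' @return One-row tibble: `language`, `n_words`, `mean_informativeness`,
#'   `mean_word_length`, `mean_passage_length_words`, `r_length`, `r_zipf`,
#'   `r_predictability`.
#' @export
summarize_language <- function(scores, sentences, covariates = NULL,
                               method = "pearson") {
  kept <- scores[!scores$outlier, , drop = FALSE]
  if (nrow(kept) == 0L) {
    wi_abort("No scored records remain after outlier exclusion.",
             "wordinfo_empty_summary")
  }
  language <- if ("language" %in% names(kept)) kept$language[1] else sentences$language[1]
  if (is.null(sentences[["passage_id"]])) sentences$passage_id <- sentences$sentence_id
  # passage length counts all scored word tokens, outliers included: length
  # is a property of the text, not of the score quality
  tok_per_sentence <- table(scores$sentence_id)
  pass_of <- sentences$passage_id[match(names(tok_per_sentence), sentences$sentence_id)]
  passage_len <- tapply(as.numeric(tok_per_sentence), pass_of, sum)

  quiet_cor <- function(cov) {
    withCallingHandlers(
      correlate(kept, cov, method = method),
      wordinfo_undefined_correlation = function(w) invokeRestart("muffleWarning")
    )
  }
  zp <- pr <- rep(NA_real_, nrow(kept))
  if (!is.null(covariates)) {
    key <- paste(kept$sentence_id, kept$token_index)
    i <- match(key, paste(covariates$sentence_id, covariates$token_index))
    if (!is.null(covariates[["zipf"]])) zp <- covariates[["zipf"]][i]
    if (!is.null(covariates[["predictability"]])) pr <- covariates[["predictability"]][i]
  }
  tibble::tibble(
    language = language,
    n_words = nrow(kept),
    mean_informativeness = mean(kept$informativeness),
    mean_word_length = mean(nchar(kept$word)),
    mean_passage_length_words = mean(passage_len),
    r_length = quiet_cor(nchar(kept$word)),
    r_zipf = quiet_cor(zp),
    r_predictability = quiet_cor(pr)
  )
}
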