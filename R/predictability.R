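# Embedding-based predictability: cosine between a word's static vector and
# the aggregate vector of its preceding sentence context.

#' Read a static word-vector lexicon (word2vec text format)
#'
#' Expects the usual text layout: a first line `"<count> <dim>"`, then one
#' `word v1 ... vdim` row per word. Used for the predictability covariate
#' (fastText-style static vectors in practice; any text-format lexicon works).
#'
#' @param path Path to the lexicon file.
#' @return A numeric matrix with one row per word, words as rownames.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 2L) wi_abort("Lexicon file has no vector rows.", "wordinfo_parse_error")
  hdr <- strsplit(squish(lines[1]), " ", fixed = TRUE)[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    wi_abort("Lexicon must start with a '<count> <dim>' header line.",
             "wordinfo_parse_error")
  }
  dim <- as.integer(hdr[2])
  rows <- strsplit(squish(lines[-1]), " ", fixed = TRUE)
  rows <- rows[lengths(rows) == dim + 1L]
  words <- vapply(rows, `[[`, character(1), 1L)
  mat <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  if (any(!is.finite(mat))) wi_abort("Lexicon contains non-finite values.", "wordinfo_parse_error")
  rownames(mat) <- words
  mat
}

#' Write a lexicon in word2vec text format
#' @param mat Matrix with words as rownames.
#' @param path Output path.
#' @export
write_lexicon <- function(mat, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  writeLines(paste(rownames(mat),
                   apply(mat, 1L, function(r) paste(sprintf("%.12g", r), collapse = " "))),
             con)
  invisible(path)
}

# Case-folded lookup with an exact-case first pass; NULL when OOV.
lexicon_lookup <- function(word, lexicon) {
  i <- match(word, rownames(lexicon))
  if (is.na(i)) i <- match(tolower(word), rownames(lexicon))
  if (is.na(i)) NULL else lexicon[i, ]
}

#' Aggregate vector of a preceding context
#'
#' Unweighted arithmetic mean of the in-lexicon vectors of the preceding
#' word cores; out-of-lexicon words are skipped. Returns `NULL` (missing)
#' when no preceding word is in the lexicon — missingness is data here, not
#' an error.
#'
#' @param preceding_cores Character vector of the word cores preceding the
#'   target word (possibly empty for a sentence-initial word).
#' @param lexicon Matrix from [read_lexicon()].
#' @return Numeric vector, or `NULL` when no context is available.
#' @export
context_vector <- function(preceding_cores, lexicon) {
  vecs <- Filter(Negate(is.null), lapply(preceding_cores, lexicon_lookup, lexicon = lexicon))
  if (length(vecs) == 0L) return(NULL)
  colMeans(do.call(rbind, vecs))
}

#' Predictability of a word given its preceding context
#'
#' Cosine similarity between the word's static vector and the mean vector of
#' the in-lexicon words preceding it in the sentence. Missing (`NA`) for
#' sentence-initial words, for out-of-lexicon target words, and when the
#' whole context is out of lexicon.
#'
#' @param word_core Target word core.
#' @param preceding_cores Cores of the words before it, in order.
#' @param lexicon Matrix from [read_lexicon()].
#' @return One-row tibble: `word`, `predictability`, `n_context_words`
#'   (in-lexicon preceding words used), `oov` (target word out of lexicon).
#' @export
predictability <- function(word_core, preceding_cores, lexicon) {
  wv <- lexicon_lookup(word_core, lexicon)
  ctx <- context_vector(preceding_cores, lexicon)
  n_ctx <- if (is.null(ctx)) 0L else {
    sum(!vapply(preceding_cores, function(w) is.null(lexicon_lookup(w, lexicon)), logical(1)))
  }
  pred <- if (is.null(wv) || is.null(ctx)) NA_real_ else cosine_similarity(wv, ctx)
  tibble::tibble(word = word_core, predictability = pred,
                 n_context_words = n_ctx, oov = is.null(wv))
}

#' Predictability for every word of a sentence
#'
#' @param sent A [sentence()].
#' @param lexicon Matrix from [read_lexicon()].
#' @return Tibble with one row per token: `sentence_id`, `token_index`,
#'   `word`, `predictability`, `n_context_words`, `oov`.
#' @export
predictability_sentence <- function(sent, lexicon) {
  stopifnot(inherits(sent, "wi_sentence"))
  cores <- sent$tokens$core
  rows <- lapply(seq_along(cores), function(i) {
    predictability(cores[i], cores[seq_len(i - 1L)], lexicon)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(sentence_id = sent$id,
                  token_index = sent$tokens$token_index, .before = 1L)
}
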