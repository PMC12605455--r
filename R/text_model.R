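#' Segment a sentence into word tokens
#'
#' Splits `raw_text` on whitespace and partitions each chunk into leading
#' punctuation, a core, and trailing punctuation. Punctuation is any Unicode
#' character in the P* general categories; it is stripped only at chunk edges,
#' so word-internal apostrophes and hyphens are preserved (`"today's"` stays
#' whole, a trailing comma is moved to `trailing_punct`). Chunks whose core is
#' empty (pure punctuation) are not word tokens and are dropped. Numerals and
#' symbols with a non-empty core count as words.
#'
#' @param raw_text A single non-empty string.
#' @return A tibble with one row per word token and columns `token_index`
#'   (0-based), `surface`, `core`, `leading_punct`, `trailing_punct`,
#'   `core_length` (printed characters in `core`).
#' @examples
#' segment_words("the wedding was ruined by the heavy rain and snow")
#' @export
segment_words <- function(raw_text) {
  if (length(raw_text) != 1L || is.na(raw_text)) {
    wi_abort("`raw_text` must be a single string.", "wordinfo_empty_sentence")
  }
  text <- squish(raw_text)
  if (!nzchar(text)) {
    wi_abort("Sentence is empty after whitespace normalization.",
             "wordinfo_empty_sentence")
  }
  chunks <- strsplit(text, " ", fixed = TRUE)[[1]]
  lead <- regmatches(chunks, regexpr("^\\p{P}+", chunks, perl = TRUE))
  leading <- character(length(chunks))
  leading[grepl("^\\p{P}+", chunks, perl = TRUE)] <- lead
  rest <- substr(chunks, nchar(leading) + 1L, nchar(chunks))
  trailing <- character(length(chunks))
  has_tr <- grepl("\\p{P}+$", rest, perl = TRUE)
  trailing[has_tr] <- regmatches(rest, regexpr("\\p{P}+$", rest, perl = TRUE))
  core <- substr(rest, 1L, nchar(rest) - nchar(trailing))
  keep <- nzchar(core)
  tibble::tibble(
    token_index   = seq_len(sum(keep)) - 1L,
    surface       = chunks[keep],
    core          = core[keep],
    leading_punct = leading[keep],
    trailing_punct = trailing[keep],
    core_length   = nchar(core[keep])
  )
}

#' Construct a sentence object
#'
#' Bundles raw text with its word tokens, a stable identifier, and a language
#' code. Tokenization is deterministic and language-agnostic; sentence
#' segmentation of longer passages is the caller's responsibility (see
#' [split_sentences()] for a convenience splitter).
#'
#' @param raw_text Sentence text (UTF-8).
#' @param id Opaque sentence identifier.
#' @param language BCP-47-style language code.
#' @return An object of class `wi_sentence`: a list with `id`, `language`,
#'   `raw_text` (whitespace-normalized) and `tokens` (see [segment_words()]).
#' @export
sentence <- function(raw_text, id = "s1", language = "und") {
  tokens <- segment_words(raw_text)
  structure(
    list(id = as.character(id), language = as.character(language),
         raw_text = squish(raw_text), tokens = tokens),
    class = "wi_sentence"
  )
}

#' @export
print.wi_sentence <- function(x, ...) {
  cat(sprintf("<wi_sentence %s [%s], %d tokens>\n  %s\n",
              x$id, x$language, nrow(x$tokens), x$raw_text))
  invisible(x)
}

#' Rebuild text from word tokens
#'
#' Joins token surfaces with single spaces; the inverse of [segment_words()]
#' up to whitespace normalization.
#'
#' @param tokens A token tibble as produced by [segment_words()].
#' @return A single string (empty for an empty token list).
#' @export
detokenize <- function(tokens) {
  if (is.null(tokens) || nrow(tokens) == 0L) return("")
  paste(tokens$surface, collapse = " ")
}

#' Remove one word from a sentence
#'
#' Returns the text of the sentence with the word at `index` removed, the
#' "revised sentence" used by the leave-one-out informativeness measure. Edge
#' punctuation carried by the removed token belongs to the sentence rather
#' than the word, so it is re-attached to the preceding remaining token (or to
#' the following token when the first word is removed).
#'
#' @param sent A `wi_sentence`.
#' @param index 0-based word-token position to remove.
#' @return The revised sentence text. The input is not modified.
#' @export
remove_word <- function(sent, index) {
  stopifnot(inherits(sent, "wi_sentence"))
  n <- nrow(sent$tokens)
  if (n < 2L) {
    wi_abort("Cannot remove a word from a single-token sentence; the score is undefined.",
             "wordinfo_degenerate_sentence")
  }
  if (length(index) != 1L || is.na(index) || index < 0L || index >= n) {
    wi_abort(sprintf("Token index %s out of range [0, %d].", format(index), n - 1L),
             "wordinfo_index_error")
  }
  i <- as.integer(index) + 1L
  toks <- sent$tokens
  punct <- paste0(toks$leading_punct[i], toks$trailing_punct[i])
  surfaces <- toks$surface[-i]
  if (nzchar(punct)) {
    if (i > 1L) {
      surfaces[i - 1L] <- paste0(surfaces[i - 1L], punct)
    } else {
      surfaces[1L] <- paste0(punct, surfaces[1L])
    }
  }
  paste(surfaces, collapse = " ")
}

#' Split a passage into sentences on terminal punctuation
#'
#' Convenience splitter for passage files: breaks on runs of `.`, `!`, `?`
#' (keeping them with the preceding sentence) followed by whitespace. Supplied
#' as plumbing only — scored results depend on the caller's segmentation, and
#' careful work should segment passages upstream.
#'
#' @param text A passage string.
#' @return Character vector of sentence texts (whitespace-normalized).
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1L)
  parts <- strsplit(squish(text), "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts[nzchar(parts)]
}
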