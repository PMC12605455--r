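# The informativeness measure: leave-one-out embedding dissimilarity and
# its natural-log transform, plus the outlier rule and the word-sentence
# similarity comparison measure.

#' Raw dissimilarity from a cosine similarity
#'
#' The untransformed measure: `1 - cosine(full sentence, sentence without the
#' word)`. Values near 0 mean the word barely changes the sentence meaning;
#' values near 1 mean the revised sentence is orthogonal to the original.
#'
#' @param cos_sim Cosine similarity in `[-1, 1]` (vectorized).
#' @return `1 - cos_sim`, in `[0, 2]`.
#' @export
raw_dissimilarity <- function(cos_sim) {
  if (any(is.na(cos_sim)) || any(cos_sim < -1 | cos_sim > 1)) {
    wi_abort("Cosine similarity must lie in [-1, 1].", "wordinfo_domain_error")
  }
  1 - cos_sim
}

#' Log-transformed informativeness
#'
#' Natural log of the raw dissimilarity. Omitting most words changes sentence
#' meaning only minutely, so raw dissimilarities pile up near zero with a long
#' right tail; the log transform spreads that mass out. Non-positive
#' dissimilarities (possible when a cosine rounds to 1 or slightly above) are
#' clamped to a floor of `1e-12` before the log, giving about `-27.6` — far
#' below the `-10` outlier threshold, so clamped records are always excluded
#' downstream.
#'
#' @param d Raw dissimilarity, `>= 0` (vectorized).
#' @param floor Clamp floor for `d <= floor` (default `1e-12`).
#' @return A list with `informativeness` (natural-log scale, always
#'   `<= log(2)`) and logical `clamped`.
#' @export
log_informativeness <- function(d, floor = 1e-12) {
  if (any(is.na(d)) || any(d < 0)) {
    wi_abort("Raw dissimilarity must be >= 0.", "wordinfo_domain_error")
  }
  clamped <- d <= floor
  list(informativeness = log(pmax(d, floor)), clamped = clamped)
}

#' Score every word of a sentence
#'
#' For each word token, embeds the full sentence (once, reused across words)
#' and the revised sentence with that word removed, and records the cosine
#' between the two, the raw dissimilarity, and the log informativeness.
#' Because the measure is computed against the specific containing sentence,
#' the same word receives different scores in different contexts — and, with
#' an order-sensitive backend, at different positions of the same sentence.
#'
#' @param sent A [sentence()] with at least 2 tokens.
#' @param spec An [embedder_spec()].
#' @param outlier_threshold Passed to [flag_outliers()] (default `-10`).
#' @return A tibble with one row per token: `sentence_id`, `token_index`,
#'   `word` (token core), `cosine_full_vs_partial`, `raw_dissimilarity`,
#'   `informativeness`, `outlier`, `clamped`, ordered by `token_index`.
#' @export
score_sentence <- function(sent, spec, outlier_threshold = -10) {
  stopifnot(inherits(sent, "wi_sentence"))
  n <- nrow(sent$tokens)
  if (n < 2L) {
    wi_abort(sprintf("Sentence '%s' has fewer than 2 tokens; informativeness is undefined.",
                     sent$id),
             "wordinfo_degenerate_sentence")
  }
  v_full <- tryCatch(
    embed_text(sent$raw_text, spec),
    wordinfo_config_error = function(e) stop(e),
    error = function(e) {
      wi_abort(sprintf("Embedding backend failed on sentence '%s': %s",
                       sent$id, conditionMessage(e)),
               "wordinfo_backend_error")
    }
  )
  cosines <- vapply(seq_len(n) - 1L, function(idx) {
    cosine_similarity(v_full, embed_text(remove_word(sent, idx), spec))
  }, numeric(1))
  d <- raw_dissimilarity(cosines)
  li <- log_informativeness(d)
  out <- tibble::tibble(
    sentence_id = sent$id,
    token_index = sent$tokens$token_index,
    word = sent$tokens$core,
    cosine_full_vs_partial = cosines,
    raw_dissimilarity = d,
    informativeness = li$informativeness,
    outlier = FALSE,
    clamped = li$clamped
  )
  flag_outliers(out, threshold = outlier_threshold, quiet = TRUE)
}

#' Score a corpus of sentences
#'
#' @param sentences A list of [sentence()] objects, or a tibble with columns
#'   `sentence_id`, `language`, `raw_text`.
#' @inheritParams score_sentence
#' @return Row-bound [score_sentence()] tibbles with a `language` column.
#' @export
score_corpus <- function(sentences, spec, outlier_threshold = -10) {
  if (is.data.frame(sentences)) {
    sentences <- lapply(seq_len(nrow(sentences)), function(i) {
      sentence(sentences$raw_text[i], id = sentences$sentence_id[i],
               language = sentences$language[i])
    })
  }
  dplyr::bind_rows(lapply(sentences, function(s) {
    dplyr::mutate(score_sentence(s, spec, outlier_threshold),
                  language = s$language, .before = 1L)
  }))
}

#' Flag informativeness outliers
#'
#' Marks records whose informativeness is strictly smaller than the threshold
#' (default `-10`). Such values form clear outliers against length, frequency
#' and predictability and are most plausibly artifacts of degenerate embedding
#' estimates; downstream summaries and model tables exclude them before any
#' statistic is computed.
#'
#' @param records An [score_sentence()]-shaped tibble.
#' @param threshold Exclusion threshold (strict `<`; default `-10`).
#' @param quiet Suppress the flagged-count message.
#' @return `records` with the `outlier` column set.
#' @export
flag_outliers <- function(records, threshold = -10, quiet = FALSE) {
  records$outlier <- records$informativeness < threshold
  if (!quiet) {
    message(sprintf("flag_outliers: %d of %d records below %s",
                    sum(records$outlier), nrow(records), format(threshold)))
  }
  records
}

#' Word-sentence similarity (comparison measure)
#'
#' The earlier embedding-based importance measure: the cosine between the
#' embedding of the word itself and the embedding of the whole sentence it
#' appears in (word included). Provided only for convergent-validity
#' comparisons against the leave-one-out measure; a word can be dissimilar to
#' its sentence yet crucial to the message, which is what motivates the
#' leave-one-out definition.
#'
#' @param word A non-empty token core.
#' @param sent A [sentence()].
#' @param spec An [embedder_spec()].
#' @return Cosine similarity in `[-1, 1]`.
#' @export
word_sentence_similarity <- function(word, sent, spec) {
  stopifnot(inherits(sent, "wi_sentence"))
  if (!nzchar(squish(word))) {
    wi_abort("`word` must be non-empty.", "wordinfo_empty_input")
  }
  cosine_similarity(embed_text(word, spec), embed_text(sent$raw_text, spec))
}
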