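# Bundled worked-example fixtures.

#' Worked-example sentence values
#'
#' The printed per-word values (cosine between full and leave-one-out
#' sentence, raw dissimilarity, log informativeness) for the bundled
#' 28-token English example sentence, as published for the pinned pretrained
#' multilingual backend. Cosine and dissimilarity keep their printed form
#' (including the `">0.999"` / `"<0.001"` bound rows); numeric columns
#' `cosine_num` and `dissimilarity_num` carry `NA` for those bounds.
#'
#' @return Tibble with `word`, `cosine`, `dissimilarity`, `informativeness`,
#'   `cosine_num`, `dissimilarity_num`.
#' @export
example_sentence_values <- function() {
  path <- system.file("extdata", "example_sentence_values.tsv", package = "wordinfo")
  tab <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                             stringsAsFactors = FALSE,
                                             fileEncoding = "UTF-8"))
  tab$cosine_num <- suppressWarnings(as.numeric(tab$cosine))
  tab$dissimilarity_num <- suppressWarnings(as.numeric(tab$dissimilarity))
  tab
}

#' Bundled example sentences
#'
#' Five English sentences used throughout the documentation and tests: the
#' 28-token worked-example sentence and two context-specificity pairs (the
#' same word in a context where it is crucial vs. redundant).
#'
#' @return Tibble with `sentence_id`, `language`, `raw_text`.
#' @export
example_sentences <- function() {
  read_sentences(system.file("extdata", "example_sentences.tsv", package = "wordinfo"))
}
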