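# File-level interfaces: sentence files, token dumps, score files with
# backend provenance headers.

#' Read a sentence corpus file
#'
#' One sentence per line, UTF-8, with optional leading `id<TAB>language<TAB>`
#' columns (lines without tabs get generated ids and language `"und"`).
#'
#' @param path File path.
#' @return Tibble with `sentence_id`, `language`, `raw_text`.
#' @export
read_sentences <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(squish(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 3L) {
      tibble::tibble(sentence_id = parts[1], language = parts[2],
                     raw_text = paste(parts[-(1:2)], collapse = "\t"))
    } else {
      tibble::tibble(sentence_id = sprintf("s%04d", i), language = "und",
                     raw_text = lines[i])
    }
  })
  dplyr::bind_rows(rows)
}

#' Write a token dump
#'
#' TSV with columns `sentence_id`, `token_index`, `surface`, `core`,
#' `leading_punct`, `trailing_punct`, `core_length`.
#'
#' @param sentences Tibble from [read_sentences()] or a list of [sentence()]s.
#' @param path Output path.
#' @export
write_tokens <- function(sentences, path) {
  if (is.data.frame(sentences)) {
    sentences <- lapply(seq_len(nrow(sentences)), function(i) {
      sentence(sentences$raw_text[i], id = sentences$sentence_id[i],
               language = sentences$language[i])
    })
  }
  dump <- dplyr::bind_rows(lapply(sentences, function(s) {
    dplyr::mutate(s$tokens, sentence_id = s$id, .before = 1L)
  }))
  utils::write.table(dump, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write scored records with backend provenance
#'
#' TSV of informativeness records preceded by `#`-comment header lines
#' recording the backend name, dimension and seed — scores are meaningless
#' without backend provenance, since changing the encoder changes every
#' value.
#'
#' @param records [score_corpus()] output.
#' @param path Output path.
#' @param spec The [embedder_spec()] that produced the records.
#' @export
write_scores <- function(records, path, spec) {
  stopifnot(inherits(spec, "wi_embedder_spec"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("#backend=%s", spec$backend),
               sprintf("#dim=%d", spec$dim),
               sprintf("#seed=%d", spec$seed),
               sprintf("#order_sensitive=%s", spec$order_sensitive)), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score file written by [write_scores()]
#' @param path File path.
#' @return A list: `records` tibble and `provenance` (named character).
#' @export
read_scores <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  prov <- stats::setNames(vapply(kv, `[[`, character(1), 2L),
                          vapply(kv, `[[`, character(1), 1L))
  body <- lines[!startsWith(lines, "#")]
  records <- tibble::as_tibble(utils::read.table(
    text = paste(body, collapse = "\n"), header = TRUE, sep = "\t",
    stringsAsFactors = FALSE))
  list(records = records, provenance = prov)
}
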