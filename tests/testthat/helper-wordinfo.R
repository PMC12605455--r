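# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, re-embedding from scratch) so they stay independent of the
# package's own computation paths.

# A fixed 20-sentence English-like fixture corpus, built in code.
fixture_corpus <- function() {
  texts <- c(
    "the wedding was ruined by the heavy rain and snow",
    "the royal couple married in a beautiful wedding ceremony",
    "The athlete ran as she crossed the finish line of the marathon",
    "The bride ran as she saw the groom in the wedding",
    "a quiet library invites slow careful reading every afternoon",
    "storm clouds gathered over the harbor before the regatta began",
    "children painted bright murals along the old station wall",
    "the chemist measured each sample twice before the analysis",
    "migrating geese followed the river valley toward warmer ground",
    "an engineer sketched the bridge design on a napkin",
    "fresh bread cooled on the windowsill of the bakery",
    "the violinist tuned her instrument behind the velvet curtain",
    "volunteers planted oak saplings across the burned hillside",
    "the museum displayed ancient coins beside clay tablets",
    "morning fog erased the outline of the fishing boats",
    "a patient tutor explained the proof one line at a time",
    "the editor trimmed every redundant phrase from the draft",
    "lanterns drifted down the river during the autumn festival",
    "the goalkeeper studied footage of the rival strikers",
    "wind turbines turned slowly on the distant ridge")
  tibble::tibble(sentence_id = sprintf("fx%02d", seq_along(texts)),
                 language = "en", raw_text = texts)
}

fixture_sentences <- function() {
  corp <- fixture_corpus()
  lapply(seq_len(nrow(corp)), function(i) {
    sentence(corp$raw_text[i], id = corp$sentence_id[i], language = corp$language[i])
  })
}

# Double-loop cosine oracle (no vectorized dot product).
oracle_cosine <- function(u, v) {
  dot <- 0; nu <- 0; nv <- 0
  for (i in seq_along(u)) {
    dot <- dot + u[i] * v[i]
    nu <- nu + u[i]^2
    nv <- nv + v[i]^2
  }
  dot / (sqrt(nu) * sqrt(nv))
}

# Brute-force sentence scorer: re-embeds the full sentence for every word,
# builds each leave-one-out text by hand from whitespace chunks, no reuse.
oracle_score_sentence <- function(text, spec) {
  chunks <- strsplit(gsub("\\s+", " ", trimws(text)), " ")[[1]]
  is_word <- gsub("^[[:punct:]‘’“”]+|[[:punct:]‘’“”]+$",
                  "", chunks) != ""
  word_pos <- which(is_word)
  sapply(word_pos, function(i) {
    full <- embed_text(paste(chunks, collapse = " "), spec)
    left <- chunks[-i]
    first_match <- function(x, pat) {
      m <- regmatches(x, regexpr(pat, x, perl = TRUE))
      if (length(m)) m else ""
    }
    punct <- paste0(
      first_match(chunks[i], "^\\p{P}+"),
      first_match(sub("^\\p{P}+", "", chunks[i], perl = TRUE), "\\p{P}+$"))
    if (nzchar(punct)) {
      j <- if (i > 1L) i - 1L else 1L
      left[j] <- if (i > 1L) paste0(left[j], punct) else paste0(punct, left[j])
    }
    part <- embed_text(paste(left, collapse = " "), spec)
    log(1 - oracle_cosine(full, part))
  })
}

# Textbook two-pass Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Moment skewness.
oracle_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (sqrt(mean((x - m)^2)))^3
}

default_spec <- function(seed = 1L, dim = 64L) embedder_spec(seed = seed, dim = dim)
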