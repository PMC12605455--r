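# Deterministic synthetic corpora and eye-movement data with known ground
# truth, so scoring, analytics and the fixed-effects check are testable
# offline against planted coefficients.

#' Configuration for the synthetic generators
#'
#' All generator randomness is keyed by `seed`; the same config reproduces
#' every output bitwise. Word frequencies follow a Zipf-like rank law and
#' word lengths grow with frequency rank (the law of abbreviation), which is
#' what couples length and frequency to informativeness once the corpus is
#' scored: longer words carry more hashed-trigram mass under the reference
#' embedder, so removing them moves the sentence vector further.
#'
#' @param seed Integer master seed.
#' @param n_languages Number of synthetic languages.
#' @param n_passages Passages per language (translation-equivalent across
#'   languages: passage `k` has the same "meaning slot" everywhere).
#' @param tokens_per_passage Word tokens per passage before packing.
#' @param packing_factors Per-language tokens-per-meaning multiplier: a
#'   language with factor 1.5 spends 1.5x the tokens on the same passage,
#'   diluting per-word information.
#' @param vocab_size Word types per language.
#' @param mean_word_length Per-language target mean word length (characters).
#' @param length_coupling Strength of the rank-to-length growth (0 = all
#'   words the same expected length, killing the length coupling).
#' @param zipf_exponent Rank-frequency exponent (frequency skew; larger =
#'   more mass on few words).
#' @param sentence_len_range Min/max tokens per sentence.
#' @param lexicon_dim Dimension of the toy static-vector lexicon. Frequent
#'   words lie nearer a shared base direction, so embedding-based
#'   predictability is higher for frequent words.
#' @param n_subjects Simulated participants.
#' @param eye Named list of eye-model coefficients on centered, scaled
#'   covariates: `a_tfd` (log-ms intercept), `b_len`, `b_zipf`, `b_pred`,
#'   `b_info`, `b_skill`, `b_skill_info` (total-time model); `a_skip`,
#'   `b_len_skip`, `b_zipf_skip`, `b_info_skip` (first-run skipping logit;
#'   length and informativeness negative by default, mirroring the canonical
#'   direction); `a_rr`, `b_len_rr`, `b_zipf_rr`, `b_pred_rr`, `b_info_rr`
#'   (rereading logit).
#' @param sd_subject,sd_word Random-intercept SDs (subject; word type within
#'   language), log-ms scale.
#' @param sd_resid Residual SD of log total fixation time.
#' @return An object of class `wi_synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_languages = 2L,
                         n_passages = 10L,
                         tokens_per_passage = 100L,
                         packing_factors = rep(1, n_languages),
                         vocab_size = 120L,
                         mean_word_length = rep(5, n_languages),
                         length_coupling = 1.0,
                         zipf_exponent = 1.1,
                         sentence_len_range = c(8L, 14L),
                         lexicon_dim = 16L,
                         n_subjects = 40L,
                         eye = list(),
                         sd_subject = 0.15,
                         sd_word = 0.10,
                         sd_resid = 0.35) {
  eye_default <- list(
    a_tfd = 5.5, b_len = 0.15, b_zipf = -0.10, b_pred = -0.02, b_info = 0.05,
    b_skill = -0.10, b_skill_info = -0.02,
    a_skip = -1.5, b_len_skip = -0.75, b_zipf_skip = 0.19, b_info_skip = -0.02,
    a_rr = -1.5, b_len_rr = 0.17, b_zipf_rr = -0.21, b_pred_rr = -0.08,
    b_info_rr = 0.05)
  eye <- utils::modifyList(eye_default, eye)
  stopifnot(sd_resid > 0, n_subjects >= 2,
            length(packing_factors) == n_languages,
            length(mean_word_length) == n_languages)
  cfg <- structure(
    list(seed = as.integer(seed), n_languages = as.integer(n_languages),
         n_passages = as.integer(n_passages),
         tokens_per_passage = as.integer(tokens_per_passage),
         packing_factors = packing_factors, vocab_size = as.integer(vocab_size),
         mean_word_length = mean_word_length, length_coupling = length_coupling,
         zipf_exponent = zipf_exponent,
         sentence_len_range = as.integer(sentence_len_range),
         lexicon_dim = as.integer(lexicon_dim), n_subjects = as.integer(n_subjects),
         eye = eye, sd_subject = sd_subject, sd_word = sd_word,
         sd_resid = sd_resid),
    class = "wi_synth_config")
  if (cfg$vocab_size < cfg$sentence_len_range[2]) {
    wi_abort("Vocabulary is smaller than the tokens requested per sentence.",
             "wordinfo_config_error")
  }
  cfg
}

#' Hash of a synthetic configuration
#'
#' Every generator output is keyed by `(config hash, seed)`; changing any
#' config field changes the hash.
#'
#' @param config A [synth_config()].
#' @return Hexadecimal hash string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "wi_synth_config"))
  h <- fnv1a32(paste(deparse(unclass(config)), collapse = ""))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Language vocabulary: rank-frequency law + rank-dependent word lengths.
make_vocab <- function(config, lang_idx) {
  v <- config$vocab_size
  ranks <- seq_len(v)
  prob <- 1 / ranks^config$zipf_exponent
  prob <- prob / sum(prob)
  lens <- pmax(2L, round(
    config$mean_word_length[lang_idx] +
      config$length_coupling * (log(ranks) - mean(log(ranks))) +
      stats::rnorm(v, 0, 0.6)))
  prefix <- letters[lang_idx]
  words <- character(v)
  for (r in ranks) {
    repeat {
      w <- paste0(prefix, paste(sample(letters, lens[r] - 1L, replace = TRUE),
                                collapse = ""))
      if (!w %in% words) break
    }
    words[r] <- w
  }
  list(words = words, prob = prob)
}

#' Generate a synthetic multilingual corpus
#'
#' Produces, per language: one-sentence-per-row text with passage structure,
#' a frequency table counting exactly the generated tokens, and a toy static
#' lexicon for predictability. Passages are translation-equivalent across
#' languages (same passage index = same meaning slot); languages with a
#' larger packing factor spend more tokens on the same passage.
#'
#' @param config A [synth_config()].
#' @return A list: `sentences` (tibble `sentence_id`, `language`,
#'   `passage_id`, `raw_text`), `freq_tables` (named list of [freq_table()]),
#'   `lexicons` (named list of matrices), `hash`.
#' @export
make_corpus <- function(config) {
  stopifnot(inherits(config, "wi_synth_config"))
  with_private_rng(derive_seed(config$seed, "corpus"), function() {
    sent_rows <- list()
    freq_tables <- list()
    lexicons <- list()
    for (l in seq_len(config$n_languages)) {
      lang <- sprintf("L%d", l)
      voc <- make_vocab(config, l)
      counts <- integer(config$vocab_size)
      for (p in seq_len(config$n_passages)) {
        n_tok <- max(config$sentence_len_range[1],
                     round(config$tokens_per_passage * config$packing_factors[l]))
        toks_idx <- sample.int(config$vocab_size, n_tok, replace = TRUE,
                               prob = voc$prob)
        counts <- counts + tabulate(toks_idx, config$vocab_size)
        # split the passage into sentences
        pos <- 1L; s <- 0L
        while (pos <= n_tok) {
          len <- sample(seq(config$sentence_len_range[1],
                            config$sentence_len_range[2]), 1L)
          if (n_tok - pos + 1L - len < config$sentence_len_range[1]) {
            len <- n_tok - pos + 1L  # absorb the remainder
          }
          idx <- toks_idx[pos:(pos + len - 1L)]
          s <- s + 1L
          sent_rows[[length(sent_rows) + 1L]] <- tibble::tibble(
            sentence_id = sprintf("%s_p%02d_s%02d", lang, p, s),
            language = lang,
            passage_id = sprintf("%s_p%02d", lang, p),
            raw_text = paste(voc$words[idx], collapse = " "))
          pos <- pos + len
        }
      }
      names(counts) <- voc$words
      freq_tables[[lang]] <- freq_table(counts, language = lang)
      # frequent words lie near a shared base direction -> higher
      # predictability for frequent words
      base <- stats::rnorm(config$lexicon_dim)
      base <- base / sqrt(sum(base^2))
      alpha <- 1 / (1 + 0.03 * seq_len(config$vocab_size))
      noise <- matrix(stats::rnorm(config$vocab_size * config$lexicon_dim),
                      nrow = config$vocab_size)
      lex <- alpha * matrix(base, config$vocab_size, config$lexicon_dim,
                            byrow = TRUE) + (1 - alpha) * noise
      lex <- lex / sqrt(rowSums(lex^2))
      rownames(lex) <- voc$words
      lexicons[[lang]] <- lex
    }
    list(sentences = dplyr::bind_rows(sent_rows), freq_tables = freq_tables,
         lexicons = lexicons, hash = config_hash(config))
  })
}

#' Simulate eye-movement records with planted effects
#'
#' Given word-level covariates (normally the scored synthetic corpus), draws
#' per-subject and per-word-type random intercepts, simulates log total
#' fixation time as a linear function of the centered, scaled covariates
#' (plus a reading-skill main effect and a skill-by-informativeness
#' interaction), and first-run skipping and rereading from logistic links.
#' Durations are back-transformed to integer milliseconds with first-pass
#' measures carved out of total time so that `ffd <= gaze <= tfd` always
#' holds and `reread` is exactly `tfd > gaze`. Skill test scores for five
#' synthetic proficiency tests load on one latent skill factor.
#'
#' @param config A [synth_config()].
#' @param word_inputs Tibble with one row per word token: `language`,
#'   `sentence_id`, `token_index`, `word`, `informativeness`, and optionally
#'   `length`, `zipf`, `predictability` (missing covariates enter as zero
#'   effect).
#' @param seed Seed for this draw (default `config$seed`); vary it for
#'   replicate draws under one configuration.
#' @return A list: `ia` (interest-area tibble through [as_ia_records()]),
#'   `skills` (subject test scores), `truth` (all planted coefficients,
#'   latent skills, and the config hash).
#' @export
make_eye_data <- function(config, word_inputs, seed = config$seed) {
  stopifnot(inherits(config, "wi_synth_config"))
  wi <- word_inputs
  if (is.null(wi[["length"]])) wi$length <- nchar(wi$word)
  scale0 <- function(x) {
    if (is.null(x) || all(is.na(x))) return(rep(0, nrow(wi)))
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  L <- scale0(wi[["length"]]); Z <- scale0(wi[["zipf"]])
  P <- scale0(wi[["predictability"]]); I <- scale0(wi[["informativeness"]])
  e <- config$eye
  with_private_rng(derive_seed(seed, "eye"), function() {
    ns <- config$n_subjects
    skill <- stats::rnorm(ns)
    u_subj <- stats::rnorm(ns, 0, config$sd_subject)
    wtype <- paste(wi$language, wi$word, sep = ":")
    types <- unique(wtype)
    u_word <- stats::setNames(stats::rnorm(length(types), 0, config$sd_word), types)
    nw <- nrow(wi)

    rows <- vector("list", ns)
    for (s in seq_len(ns)) {
      eta_tfd <- e$a_tfd + e$b_len * L + e$b_zipf * Z + e$b_pred * P +
        e$b_info * I + e$b_skill * skill[s] + e$b_skill_info * skill[s] * I +
        u_subj[s] + u_word[wtype] + stats::rnorm(nw, 0, config$sd_resid)
      p_skip <- stats::plogis(e$a_skip + e$b_len_skip * L +
                              e$b_zipf_skip * Z + e$b_info_skip * I)
      skip <- stats::rbinom(nw, 1L, p_skip)
      p_rr <- stats::plogis(e$a_rr + e$b_len_rr * L + e$b_zipf_rr * Z +
                            e$b_pred_rr * P + e$b_info_rr * I)
      rr <- stats::rbinom(nw, 1L, p_rr)

      tfd <- pmax(2L, as.integer(round(exp(eta_tfd))))
      fixated_late <- skip == 1L & rr == 1L   # skipped first pass, returned later
      never_fixed  <- skip == 1L & rr == 0L
      gaze <- ifelse(rr == 1L,
                     pmin(tfd - 1L, pmax(1L, as.integer(round(tfd * stats::runif(nw, 0.45, 0.8))))),
                     tfd)
      single_fix <- stats::runif(nw) < 0.6
      ffd <- ifelse(single_fix, gaze,
                    pmax(1L, as.integer(round(gaze * stats::runif(nw, 0.5, 0.9)))))
      ffd <- pmin(ffd, gaze)
      ffd[skip == 1L] <- NA_integer_
      gaze[skip == 1L] <- NA_integer_
      tfd[never_fixed] <- NA_integer_
      nfix_first <- ifelse(skip == 1L, 0L, ifelse(ffd == gaze, 1L, 2L))
      nfix_first[is.na(nfix_first)] <- 0L
      nfix_total <- nfix_first + ifelse(!is.na(tfd) & (fixated_late | (skip == 0L & rr == 1L)), 1L, 0L)
      rows[[s]] <- tibble::tibble(
        subject = sprintf("sub%03d", s),
        language = wi$language, trial = wi$sentence_id, ia_index = wi$token_index,
        word = wi$word,
        ffd = as.numeric(ffd), gaze = as.numeric(gaze), tfd = as.numeric(tfd),
        nfix_firstrun = nfix_first, nfix_total = nfix_total)
    }
    ia <- as_ia_records(dplyr::bind_rows(rows))

    tests <- c("towre_words", "towre_nonwords", "spelling", "lextale", "vocabulary")
    skills <- tibble::tibble(subject = sprintf("sub%03d", seq_len(ns)))
    for (t in tests) skills[[t]] <- 0.8 * skill + 0.6 * stats::rnorm(ns)

    list(ia = ia, skills = skills,
         truth = list(coefficients = e, sd_subject = config$sd_subject,
                      sd_word = config$sd_word, sd_resid = config$sd_resid,
                      skill = skill, subject_intercepts = u_subj,
                      word_intercepts = u_word, seed = seed,
                      config_hash = config_hash(config)))
  })
}
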