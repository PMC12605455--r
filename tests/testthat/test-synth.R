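test_that("the generators are bitwise-deterministic per configuration", {
  cfg <- synth_config(seed = 4, n_languages = 2, n_passages = 3,
                      tokens_per_passage = 50, vocab_size = 60, n_subjects = 4)
  c1 <- make_corpus(cfg); c2 <- make_corpus(cfg)
  expect_identical(c1, c2)
  wi <- tibble::tibble(language = "L1", sentence_id = "s", token_index = 0:49,
                       word = c1$freq_tables$L1$counts |> names() |> head(50),
                       informativeness = rnorm(50))
  e1 <- make_eye_data(cfg, wi); e2 <- make_eye_data(cfg, wi)
  expect_identical(e1$ia, e2$ia)
  expect_identical(e1$truth$coefficients, e2$truth$coefficients)
  # generator draws do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_corpus(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("changing any config field changes the config hash", {
  base <- synth_config(seed = 1)
  variants <- list(synth_config(seed = 2),
                   synth_config(seed = 1, n_passages = 11L),
                   synth_config(seed = 1, sd_resid = 0.36),
                   synth_config(seed = 1, eye = list(b_info = 0.049)))
  hashes <- vapply(c(list(base), variants), config_hash, character(1))
  expect_equal(anyDuplicated(hashes), 0L)
})

test_that("frequency tables conserve the generated token count", {
  cfg <- synth_config(seed = 6, n_languages = 1, n_passages = 10,
                      tokens_per_passage = 100, vocab_size = 80)
  corp <- make_corpus(cfg)
  expect_equal(corp$freq_tables$L1$total_tokens, 1000)
  expect_equal(sum(corp$freq_tables$L1$counts), 1000)
  # and the sentences really contain those tokens
  n_tok <- sum(lengths(strsplit(corp$sentences$raw_text, " ")))
  expect_equal(n_tok, 1000)
})

test_that("configured mean word lengths order the generated languages", {
  cfg <- synth_config(seed = 13, n_languages = 2, n_passages = 4,
                      tokens_per_passage = 80, vocab_size = 80,
                      mean_word_length = c(7, 4))
  corp <- make_corpus(cfg)
  mean_len <- function(lang) {
    toks <- unlist(strsplit(corp$sentences$raw_text[corp$sentences$language == lang], " "))
    mean(nchar(toks))
  }
  expect_gt(mean_len("L1"), mean_len("L2"))
})

test_that("undersized vocabularies are rejected", {
  expect_error(synth_config(vocab_size = 10, sentence_len_range = c(8L, 14L)),
               class = "wordinfo_config_error")
})

test_that("null informativeness effect leaves log total time uncorrelated at large n", {
  cfg <- synth_config(seed = 9, n_languages = 1, n_passages = 3,
                      tokens_per_passage = 100, vocab_size = 120, n_subjects = 40,
                      eye = list(b_info = 0, b_skill_info = 0, b_len = 0,
                                 b_zipf = 0, b_pred = 0, a_skip = -20))
  corp <- make_corpus(cfg)
  scores <- score_corpus(corp$sentences, default_spec())
  eye <- make_eye_data(cfg, dplyr::transmute(scores, language, sentence_id,
                                             token_index, word, informativeness))
  dat <- derive_dvs(filter_ia(eye$ia)$kept)
  info <- scores$informativeness[match(paste(dat$trial, dat$ia_index),
                                       paste(scores$sentence_id, scores$token_index))]
  ok <- !is.na(dat$log_tfd)
  expect_gte(sum(ok), 10000L)
  expect_lt(abs(cor(info[ok], dat$log_tfd[ok])), 0.05)
})

test_that("the rereading link hits its inverse-logit rate at intercept -2", {
  cfg <- synth_config(seed = 14, n_languages = 1, n_passages = 4,
                      tokens_per_passage = 100, vocab_size = 120, n_subjects = 40,
                      eye = list(a_rr = -2, b_len_rr = 0, b_zipf_rr = 0,
                                 b_pred_rr = 0, b_info_rr = 0,
                                 a_skip = -20))  # effectively no skipping
  corp <- make_corpus(cfg)
  scores <- score_corpus(corp$sentences, default_spec())
  eye <- make_eye_data(cfg, dplyr::transmute(scores, language, sentence_id,
                                             token_index, word, informativeness))
  rate <- mean(eye$ia$reread[!is.na(eye$ia$tfd)])
  expect_equal(rate, 0.1192, tolerance = 0.05)  # plogis(-2) = 0.1192, sampling slack
})

test_that("simulated durations never violate the interest-area invariants", {
  cfg <- synth_config(seed = 17, n_languages = 1, n_passages = 2,
                      tokens_per_passage = 80, vocab_size = 60, n_subjects = 10)
  corp <- make_corpus(cfg)
  scores <- score_corpus(corp$sentences, default_spec())
  ia <- make_eye_data(cfg, dplyr::transmute(scores, language, sentence_id,
                                            token_index, word, informativeness))$ia
  fix <- !is.na(ia$tfd)
  expect_true(all(is.na(ia$ffd) | ia$ffd <= ia$gaze))
  expect_true(all(is.na(ia$gaze) | ia$gaze <= ia$tfd))
  expect_true(all(ia$ffd[fix & !ia$skipped_first_run] ==
                    round(ia$ffd[fix & !ia$skipped_first_run])))
  # skipped-first-run rows carry no first-pass durations
  expect_true(all(is.na(ia$ffd[ia$skipped_first_run])))
  # reread is exactly tfd > gaze (or late fixation) among fixated rows
  expect_equal(ia$reread[fix], is.na(ia$gaze[fix]) | ia$tfd[fix] > ia$gaze[fix])
})

test_that("the full synthetic pipeline runs end to end and recovers planted signs", {
  t0 <- Sys.time()
  cfg <- synth_config(seed = 23, n_languages = 1, n_passages = 3,
                      tokens_per_passage = 100, vocab_size = 120, n_subjects = 30,
                      eye = list(b_info = 0.06, b_len = 0.12, b_zipf = -0.08))
  corp <- make_corpus(cfg)
  scores <- score_corpus(corp$sentences, default_spec())
  wi <- dplyr::transmute(scores, language, sentence_id, token_index, word,
                         informativeness,
                         zipf = zipf(word, corp$freq_tables$L1))
  eye <- make_eye_data(cfg, wi)
  tab <- build_model_table(derive_dvs(filter_ia(eye$ia)$kept), scores,
                           skills = composite_skill(eye$skills),
                           covariates = dplyr::select(wi, language, sentence_id,
                                                      token_index, zipf))
  est <- fit_effect_check(tab, "log_tfd", c("length", "zipf", "informativeness"))
  expect_equal(sign(est$beta), c(1, -1, 1))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
})
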