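write_toy_ia <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                            .local_envir = parent.frame())) {
  header <- "subject,language,trial,ia_index,word,ffd,gaze,tfd,nfix_firstrun,nfix_total"
  writeLines(c(header, rows), path)
  path
}

test_that("IA reports are read with schema and parse validation", {
  path <- write_toy_ia(c("s1,en,t1,0,the,180,180,180,1,1",
                         "s1,en,t1,1,cat,NA,NA,NA,0,0",
                         "s1,en,t1,2,sat,150,300,520,2,3"))
  rec <- read_ia_report(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$skipped_first_run, c(FALSE, TRUE, FALSE))
  expect_equal(rec$reread, c(FALSE, FALSE, TRUE))

  bad_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,language,trial,ia_index,word,ffd,gaze,nfix_firstrun,nfix_total",
               "s1,en,t1,0,the,180,180,1,1"), bad_col)
  err <- tryCatch(read_ia_report(bad_col), error = identity)
  expect_s3_class(err, "wordinfo_schema_error")
  expect_match(conditionMessage(err), "tfd")

  bad_num <- write_toy_ia(c("s1,en,t1,0,the,180,180,180,1,1",
                            "s1,en,t1,1,cat,abc,200,200,1,1"))
  err2 <- tryCatch(read_ia_report(bad_num), error = identity)
  expect_s3_class(err2, "wordinfo_parse_error")
  expect_match(conditionMessage(err2), "row 2")

  disordered <- write_toy_ia("s1,en,t1,0,the,300,200,400,1,2")
  expect_error(read_ia_report(disordered), class = "wordinfo_schema_error")
})

test_that("fixation-time filters are strict at 80/2000/800/1000 ms and keep skips", {
  rec <- as_ia_records(tibble::tibble(
    subject = "s1", language = "en", trial = "t1", ia_index = 0:7,
    word = letters[1:8],
    ffd  = c(79,   80,  300,  900, 400, NA,  100, 801),
    gaze = c(79,   80,  600,  950, 1001, NA, 100, 900),
    tfd  = c(79,   80,  2000, 1800, 1500, NA, 2001, 950),
    nfix_firstrun = c(1, 1, 1, 1, 1, 0, 1, 1),
    nfix_total = c(1, 1, 1, 1, 1, 0, 2, 1)))
  out <- filter_ia(rec)
  kept <- out$kept
  # tfd 79 out, tfd 80 kept, tfd 2000 kept, ffd 900 out (FFD rule),
  # gaze 1001 out, skipped word kept, tfd 2001 out, ffd 801 out
  expect_equal(kept$ia_index, c(1L, 2L, 5L))
  expect_equal(out$log$n_removed[out$log$rule == "total"], 5L)
  expect_equal(out$log$proportion[out$log$rule == "total"], 5 / 8)
  # the FFD rule catches the row before the (also-violated) gaze rule counts it
  expect_gte(out$log$n_removed[out$log$rule == "ffd > 800 ms"], 2L)
})

test_that("filtering is idempotent", {
  cfg <- synth_config(seed = 3, n_languages = 1, n_passages = 2,
                      tokens_per_passage = 60, vocab_size = 60, n_subjects = 5)
  corp <- make_corpus(cfg)
  scores <- score_corpus(corp$sentences, default_spec())
  eye <- make_eye_data(cfg, dplyr::transmute(scores, language, sentence_id,
                                             token_index, word, informativeness))
  once <- filter_ia(eye$ia)
  twice <- filter_ia(once$kept)
  expect_identical(once$kept, twice$kept)
  expect_equal(twice$log$n_removed[twice$log$rule == "total"], 0L)
})

test_that("the five dependent variables are derived per definition", {
  rec <- as_ia_records(tibble::tibble(
    subject = "s1", language = "en", trial = "t1", ia_index = 0:3,
    word = c("a", "b", "c", "d"),
    ffd  = c(200, 250, NA, NA),
    gaze = c(200, 250, NA, NA),
    tfd  = c(200, 520, NA, 310),
    nfix_firstrun = c(1, 1, 0, 0),
    nfix_total = c(1, 2, 0, 1)))
  dv <- derive_dvs(rec)
  expect_equal(dv$skip, c(0L, 0L, 1L, 1L))
  expect_equal(dv$reread, c(0L, 1L, NA_integer_, 1L))
  expect_equal(dv$log_tfd[1], log(200), tolerance = 1e-12)
  expect_equal(dv$log_tfd[1], 5.2983, tolerance = 1e-4)
  expect_true(is.na(dv$log_ffd[3]) && is.na(dv$log_tfd[3]))
  # reread is 1 exactly when total time exceeds gaze among fixated rows
  fix <- !is.na(dv$tfd)
  expect_equal(dv$reread[fix] == 1L,
               is.na(dv$gaze[fix]) | dv$tfd[fix] > dv$gaze[fix])
})

test_that("composite skill averages per-test z-scores", {
  sk <- tibble::tibble(subject = c("a", "b", "c"),
                       t1 = c(10, 20, 30), t2 = c(1, 2, 3), t3 = c(5, 5, 8),
                       t4 = c(0, 1, 2), t5 = c(100, 90, 110))
  out <- composite_skill(sk)
  # a subject at the sample mean on every test scores 0
  at_mean <- composite_skill(tibble::tibble(
    subject = c("a", "b", "c"), t1 = c(1, 2, 3), t2 = c(4, 5, 6)))
  expect_equal(at_mean$composite[2], 0, tolerance = 1e-12)
  # composite is the mean of the z columns
  zc <- as.matrix(out[, paste0("z_", c("t1", "t2", "t3", "t4", "t5"))])
  expect_equal(out$composite, rowMeans(zc))
  expect_equal(mean(c(1, 1, 1, 1, 1)), 1)  # sanity of definition: mean of z's
  expect_equal(mean(c(2, 0, 0, 0, -2)), 0)
  # missing tests drop from the mean with the count recorded
  sk$t2[1] <- NA
  out2 <- composite_skill(sk)
  expect_equal(out2$n_tests[1], 4)
  expect_equal(out2$composite[1], mean(unlist(out2[1, c("z_t1", "z_t3", "z_t4", "z_t5")])))
  # constant test -> undefined-z signal
  expect_warning(composite_skill(tibble::tibble(subject = c("a", "b"),
                                                t1 = c(1, 1), t2 = c(1, 2))),
                 class = "wordinfo_undefined_z")
  expect_error(composite_skill(tibble::tibble(subject = "a", t1 = 1)),
               class = "wordinfo_domain_error")
})

test_that("build_model_table inner-joins, drops outliers, and scales covariates", {
  cfg <- synth_config(seed = 8, n_languages = 1, n_passages = 3,
                      tokens_per_passage = 80, vocab_size = 60, n_subjects = 6)
  corp <- make_corpus(cfg)
  scores <- score_corpus(corp$sentences, default_spec())
  wi <- dplyr::transmute(scores, language, sentence_id, token_index, word,
                         informativeness,
                         zipf = zipf(word, corp$freq_tables$L1))
  eye <- make_eye_data(cfg, wi)
  kept <- derive_dvs(filter_ia(eye$ia)$kept)
  skills <- composite_skill(eye$skills)
  cov <- dplyr::select(wi, language, sentence_id, token_index, zipf)

  # plant one outlier score and one unmatched interest area
  scores2 <- scores
  scores2$informativeness[3] <- -11
  scores2 <- flag_outliers(scores2, quiet = TRUE)
  kept2 <- kept
  kept2$ia_index[1] <- 9999L
  tab <- build_model_table(kept2, scores2, skills = skills, covariates = cov)

  # scaled covariates have mean 0, sd 1 over retained rows
  for (col in c("length", "zipf", "informativeness", "composite")) {
    expect_lt(abs(mean(tab[[col]], na.rm = TRUE)), 1e-8)
    expect_equal(stats::sd(tab[[col]], na.rm = TRUE), 1, tolerance = 1e-8)
  }
  # the outlier word token and the unmatched row are gone
  bad_key <- paste(scores$sentence_id[3], scores$token_index[3])
  expect_false(any(paste(tab$trial, tab$ia_index) == bad_key))
  expect_false(any(tab$ia_index == 9999L))
  # join conservation: no duplication, row count bounded by the smaller input
  expect_lte(nrow(tab), nrow(kept2))
  expect_false(any(duplicated(tab[c("subject", "trial", "ia_index")])))
  # scaling metadata is recorded
  meta <- attr(tab, "scaling")
  expect_true(all(c("informativeness", "zipf") %in% names(meta)))
  expect_gt(meta$informativeness$sd, 0)

  # duplicate keys and empty joins are errors
  expect_error(build_model_table(kept, dplyr::bind_rows(scores, scores)),
               class = "wordinfo_duplicate_key")
  empty_ia <- kept; empty_ia$language <- "zz"
  expect_error(build_model_table(empty_ia, scores), class = "wordinfo_empty_table")
})

test_that("fit_effect_check flags collinear terms and undersized tables", {
  cfg <- synth_config(seed = 12, n_languages = 1, n_passages = 2,
                      tokens_per_passage = 60, vocab_size = 60, n_subjects = 6)
  corp <- make_corpus(cfg)
  scores <- score_corpus(corp$sentences, default_spec())
  eye <- make_eye_data(cfg, dplyr::transmute(scores, language, sentence_id,
                                             token_index, word, informativeness))
  tab <- build_model_table(derive_dvs(filter_ia(eye$ia)$kept), scores,
                           skills = composite_skill(eye$skills))
  tab$info_copy <- tab$informativeness
  err <- tryCatch(fit_effect_check(tab, "log_tfd", c("informativeness", "info_copy")),
                  error = identity)
  expect_s3_class(err, "wordinfo_rank_deficient")
  expect_match(conditionMessage(err), "info_copy")
  expect_error(fit_effect_check(tab[1:20, ], "log_tfd", "informativeness"),
               class = "wordinfo_degenerate_fit")
})

test_that("a planted effect on log total fixation time is recovered within its interval", {
  cfg <- synth_config(seed = 101, n_languages = 1, n_passages = 3,
                      tokens_per_passage = 100, vocab_size = 120,
                      n_subjects = 40, eye = list(b_info = 0.05))
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
  b <- est[est$term == "informativeness", ]
  expect_gt(b$beta, 0)
  expect_lt(abs(b$beta - 0.05), 1.96 * b$se)
})

test_that("the binary rereading model estimates a planted logistic effect's sign", {
  cfg <- synth_config(seed = 77, n_languages = 1, n_passages = 3,
                      tokens_per_passage = 100, vocab_size = 120,
                      n_subjects = 30, eye = list(b_info_rr = 0.4, a_rr = -1))
  corp <- make_corpus(cfg)
  scores <- score_corpus(corp$sentences, default_spec())
  eye <- make_eye_data(cfg, dplyr::transmute(scores, language, sentence_id,
                                             token_index, word, informativeness))
  tab <- build_model_table(derive_dvs(filter_ia(eye$ia)$kept), scores)
  est <- fit_effect_check(tab, "reread", c("length", "informativeness"))
  b <- est[est$term == "informativeness", ]
  expect_gt(b$beta, 0)
  expect_gt(b$beta / b$se, 2)
})

test_that("the absorption check agrees with a crossed mixed model on sign and magnitude", {
  cfg <- synth_config(seed = 55, n_languages = 1, n_passages = 3,
                      tokens_per_passage = 100, vocab_size = 120,
                      n_subjects = 25, eye = list(b_info = 0.06))
  corp <- make_corpus(cfg)
  scores <- score_corpus(corp$sentences, default_spec())
  eye <- make_eye_data(cfg, dplyr::transmute(scores, language, sentence_id,
                                             token_index, word, informativeness))
  tab <- build_model_table(derive_dvs(filter_ia(eye$ia)$kept), scores)
  est <- fit_effect_check(tab, "log_tfd", c("length", "informativeness"))
  fit <- lme4::lmer(log_tfd ~ length + informativeness +
                      (1 | subject) + (1 | word_in_language),
                    data = tab, REML = FALSE)
  b_lmm <- lme4::fixef(fit)[["informativeness"]]
  b_abs <- est$beta[est$term == "informativeness"]
  expect_equal(sign(b_abs), sign(b_lmm))
  expect_lt(abs(b_abs - b_lmm), 0.02)
})
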