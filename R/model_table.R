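# Model-ready analysis table and the desk-scale fixed-effects check.

#' Build the model-ready analysis table
#'
#' Inner-joins filtered interest-area records with word-level informativeness
#' scores and covariates (on `language`, `trial`/`sentence_id`, and
#' `ia_index`/`token_index`), and with per-subject skill composites; drops
#' outlier-flagged informativeness rows; then centers and scales every
#' covariate over the retained rows. Scaling metadata (per-covariate mean and
#' sd) is stored in the `"scaling"` attribute so estimates can be mapped back
#' to raw units and so external mixed-model tooling can reproduce the exact
#' design.
#'
#' @param ia Filtered interest-area tibble with DVs (see [derive_dvs()]).
#' @param scores Informativeness records with a `language` column
#'   ([score_corpus()] output); `sentence_id` must match `ia$trial`.
#' @param skills Output of [composite_skill()] (optional; `NULL` to omit).
#' @param covariates Optional tibble keyed by `(language, sentence_id,
#'   token_index)` with any of `length`, `zipf`, `predictability`,
#'   `surprisal`. `length` defaults to the printed-character count of the
#'   scored word core. `surprisal` is a pass-through column: the package
#'   never computes it, but when supplied it is centered and scaled like any
#'   other covariate.
#' @param per_language Scale within language instead of pooled (default
#'   pooled).
#' @return Tibble with one row per retained (subject, word token): DV columns
#'   (`skip`, `log_ffd`, `log_gaze`, `log_tfd`, `reread`), scaled covariates,
#'   and grouping keys (`subject`, `word_in_language`, `language`). Attribute
#'   `"scaling"` holds the centering/scaling metadata.
#' @export
build_model_table <- function(ia, scores, skills = NULL, covariates = NULL,
                              per_language = FALSE) {
  scores <- scores[!scores$outlier, , drop = FALSE]
  word_tab <- tibble::tibble(
    language = scores$language,
    trial = scores$sentence_id,
    ia_index = scores$token_index,
    word_core = scores$word,
    informativeness = scores$informativeness,
    length = nchar(scores$word)
  )
  if (anyDuplicated(word_tab[c("language", "trial", "ia_index")])) {
    wi_abort("Duplicate (language, trial, ia_index) keys in scores.",
             "wordinfo_duplicate_key")
  }
  if (!is.null(covariates)) {
    covariates <- dplyr::rename(covariates, trial = "sentence_id",
                                ia_index = "token_index")
    if (anyDuplicated(covariates[c("language", "trial", "ia_index")])) {
      wi_abort("Duplicate (language, trial, ia_index) keys in covariates.",
               "wordinfo_duplicate_key")
    }
    if ("length" %in% names(covariates)) word_tab$length <- NULL
    word_tab <- dplyr::inner_join(word_tab, covariates,
                                  by = c("language", "trial", "ia_index"))
  }
  ia$trial <- as.character(ia$trial)
  word_tab$trial <- as.character(word_tab$trial)
  tab <- dplyr::inner_join(ia, word_tab, by = c("language", "trial", "ia_index"))
  if (!is.null(skills)) {
    tab <- dplyr::inner_join(tab,
                             skills[, c("subject", "composite"), drop = FALSE],
                             by = "subject")
  }
  if (nrow(tab) == 0L) {
    wi_abort("Joining interest areas with scores produced an empty table.",
             "wordinfo_empty_table")
  }
  tab$word_in_language <- paste(tab$language, tab$word_core, sep = ":")

  cov_cols <- intersect(c("length", "zipf", "predictability", "informativeness",
                          "surprisal", "composite"),
                        names(tab))
  scaling <- list()
  for (col in cov_cols) {
    if (per_language) {
      grp <- split(seq_len(nrow(tab)), tab$language)
      mu <- sdv <- numeric(0)
      for (g in names(grp)) {
        i <- grp[[g]]
        m <- mean(tab[[col]][i], na.rm = TRUE)
        s <- stats::sd(tab[[col]][i], na.rm = TRUE)
        tab[[col]][i] <- (tab[[col]][i] - m) / s
        mu[g] <- m; sdv[g] <- s
      }
      scaling[[col]] <- list(mean = mu, sd = sdv, per_language = TRUE)
    } else {
      m <- mean(tab[[col]], na.rm = TRUE)
      s <- stats::sd(tab[[col]], na.rm = TRUE)
      tab[[col]] <- (tab[[col]] - m) / s
      scaling[[col]] <- list(mean = m, sd = s, per_language = FALSE)
    }
  }
  attr(tab, "scaling") <- scaling
  tab
}

#' Desk-scale fixed-effects validation check
#'
#' Estimates covariate effects on one dependent variable with subject and
#' word-within-language intercepts absorbed as categorical fixed effects:
#' ordinary least squares for continuous (log-duration) DVs, and
#' iteratively-reweighted logistic regression for the binary DVs (`skip`,
#' `reread`).
#'
#' Terms that vary within a word type (informativeness, predictability,
#' interactions with subject-level scores) are estimated directly in the
#' absorbed regression. Terms that are constant within a word type (length,
#' Zipf frequency) carry no within-type information once word intercepts are
#' absorbed, so they are estimated in a second least-squares stage that
#' regresses the absorbed word-type intercepts on the type-level covariates —
#' the same between-type information a crossed-intercepts mixed model uses
#' for them, with standard errors on the word-type level. This is a
#' validation-grade approximation for sign and rough-magnitude checks on
#' synthetic data, not the mixed model used for inferential work; export the
#' table and fit that with dedicated mixed-model tooling.
#'
#' @param table A [build_model_table()] tibble.
#' @param dv One of `"skip"`, `"log_ffd"`, `"log_gaze"`, `"log_tfd"`,
#'   `"reread"`.
#' @param terms Fixed-effect terms, e.g.
#'   `c("length", "zipf", "informativeness", "informativeness:composite")`.
#' @return Tibble of effect estimates: `dv`, `term`, `beta`, `se`, `n_obs`,
#'   `stage` (`"within"` or `"between"`), for the requested terms only
#'   (absorbed intercepts are not reported).
#' @export
fit_effect_check <- function(table, dv, terms) {
  stopifnot(dv %in% names(table))
  binary <- dv %in% c("skip", "reread")
  used <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  need <- c(dv, used, "subject", "word_in_language")
  rows <- stats::complete.cases(table[, need, drop = FALSE])
  dat <- table[rows, , drop = FALSE]
  if (nrow(dat) < 50L) {
    wi_abort(sprintf("Only %d complete rows for dv '%s'; need at least 50.",
                     nrow(dat), dv),
             "wordinfo_degenerate_fit")
  }
  dat$subject <- factor(dat$subject)
  dat$word_in_language <- factor(dat$word_in_language)

  # model-matrix columns for the requested terms, one column per term
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = " + "))), dat)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  colnames(mm) <- normalize_terms(colnames(mm), terms)
  if (!setequal(colnames(mm), terms)) {
    wi_abort("Terms must be numeric covariates or interactions of them.",
             "wordinfo_config_error")
  }
  mm <- mm[, terms, drop = FALSE]
  qrx <- qr(cbind(1, mm))
  if (qrx$rank < ncol(mm) + 1L) {
    bad <- colnames(mm)[qr(mm)$pivot[seq.int(qr(mm)$rank + 1L, ncol(mm))]]
    wi_abort(sprintf("Rank-deficient fit: term(s) %s are collinear.",
                     paste(bad, collapse = ", ")),
             "wordinfo_rank_deficient")
  }

  # partition terms: within-type variation vs. constant per word type
  wss <- apply(mm, 2L, function(x) {
    sum(tapply(x, dat$word_in_language, function(v) sum((v - mean(v))^2)))
  })
  within_terms <- colnames(mm)[wss > 1e-8 * nrow(dat)]
  between_terms <- setdiff(colnames(mm), within_terms)

  fdat <- data.frame(.dv = dat[[dv]], mm[, within_terms, drop = FALSE],
                     subject = dat$subject,
                     word_in_language = dat$word_in_language,
                     check.names = FALSE)
  fml <- stats::as.formula(paste(
    ".dv ~", paste(c(sprintf("`%s`", within_terms), "subject", "word_in_language"),
                   collapse = " + ")))
  fit <- if (binary) {
    withCallingHandlers(
      stats::glm(fml, data = fdat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          wi_warn("Possible separation: fitted probabilities at 0 or 1.",
                  "wordinfo_separation")
          invokeRestart("muffleWarning")
        }
      }
    )
  } else {
    stats::lm(fml, data = fdat)
  }
  cf <- stats::coef(summary(fit))
  rn <- gsub("`", "", rownames(cf))
  est <- list()
  for (t in within_terms) {
    i <- match(t, rn)
    est[[t]] <- c(beta = cf[i, "Estimate"], se = cf[i, "Std. Error"])
  }

  if (length(between_terms)) {
    # word-type intercepts (reference level at 0), regressed on the
    # type-constant covariates
    co <- stats::coef(fit)
    lev <- levels(dat$word_in_language)
    alpha <- stats::setNames(rep(0, length(lev)), lev)
    dum <- grep("^word_in_language", names(co))
    alpha[sub("^word_in_language", "", names(co)[dum])] <- co[dum]
    first <- !duplicated(dat$word_in_language)
    bt <- mm[first, between_terms, drop = FALSE]
    bfit <- stats::lm(alpha[as.character(dat$word_in_language[first])] ~ bt)
    bcf <- stats::coef(summary(bfit))
    for (k in seq_along(between_terms)) {
      est[[between_terms[k]]] <- c(beta = bcf[k + 1L, "Estimate"],
                                   se = bcf[k + 1L, "Std. Error"])
    }
  }
  out <- tibble::tibble(
    dv = dv,
    term = terms,
    beta = vapply(terms, function(t) est[[t]][["beta"]], numeric(1),
                  USE.NAMES = FALSE),
    se = vapply(terms, function(t) est[[t]][["se"]], numeric(1),
                USE.NAMES = FALSE),
    n_obs = nrow(dat),
    stage = ifelse(terms %in% within_terms, "within", "between")
  )
  out
}

# model.matrix may print "b:a" for a requested "a:b"; map names back.
flip_interactions <- function(terms) {
  vapply(strsplit(terms, ":", fixed = TRUE),
         function(p) paste(rev(p), collapse = ":"), character(1))
}
normalize_terms <- function(found, requested) {
  flipped <- flip_interactions(requested)
  out <- found
  for (i in seq_along(found)) {
    j <- match(found[i], c(requested, flipped))
    if (!is.na(j)) out[i] <- requested[(j - 1L) %% length(requested) + 1L]
  }
  out
}
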