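---
title: "Measuring word informativeness with leave-one-out sentence embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring word informativeness with leave-one-out sentence embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordinfo)
library(dplyr)
```

## The measure

How important is a single word to the meaning of the sentence it appears in?
`wordinfo` operationalizes this as a leave-one-out comparison in a sentence
embedding space. For word $i$ in sentence $j$, with $\mathbf{s}_j$ the
embedding of the full sentence and $\mathbf{s}_{j \setminus i}$ the embedding
of the same sentence with word $i$ removed, the raw dissimilarity is

$$d_{ij} = 1 - \cos(\mathbf{s}_j,\ \mathbf{s}_{j \setminus i}),$$

and the informativeness score is its natural log,

$$I_{ij} = \ln d_{ij}.$$

Removing an expendable word barely moves the sentence vector, so $d_{ij}$
sits near 0; removing a word that carries the message moves it further.
Because omitting most words in natural sentences changes meaning only
minutely, raw dissimilarities pile up near zero with a long right tail; the
log transform spreads that mass into a roughly symmetric scale without
changing the ordering (less negative = more informative). Since cosine is
bounded below by $-1$, $d_{ij} \le 2$ and $I_{ij} \le \ln 2$.

Two properties distinguish this from the older word-to-sentence cosine
(which the package also provides, as `word_sentence_similarity()`, for
convergent-validity comparisons): the score is *context specific* — the same
word can be crucial in one sentence and redundant in another — and it
measures *contribution*, not topical resemblance. A word can be semantically
distant from its sentence yet indispensable to its message; the leave-one-out
construction captures exactly that.

```{r wedding}
spec <- embedder_spec(backend = "reference", dim = 64, seed = 1)
crucial   <- sentence("the wedding was ruined by the heavy rain and snow", "s1")
redundant <- sentence("the royal couple married in a beautiful wedding ceremony", "s2")
bind_rows(score_sentence(crucial, spec), score_sentence(redundant, spec)) |>
  filter(word == "wedding")
```

## Tokenization and word removal

Scores are defined over orthographic words in space-delimited alphabetic
scripts (unspaced scripts such as Chinese or Japanese are out of scope).
`segment_words()` splits on whitespace and strips Unicode punctuation (the
`P*` general categories) from chunk edges only, so `"lifetime,"` scores as
`lifetime` while `"today's"` keeps its internal apostrophe and scores whole.
Numerals and symbols count as words when their core is non-empty. Two
conventions were genuinely open and are package decisions:

* **Punctuation of a removed word.** Edge punctuation belongs to the
  sentence, not the word, so `remove_word()` re-attaches it to the preceding
  remaining token (to the following token when the first word is removed).
  Embedded texts therefore keep their sentence-level punctuation intact.
* **Case.** Text reaches the embedder exactly as written; the intended
  pretrained backends are cased models, and case can be meaning-bearing.

Sentence segmentation of passages is the caller's responsibility;
`split_sentences()` is a convenience terminal-punctuation splitter only, and
careful work should segment upstream.

## Embedding backends

`embedder_spec()` names the backend; scores are never comparable across
backends, so every score file records backend, dimension and seed in its
header. The intended production backend is a pretrained multilingual
sentence encoder, plugged in at run time via `register_embedder()` — the
package never loads one itself, so everything here runs offline.

The built-in `"reference"` backend exists so that the entire pipeline is
testable deterministically: each whitespace token contributes its character
trigrams (with `<`/`>` boundary marks), hashed by 32-bit FNV-1a into 4096
signed buckets, weighted by a positional decay of $0.9^{\text{index}}$; the
bucket vector is projected through a Gaussian random matrix drawn once from
the seed and L2-normalized. The construction is order sensitive, every token
removal changes the vector, longer tokens carry more trigram mass, and the
output is bitwise reproducible from `(seed, dim, text)`. Trigram size,
decay, bucket count and the hash are pinned: nothing downstream depends on
the particular choice, but reproducibility depends on never changing it. The
reference backend knows orthography and order, never meaning — conclusions
about semantic behavior require a pretrained encoder.

Degenerate arithmetic is handled once, centrally: cosines are clipped into
$[-1, 1]$ against floating-point overshoot, and dissimilarities at or below
$10^{-12}$ (possible when a cosine rounds to 1) are clamped to that floor
before the log, yielding $\approx -27.6$ with a `clamped` flag. Clamped
records always fall below the outlier threshold, so they can never leak into
summaries.

## Outliers and covariates

Scores below $-10$ (on the log scale) form clear outliers in their relations
with length and frequency and most plausibly reflect degenerate embedding
estimates; `flag_outliers()` marks them (strictly below the threshold, which
is a parameter defaulting to $-10$) and every downstream summary, correlation
and model table excludes flagged rows before computing anything.

The standard psycholinguistic covariates are built in:

* **Zipf frequency** — $\log_{10}$ of frequency per billion tokens.
  Out-of-vocabulary handling is unstated in common frequency norms, so
  `zipf()` defaults to Laplace smoothing ($s = 1$, vocabulary-size
  corrected), with $s = 0$ giving the plain transform.
* **Predictability** — the cosine between a word's static vector (a
  fastText-style lexicon in word2vec text format) and the unweighted mean of
  the in-lexicon vectors of its preceding words. The aggregator is a package
  decision (the composition used in prior embedding-predictability work is
  not fully specified); the unweighted mean is the field's default. A
  sentence-initial or out-of-lexicon word yields a missing value — missing
  predictability is data, not an error. Lexicon lookup tries exact case
  first, then case-folded, since static lexicons are typically lowercased.
* **Surprisal** — a pass-through column contract only: language-model
  surprisal is never computed here, but a supplied column is centered and
  scaled like any other covariate.

`summarize_language()` reports per-language means and correlations
(Pearson by default, matching the linear descriptive fits these analyses
usually show; Spearman available), always within language — cross-linguistic
relations are between language *means*, and pooling tokens across languages
would conflate the two levels.

## The eye-movement pipeline

`read_ia_report()` ingests word-level (interest-area) fixation reports with
a documented column contract (`subject, language, trial, ia_index, word,
ffd, gaze, tfd, nfix_firstrun, nfix_total`, durations in ms). Filtering
removes fixated words with total fixation time under 80 ms or over 2000 ms,
first fixation over 800 ms, or gaze over 1000 ms — all comparisons strict,
exactly as the rules are worded, so 80 ms and 2000 ms themselves survive.
Skipped words carry no durations and are never filtered. The five dependent
variables follow the standard processing-stage ladder: first-run skipping
(all words), and — for words fixated at least once — log first fixation
duration, log gaze duration, log total fixation duration, and rereading
(total time exceeding gaze). Words skipped in the first pass but fixated
later count as skipped *and* reread, with first-pass durations missing.

`composite_skill()` z-standardizes each proficiency test over the analysis
sample (pooled, not within site) and averages available z-scores per
subject. `build_model_table()` inner-joins everything on
`(language, trial, ia_index)`, drops outlier-flagged scores, and centers and
scales all covariates over the retained rows (pooled by default; a
per-language switch exists because the convention is genuinely ambiguous),
recording the scaling metadata as an attribute.

### The desk-scale effect check

`fit_effect_check()` is a validation instrument, not an inference engine:
it absorbs subject and word-within-language intercepts as categorical fixed
effects (OLS for log durations, IRLS logistic for the binary measures).
One estimation subtlety matters. Covariates that vary within a word type —
informativeness, predictability, interactions with subject-level skill — are
identified by the within-type contrasts and come from the absorbed
regression directly. Covariates constant within a type (length, Zipf
frequency) are perfectly collinear with the word dummies, so they are
estimated in a second stage regressing the absorbed word-type intercepts on
the type-level covariates — the same between-type information a
crossed-random-intercepts model uses for them, with standard errors on the
word-type level. On synthetic data this two-stage check agrees with
`lme4::lmer` to within hundredths on all coefficients (one test asserts
this), but it is deliberately not the mixed model: export the `ModelTable`
and fit the crossed random-effects models with dedicated tooling for real
inferential work.

## The synthetic generator

`synth_config()` + `make_corpus()` + `make_eye_data()` exist so every stage
can be tested against known truth, offline. The generator emulates:

* **Corpus structure** — a rank-frequency law (`zipf_exponent`, default 1.1)
  with word length growing in frequency rank (`length_coupling`, the law of
  abbreviation). These two choices are what couple length and frequency to
  informativeness once the corpus is scored: longer words carry more trigram
  mass under the reference embedder. Passages are translation-equivalent
  across synthetic languages; `packing_factors` makes a language spend more
  tokens on the same meaning, which dilutes per-word informativeness — the
  cross-linguistic packing relation holds by construction.
* **Eye movements** — log total fixation time linear in centered, scaled
  covariates (default intercept 5.5 log-ms ≈ 245 ms) plus subject and
  word-type random intercepts (SDs 0.15 and 0.10) and residual noise
  (SD 0.35), values in the range typical of passage-reading log durations;
  skipping and rereading from logistic links, with negative length and
  informativeness coefficients on skipping by default so sign-recovery tests
  exercise the canonical direction; a latent reading-skill factor loading on
  five synthetic test scores, with a negative skill-by-informativeness
  interaction. First-pass durations are carved out of total time so
  `ffd <= gaze <= tfd` holds in every record and `reread` is exactly
  `tfd > gaze`.

What the generator does **not** emulate: saccade dynamics, launch-site and
preview effects, any semantic structure in the reference embeddings, or the
empirical MECO distributions beyond first moments. Passing recovery tests
therefore demonstrates that the pipeline arithmetic is faithful — filters,
joins, scaling, estimation — not that the informativeness effect exists in
human data; that evidence requires the real corpus and encoder.

## Problem sizes and numerical choices

The default test and validation runs use corpora of 300–1000 word tokens,
vocabularies of 60–150 types, and 25–40 simulated subjects (about 12,000
interest areas per replicate; 50 replicates for the recovery rates), sizes
at which every documented property is comfortably detectable on a single
CPU. Clamp floor $10^{-12}$; outlier threshold $-10$ (strict); filter bounds
80/2000/800/1000 ms (strict); reference embedder dimension 64 by default
(minimum 8, below which random projections of the bucket vector distort
cosines too much to be useful).

## Known limitations

* The reference backend is orthographic; semantic claims need a pretrained
  encoder (`inst/integration/meco_workflow.R` scripts that workflow,
  including the full worked-example reproduction and corpus-scale
  validation; it requires downloads and is excluded from the offline suite).
* Mixed-model coefficients, the ~3% empirical filtering share, by-language
  correlation ranges and convergent-validity correlations from full-corpus
  analyses are likewise only reproducible through that workflow.
* Scores depend on the embedding backend; comparisons across studies are
  only meaningful with the backend pinned (hence the provenance headers).
* Unspaced scripts and morphological segmentation are out of scope; the
  orthographic word is the unit throughout.
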