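# wordinfo

Quantifying how informative each word is to the meaning of the sentence it
appears in, and validating that score against eye-movement reading behavior.

Readers do not treat all words equally: some words carry the message, others
are scaffolding, and eye movements during reading reflect the difference.
`wordinfo` computes an objective, interpretable, multilingual word-importance
score from sentence embeddings. For word *i* in sentence *j*,

```
d_ij = 1 − cos( embed(sentence_j), embed(sentence_j without word_i) )
I_ij = ln(d_ij)
```

Removing a dispensable word barely moves the sentence vector (d near 0, very
negative I); removing a message-bearing word moves it a lot (I nearer 0).
The natural-log transform removes the strong right skew of the raw
dissimilarities. Scores below −10 are flagged as estimation outliers and
excluded from all summaries.

The package is for psycholinguists and reading researchers who want to score
their own materials, correlate the score with the standard covariates
(length, Zipf-transformed frequency, embedding-based predictability), and
build model-ready tables from interest-area fixation reports. It ships a
deterministic reference embedder so the full pipeline runs and tests offline;
pretrained multilingual sentence encoders plug in at run time via
`register_embedder()`.

## Worked example

The score is context specific — the same word can be crucial in one sentence
and redundant in another:

```r
library(wordinfo)
library(dplyr)

spec <- embedder_spec(backend = "reference", dim = 64, seed = 1)
s1 <- sentence("the wedding was ruined by the heavy rain and snow", "s1")
s2 <- sentence("the royal couple married in a beautiful wedding ceremony", "s2")
bind_rows(score_sentence(s1, spec), score_sentence(s2, spec)) |>
  filter(word == "wedding")
#>   sentence_id token_index    word cosine_full_vs_partial raw_dissimilarity
#> 1          s1           1 wedding                  0.826            0.1744
#> 2          s2           7 wedding                  0.951            0.0495
#>   informativeness outlier clamped
#> 1           -1.75   FALSE   FALSE
#> 2           -3.01   FALSE   FALSE
```

In the first sentence "wedding" is never mentioned again yet defines what
was ruined, and its score is high (−1.75, close to 0); in the second it is
topically redundant and scores low (−3.01). One record is produced per word
token: the cosine between the full and leave-one-out sentence embeddings,
the raw dissimilarity `1 − cosine`, the log score, and outlier/clamp flags.

The package also bundles the published per-word values for a 28-token
example sentence under the pinned pretrained multilingual encoder
(`example_sentence_values()`), e.g. content words like "inventions" (−3.542)
and "machines" (−2.976) versus function words like "of" (−6.698) — useful
for checking the arithmetic (`exp(−2.976) ≈ 0.051 = 1 − 0.949`) and as a
target for the optional pretrained-backend workflow.

Beyond scoring, the pipeline goes all the way to analysis tables:
`read_ia_report()` → `filter_ia()` (strict 80/2000/800/1000 ms rules) →
`derive_dvs()` (skipping, first fixation, gaze, total time, rereading) →
`build_model_table()` (joins scores, covariates and skill composites,
centers and scales) → `fit_effect_check()` (a desk-scale fixed-effects
check; export the table for real mixed-model inference). A seeded synthetic
generator (`synth_config()`, `make_corpus()`, `make_eye_data()`) provides
ground-truth data for all of it, and a `wordinfo` CLI script
(`inst/cli/wordinfo`) wraps the file-level workflow
(`score`, `predictability`, `describe`, `build-table`, `simulate`).

See the vignette (`vignettes/word-informativeness.Rmd`) for the model,
conventions, and the generator's assumptions, and
`inst/integration/meco_workflow.R` for the optional full-corpus workflow
with a pretrained encoder (requires downloads; not part of the test suite).

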