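# Optional integration workflow: full-corpus validation with the pretrained
# multilingual encoder and the MECO eye-movement corpus.
#
# This script is NOT part of the offline test suite. It needs:
#   * network access (or local copies) for the MECO interest-area reports,
#     frequency tables, and individual-differences scores,
#   * a Python environment with `sentence-transformers`, to serve the pinned
#     encoder "distiluse-base-multilingual-cased-v2",
#   * a mixed-model stack (lme4/lmerTest) for the inferential models.
#
# What it reproduces (and the offline suite, by design, does not):
#   * all 28 printed worked-example rows within |delta| <= 0.05 under the
#     pinned encoder,
#   * the ~3% interest-area filtering proportion,
#   * by-language correlations of informativeness with length (0.25..0.56),
#     Zipf frequency (-0.63..-0.2) and predictability (-0.55..-0.1),
#   * the informativeness-surprisal correlation (~0.29, English L2 texts),
#   * the 0.5..0.65 convergent-validity range against word-sentence cosine,
#   * the crossed mixed-effects models behind the validation tables.
#
# Usage:
#   Rscript meco_workflow.R --ia meco_ia.csv --sentences sentences.tsv \
#     --skills skills.csv --python python3 --out results/
suppressPackageStartupMessages(library(wordinfo))

args <- commandArgs(trailingOnly = TRUE)
opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
python <- opt("--python", "python3")
out_dir <- opt("--out", "integration-results")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# --- pretrained encoder served through a persistent embedding cache --------
# Texts are embedded in one Python batch call and cached to TSV; the R side
# registers a backend that reads from the cache, so wordinfo's scoring code
# path is identical to the offline one.
cache_file <- file.path(out_dir, "embedding_cache.tsv")
embed_batch_py <- function(texts) {
  tmp_in <- tempfile(fileext = ".txt"); writeLines(texts, tmp_in)
  tmp_out <- tempfile(fileext = ".tsv")
  code <- paste(
    "import sys",
    "from sentence_transformers import SentenceTransformer",
    "m = SentenceTransformer('distiluse-base-multilingual-cased-v2')",
    "texts = [l.rstrip('\\n') for l in open(sys.argv[1], encoding='utf-8')]",
    "vecs = m.encode(texts, normalize_embeddings=True)",
    "with open(sys.argv[2], 'w', encoding='utf-8') as f:",
    "    for t, v in zip(texts, vecs):",
    "        f.write(t + '\\t' + ' '.join(repr(float(x)) for x in v) + '\\n')",
    sep = "\n")
  status <- system2(python, c("-c", shQuote(code), tmp_in, tmp_out))
  stopifnot(status == 0L)
  file.append(cache_file, tmp_out)
}
load_cache <- function() {
  if (!file.exists(cache_file)) return(new.env(parent = emptyenv()))
  env <- new.env(parent = emptyenv())
  for (line in readLines(cache_file, encoding = "UTF-8")) {
    kv <- strsplit(line, "\t", fixed = TRUE)[[1]]
    assign(kv[1], as.numeric(strsplit(kv[2], " ")[[1]]), envir = env)
  }
  env
}
cache <- load_cache()
register_embedder("distiluse-base-multilingual-cased-v2", function(text, spec) {
  v <- get0(text, envir = cache)
  if (is.null(v)) {
    embed_batch_py(text)
    cache <<- load_cache()
    v <- get0(text, envir = cache)
  }
  v
})
spec <- embedder_spec(backend = "distiluse-base-multilingual-cased-v2", dim = 512L)

# --- 1. worked-example rows under the pinned encoder -----------------------
ex <- example_sentences()
vals <- example_sentence_values()
s1 <- sentence(ex$raw_text[1], "ex1", "en")
embed_batch_py(c(s1$raw_text,
                 vapply(seq_len(nrow(s1$tokens)) - 1L, remove_word,
                        character(1), sent = s1)))
cache <- load_cache()
sc <- score_sentence(s1, spec)
delta <- abs(sc$informativeness - vals$informativeness)
message(sprintf("worked-example rows within 0.05: %d / 28", sum(delta <= 0.05)))
stopifnot(all(delta <= 0.05))

# --- 2. corpus-level pipeline ----------------------------------------------
sents_path <- opt("--sentences")
ia_path <- opt("--ia")
skills_path <- opt("--skills")
if (!is.null(sents_path) && !is.null(ia_path)) {
  sents <- read_sentences(sents_path)
  embed_batch_py(sents$raw_text)
  scores <- score_corpus(sents, spec)
  write_scores(scores, file.path(out_dir, "scores_full.tsv"), spec)

  ia <- read_ia_report(ia_path)
  filt <- filter_ia(ia)
  message(sprintf("filtered proportion: %.4f (expected ~0.03)",
                  filt$log$proportion[filt$log$rule == "total"]))
  dvs <- derive_dvs(filt$kept)
  skills <- if (!is.null(skills_path)) {
    composite_skill(tibble::as_tibble(utils::read.csv(skills_path)))
  }
  tab <- build_model_table(dvs, scores, skills = skills)
  utils::write.table(tab, file.path(out_dir, "model_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # by-language descriptives
  sums <- dplyr::bind_rows(lapply(split(scores, scores$language), function(r) {
    summarize_language(r, sents[sents$language == r$language[1], , drop = FALSE])
  }))
  utils::write.table(sums, file.path(out_dir, "language_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # crossed mixed models on the exported table (the inferential tier)
  if (requireNamespace("lme4", quietly = TRUE)) {
    fit <- lme4::lmer(log_tfd ~ length + informativeness +
                        (1 | subject) + (1 | word_in_language), data = tab)
    print(summary(fit)$coefficients)
  }
}
message("integration workflow complete; outputs under ", out_dir)
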