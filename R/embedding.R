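# Text-to-vector contract, deterministic reference embedder, cosine.

# Package-local caches: seeded projection matrices and per-token n-gram
# bucket signatures (the signature depends only on the token text).
.wi_cache <- new.env(parent = emptyenv())

#' Describe an embedding backend
#'
#' A lightweight spec naming the backend, its output dimension, the seed (for
#' the reference backend) and whether it is sensitive to word order. The
#' `"reference"` backend is a fully offline, bitwise-reproducible hashed
#' n-gram embedder (see [reference_embed()]); pretrained sentence encoders
#' (e.g. multilingual sentence-BERT models) plug in through
#' [register_embedder()] so the core package never loads them itself. Backend
#' name and seed are recorded in every score file header, because scores are
#' not comparable across backends.
#'
#' @param backend Backend name; `"reference"` is built in.
#' @param dim Output dimension (reference backend: at least 8).
#' @param seed Integer seed for the reference backend's random projection.
#' @param order_sensitive Should token position affect the vector?
#' @return An object of class `wi_embedder_spec`.
#' @export
embedder_spec <- function(backend = "reference", dim = 64L, seed = 1L,
                          order_sensitive = TRUE) {
  stopifnot(is.character(backend), length(backend) == 1L)
  dim <- as.integer(dim)
  structure(
    list(backend = backend, dim = dim, seed = as.integer(seed),
         order_sensitive = isTRUE(order_sensitive)),
    class = "wi_embedder_spec"
  )
}

#' @export
print.wi_embedder_spec <- function(x, ...) {
  cat(sprintf("<wi_embedder_spec backend=%s dim=%d seed=%d order_sensitive=%s>\n",
              x$backend, x$dim, x$seed, x$order_sensitive))
  invisible(x)
}

#' Register an external embedding backend
#'
#' Adapters for pretrained encoders are registered at run time as a function
#' `function(text, spec)` returning a numeric vector of length `spec$dim`.
#' Registration is optional plumbing: all package tests and defaults use the
#' built-in reference backend and run offline.
#'
#' @param name Backend name as used in [embedder_spec()].
#' @param fn Embedding function.
#' @export
register_embedder <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (is.null(.wi_cache$backends)) .wi_cache$backends <- new.env(parent = emptyenv())
  assign(name, fn, envir = .wi_cache$backends)
  invisible(name)
}

#' Embed a text under a backend spec
#'
#' Dispatches to the backend named in `spec`. For the `"reference"` backend
#' the result is deterministic in `(seed, dim, text)`.
#'
#' @param text A single non-empty string.
#' @param spec An [embedder_spec()].
#' @return Numeric vector of length `spec$dim`.
#' @export
embed_text <- function(text, spec) {
  stopifnot(inherits(spec, "wi_embedder_spec"))
  if (length(text) != 1L || is.na(text) || !nzchar(squish(text))) {
    wi_abort("Cannot embed empty text.", "wordinfo_empty_input")
  }
  if (spec$backend == "reference") {
    return(reference_embed(text, seed = spec$seed, dim = spec$dim,
                           order_sensitive = spec$order_sensitive))
  }
  fn <- if (!is.null(.wi_cache$backends)) {
    get0(spec$backend, envir = .wi_cache$backends)
  }
  if (is.null(fn)) {
    wi_abort(sprintf("Unknown embedding backend '%s'; register it with register_embedder().",
                     spec$backend),
             "wordinfo_config_error")
  }
  v <- as.numeric(fn(text, spec))
  if (length(v) != spec$dim || !all(is.finite(v))) {
    wi_abort(sprintf("Backend '%s' returned an invalid vector.", spec$backend),
             "wordinfo_backend_error")
  }
  v
}

# Number of hash buckets for the reference embedder (fixed; part of the
# reproducibility contract together with n-gram size 3 and decay 0.9).
.WI_N_BUCKETS <- 4096L

# Signed hashed character trigrams of one token, with boundary markers.
# Returns list(idx, sign); cached per token since it is seed-independent.
token_signature <- function(token) {
  if (is.null(.wi_cache$tok)) .wi_cache$tok <- new.env(parent = emptyenv())
  hit <- get0(token, envir = .wi_cache$tok)
  if (!is.null(hit)) return(hit)
  padded <- paste0("<", token, ">")
  n <- nchar(padded)
  starts <- seq_len(max(n - 2L, 1L))
  grams <- substring(padded, starts, pmin(starts + 2L, n))
  h <- vapply(grams, fnv1a32, numeric(1), USE.NAMES = FALSE)
  sig <- list(idx = as.integer(h %% .WI_N_BUCKETS) + 1L,
              sign = ifelse((h %/% .WI_N_BUCKETS) %% 2 == 0, 1, -1))
  assign(token, sig, envir = .wi_cache$tok)
  sig
}

projection_matrix <- function(seed, dim) {
  key <- sprintf("proj_%d_%d", seed, dim)
  if (is.null(.wi_cache$proj)) .wi_cache$proj <- new.env(parent = emptyenv())
  hit <- get0(key, envir = .wi_cache$proj)
  if (!is.null(hit)) return(hit)
  P <- with_private_rng(derive_seed(seed, "reference-projection"), function() {
    matrix(stats::rnorm(.WI_N_BUCKETS * dim), nrow = .WI_N_BUCKETS, ncol = dim)
  })
  assign(key, P, envir = .wi_cache$proj)
  P
}

#' Deterministic reference embedder
#'
#' A fully offline sentence embedder used as the test stand-in for pretrained
#' encoders. Each whitespace token contributes its hashed character trigrams
#' (with `<`/`>` boundary marks, signed 32-bit FNV-1a hashing into 4096
#' buckets), weighted by a positional decay of `0.9^index` so the encoding is
#' order sensitive; the bucket vector is projected through a seeded Gaussian
#' random matrix and L2-normalized. Consequences used throughout the tests:
#' the output is bitwise-reproducible for a given `(seed, dim, text)`, has
#' unit norm, and changes whenever any token is removed (longer tokens carry
#' more trigram mass, so removing them moves the vector further).
#'
#' This construction is a reproducible testing device, not a semantic model:
#' it knows orthography and order, never meaning.
#'
#' @param text A single non-empty string.
#' @param seed Integer seed for the random projection.
#' @param dim Output dimension, at least 8.
#' @param order_sensitive Apply the positional decay (default `TRUE`)?
#' @return Unit-norm numeric vector of length `dim`.
#' @export
reference_embed <- function(text, seed = 1L, dim = 64L, order_sensitive = TRUE) {
  if (length(text) != 1L || is.na(text) || !nzchar(squish(text))) {
    wi_abort("Cannot embed empty text.", "wordinfo_empty_input")
  }
  dim <- as.integer(dim)
  if (dim < 8L) wi_abort("Reference embedder requires dim >= 8.", "wordinfo_config_error")
  tokens <- strsplit(squish(text), " ", fixed = TRUE)[[1]]
  x <- numeric(.WI_N_BUCKETS)
  for (i in seq_along(tokens)) {
    sig <- token_signature(tokens[i])
    w <- if (order_sensitive) 0.9^(i - 1L) else 1
    for (k in seq_along(sig$idx)) {
      x[sig$idx[k]] <- x[sig$idx[k]] + sig$sign[k] * w
    }
  }
  nz <- which(x != 0)
  P <- projection_matrix(as.integer(seed), dim)
  v <- as.numeric(crossprod(P[nz, , drop = FALSE], x[nz]))
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    # astronomically unlikely (all buckets cancel); perturb deterministically
    v <- P[1L, ]
    nrm <- sqrt(sum(v^2))
  }
  v / nrm
}

#' Cosine similarity between two vectors
#'
#' `u . v / (||u|| ||v||)`, clipped into `[-1, 1]` against floating-point
#' overshoot.
#'
#' @param u,v Numeric vectors of equal length and positive norm.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    wi_abort("Vectors differ in dimension.", "wordinfo_shape_error")
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    wi_abort("Cosine is undefined for a zero-norm vector.", "wordinfo_degenerate_vector")
  }
  min(1, max(-1, sum(u * v) / (nu * nv)))
}
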