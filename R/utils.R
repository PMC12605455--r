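# Internal utilities: error signalling, a pure-R FNV-1a hash, RNG hygiene.

wi_abort <- function(message, class) {
  stop(structure(
    class = c(class, "wordinfo_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

wi_warn <- function(message, class) {
  warning(structure(
    class = c(class, "wordinfo_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, kept exact in doubles by
# splitting the multiply into 16-bit halves (hash stays in [0, 2^32)).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  if (any(bytes > 255L)) {
    # re-encode non-ASCII code points as UTF-8 bytes
    bytes <- as.integer(charToRaw(enc2utf8(x)))
  }
  h <- 2166136261
  for (b in bytes) {
    # xor on 16-bit halves (h can exceed the signed 32-bit range)
    lo <- bitwXor(h %% 65536, b)
    h <- (h %/% 65536) * 65536 + lo
    # h * 16777619 mod 2^32, exact
    hlo <- h %% 65536
    hhi <- h %/% 65536
    h <- (hlo * 16777619 + ((hhi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# Derive a valid set.seed() integer (< 2^31) from a base seed and a label.
derive_seed <- function(seed, label) {
  as.integer((fnv1a32(paste0(label, ":", format(seed))) %% 2147483647))
}

# Run fn with a private RNG stream; the caller's .Random.seed is untouched.
with_private_rng <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# Whitespace normalization used throughout: collapse runs, trim ends.
squish <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x, perl = TRUE), perl = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
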