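#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit hash of a string (FNV-1a folded to a positive integer).
# Used to derive per-utterance RNG streams from (seed, speaker, sentence).
str_hash31 <- function(x) {
  bytes <- utf8ToInt(as.character(x))
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483647L)
}

# Combine a user seed with extra keys into one 31-bit seed.
combine_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.integer(seed) %% 2147483647L
  for (k in keys) {
    kk <- if (is.character(k)) str_hash31(k) else as.integer(k) %% 2147483647L
    h <- as.integer((as.numeric(h) * 48271 + as.numeric(kk)) %% 2147483647)
  }
  if (h <= 0L) h <- h + 2147483646L
  h
}

# Evaluate expr with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
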