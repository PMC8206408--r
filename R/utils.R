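#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's .Random.seed is restored afterwards so library functions do
# not perturb user-level random streams. seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed; stays below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629)
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", what), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, what) {
  check_positive(x, what)
  if (x != as.integer(x)) {
    stop(sprintf("`%s` must be a positive integer", what), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Deterministic 32-bit polynomial hash of a character vector, as 8 hex
# digits. Used to stamp output files with a config fingerprint without a
# hashing dependency; not cryptographic.
config_hash <- function(s) {
  bytes <- as.double(charToRaw(paste(s, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
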