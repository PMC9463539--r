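# internal helpers: seeded substreams, validation, hashing

# Derive a reproducible child seed from a root seed and a stream index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stream) * 16807 + 1
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

stopifnot_prob_vector <- function(p, n = N_CLASSES, tol = 1e-9, what = "probability vector") {
  if (length(p) != n || anyNA(p) || any(p < -tol) || any(p > 1 + tol))
    stop(what, " must be ", n, " probabilities in [0, 1]")
  if (abs(sum(p) - 1) > tol)
    stop(what, " must sum to 1 (got ", format(sum(p)), ")")
  invisible(TRUE)
}

clamp01 <- function(x) {  # preserves dim attributes, unlike pmin(1, ...)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Stable polynomial hash of a character scalar (hex); used for config hashes.
# Arithmetic stays below 2^53 so the result is exact in doubles.
string_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 1048573 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Canonical JSON of a (possibly nested) list with keys sorted recursively,
# so the hash is stable under key reordering.
canonical_json <- function(x) {
  sort_keys <- function(v) {
    if (is.list(v)) {
      nm <- names(v)
      if (!is.null(nm) && any(nzchar(nm))) v <- v[order(nm)]
      lapply(v, sort_keys)
    } else v
  }
  jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = NA, null = "null")
}
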