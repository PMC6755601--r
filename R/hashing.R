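MERSENNE_P61 <- 2^61 - 1
HASH_MAX32 <- 2^32 - 1

#' Hash a string to a 32-bit unsigned integer
#'
#' SHA-1 of the UTF-8 bytes of each string, truncated to the first four
#' digest bytes read big-endian. Deterministic across platforms and runs;
#' this is the map from shingle strings into the MinHash universe
#' `{0, ..., 2^32 - 1}`.
#'
#' @param x Character vector of non-empty strings.
#' @return Numeric vector of integers in `[0, 2^32 - 1]` (numeric because
#'   R's integer type is signed 32-bit).
#' @export
hash_string_32 <- function(x) {
  stopifnot(is.character(x), all(nzchar(x)))
  vapply(enc2utf8(x), function(s) {
    d <- openssl::sha1(charToRaw(s))
    sum(as.numeric(d[1:4]) * c(16777216, 65536, 256, 1))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Expected number of hash collisions (birthday-problem estimate)
#'
#' Expected number of colliding insertions when `m` uniformly distributed
#' hash values are drawn from `N` possible values:
#' `c(m, N) = m - N * (1 - ((N - 1) / N)^m)`.
#' Evaluated as `m + N * expm1(m * log1p(-1/N))`, which keeps precision at
#' `N = 2^32 - 1` where naive powering of `(N-1)/N` loses all significant
#' digits of the tiny exponent.
#'
#' @param m Number of hashed values (>= 0). Vectorized.
#' @param N Number of available hash slots (>= 1).
#' @return Expected collision count, in `[0, m)`.
#' @examples
#' estimate_collisions(197604, 2^32 - 1)   # ~4.546
#' estimate_collisions(2022448, 2^32 - 1)  # ~476.098
#' @export
estimate_collisions <- function(m, N) {
  stopifnot(all(m >= 0), all(N >= 1))
  m + N * expm1(m * log1p(-1 / N))
}

# Seed-scoped RNG: fixed kind, prior state restored on exit.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

#' Generate the MinHash universal-hash family
#'
#' Draws the coefficient vectors of the k hash functions
#' `h_i(v) = ((a_i * v + b_i) mod p) mod (2^32 - 1)` with
#' `p = 2^61 - 1` (Mersenne prime). Entries of `a` are distinct and nonzero
#' (a zero multiplier would collapse its hash function to a constant);
#' entries of `b` are distinct in `{0, ..., 2^32 - 1}`. Sampling without
#' replacement under a fixed RNG kind makes regeneration with the same
#' `(k, seed)` bit-identical.
#'
#' @param k Number of hash functions (fingerprint dimensionality), >= 1.
#' @param seed Integer seed (default 42).
#' @return An object of class `minhash_params`: list with fields `a`, `b`
#'   (numeric vectors of length `k`), `p`, `k`, `seed` and a short
#'   `fingerprint` digest identifying the family.
#' @export
generate_permutations <- function(k, seed = 42L) {
  stopifnot(k >= 1)
  k <- as.integer(k)
  ab <- with_local_seed(seed, {
    a <- sample.int(HASH_MAX32, k)            # distinct, in [1, 2^32 - 1]
    b <- sample.int(HASH_MAX32 + 1, k) - 1    # distinct, in [0, 2^32 - 1]
    list(a = as.numeric(a), b = as.numeric(b))
  })
  params <- structure(
    list(a = ab$a, b = ab$b, p = MERSENNE_P61, k = k, seed = as.integer(seed)),
    class = "minhash_params"
  )
  params$fingerprint <- params_digest(params)
  params
}

params_digest <- function(params) {
  key <- paste(c(format(params$p, digits = 22), params$k,
                 params$a, params$b), collapse = ",")
  substr(paste(as.character(openssl::sha1(charToRaw(key))), collapse = ""), 1, 12)
}

#' @export
print.minhash_params <- function(x, ...) {
  cat("MinHash hash family: k =", x$k, ", p = 2^61 - 1, seed =", x$seed,
      "\n  fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

#' Serialize / restore a MinHash hash family
#'
#' The JSON document stores `k`, `seed`, `p` and the full coefficient
#' vectors, so an index built elsewhere can be queried with bit-identical
#' hashing.
#'
#' @param params A `minhash_params` object.
#' @param path File path for the JSON document.
#' @return `write_minhash_params` returns `path` invisibly;
#'   `read_minhash_params` returns a `minhash_params` object.
#' @export
write_minhash_params <- function(params, path) {
  stopifnot(inherits(params, "minhash_params"))
  jsonlite::write_json(
    list(k = params$k, seed = params$seed, p = format(params$p, digits = 22),
         a = params$a, b = params$b),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_minhash_params
#' @export
read_minhash_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- structure(
    list(a = as.numeric(doc$a), b = as.numeric(doc$b), p = MERSENNE_P61,
         k = as.integer(doc$k), seed = as.integer(doc$seed)),
    class = "minhash_params"
  )
  params$fingerprint <- params_digest(params)
  params
}

check_hash_values <- function(values) {
  values <- unique(as.numeric(values))
  if (length(values) == 0) {
    stop("MinHash of the empty set is undefined", call. = FALSE)
  }
  if (any(values < 0 | values > HASH_MAX32 | values != trunc(values))) {
    stop("hash values must be integers in [0, 2^32 - 1]", call. = FALSE)
  }
  values
}

#' MinHash a set of 32-bit hash values
#'
#' Component i of the result is
#' `min over v of ((a_i * v + b_i) mod p) mod (2^32 - 1)`, computed with
#' exact integer arithmetic (the intermediate product needs more than 64
#' bits). The fraction of equal components between two MinHash vectors
#' sharing a hash family is an unbiased estimator of the Jaccard similarity
#' of the underlying sets.
#'
#' @param values Numeric vector of distinct integers in `[0, 2^32 - 1]`
#'   (duplicates are removed). Must be non-empty.
#' @param params A `minhash_params` object from [generate_permutations()].
#' @return An object of class `minhash_fp`: numeric vector of length
#'   `params$k` with components in `[0, 2^32 - 2]` and attribute
#'   `params_fingerprint`.
#' @export
minhash <- function(values, params) {
  stopifnot(inherits(params, "minhash_params"))
  values <- check_hash_values(values)
  new_minhash_fp(minhash_cpp(values, params$a, params$b), params)
}

new_minhash_fp <- function(components, params) {
  structure(as.numeric(components), class = "minhash_fp",
            params_fingerprint = params$fingerprint)
}

#' @export
print.minhash_fp <- function(x, ...) {
  cat("MinHash fingerprint: k =", length(x),
      ", hash family", attr(x, "params_fingerprint"), "\n")
  cat("  components:", paste(format(head(unclass(x), 6), scientific = FALSE),
                             collapse = " "),
      if (length(x) > 6) "...\n" else "\n")
  invisible(x)
}
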