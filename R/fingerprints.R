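#' Exact Jaccard (Tanimoto) similarity of two sets
#'
#' `J(A, B) = |intersect(A, B)| / |union(A, B)|`. Inputs are treated as sets
#' (duplicates removed). The companion distance is `1 - J(A, B)`, a metric.
#'
#' @param A,B Vectors over a common universe (strings or integers); not both
#'   empty.
#' @return Similarity in `[0, 1]`.
#' @seealso [jaccard_estimated()], [jaccard_distance()]
#' @export
jaccard_exact <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0) stop("Jaccard similarity of two empty sets is undefined (0/0)",
                   call. = FALSE)
  length(intersect(A, B)) / u
}

#' Estimated Jaccard similarity from MinHash fingerprints
#'
#' The fraction of positions where two MinHash vectors agree. Both vectors
#' must come from the same hash family (same `params_fingerprint`); estimates
#' across different families are meaningless and raise an error. The
#' estimator is unbiased with standard error `sqrt(J(1-J)/k)`.
#'
#' @param u,v `minhash_fp` objects of equal length.
#' @return Similarity estimate in `[0, 1]`.
#' @export
jaccard_estimated <- function(u, v) {
  stopifnot(inherits(u, "minhash_fp"), inherits(v, "minhash_fp"))
  if (length(u) != length(v)) {
    stop("MinHash vectors have different k (", length(u), " vs ", length(v),
         ")", call. = FALSE)
  }
  if (!identical(attr(u, "params_fingerprint"), attr(v, "params_fingerprint"))) {
    stop("MinHash vectors come from different hash families; ",
         "their component matches do not estimate Jaccard similarity",
         call. = FALSE)
  }
  mean(unclass(u) == unclass(v))
}

#' Jaccard distance
#'
#' `1 - similarity`, dispatching on input type: MinHash fingerprints are
#' compared with [jaccard_estimated()], plain sets with [jaccard_exact()].
#'
#' @param x,y Two `minhash_fp` objects, or two plain set vectors.
#' @return Distance in `[0, 1]`.
#' @export
jaccard_distance <- function(x, y) {
  if (inherits(x, "minhash_fp") || inherits(y, "minhash_fp")) {
    1 - jaccard_estimated(x, y)
  } else {
    1 - jaccard_exact(x, y)
  }
}

#' MHFP: MinHash fingerprint of a molecule
#'
#' The composition `minhash(hash_string_32(shingling(smiles)))`: the
#' molecular shingling is enumerated, each shingle SMILES hashed to a 32-bit
#' integer with SHA-1, and the resulting hash set min-hashed. Defaults
#' (`radius = 3`, `k = 2048`) give MHFP6, the recommended variant; fingerprint
#' names follow the diameter convention, so radius 2 is MHFP4 and radius 4 is
#' MHFP8.
#'
#' @param smiles Character vector of SMILES strings.
#' @param k Fingerprint dimensionality (number of hash functions); common
#'   choices 128, 1024, 2048, 4096. Ignored when `params` is supplied.
#' @param radius Maximum shingle radius in bonds (default 3).
#' @param params Optional `minhash_params`; generated from `(k, seed)` when
#'   omitted.
#' @param seed Seed for hash-family generation when `params` is omitted.
#' @param simplify If `TRUE` (default) return a bare `minhash_fp` for a
#'   single input instead of a length-1 list.
#' @inheritParams shingling_from_smiles
#' @return A `minhash_fp`, or a list of them for multiple inputs.
#' @examples
#' \dontrun{
#' fp <- mhfp_from_smiles("CCO")            # MHFP6, k = 2048
#' fp128 <- mhfp_from_smiles("CCO", k = 128)
#' }
#' @export
mhfp_from_smiles <- function(smiles, k = 2048, radius = 3, params = NULL,
                             seed = 42L, rings = TRUE, min_radius = 1,
                             isomeric = FALSE, simplify = TRUE) {
  if (is.null(params)) params <- generate_permutations(k, seed)
  sh <- shingling_from_smiles(smiles, radius = radius, rings = rings,
                              min_radius = min_radius, isomeric = isomeric,
                              simplify = FALSE)
  fps <- lapply(sh, function(s) minhash(hash_string_32(s), params))
  names(fps) <- names(smiles)
  if (simplify && length(fps) == 1L) fps[[1L]] else fps
}

#' MHECFP: MinHash over unfolded circular-fingerprint hashes
#'
#' Applies MinHash to a set of externally supplied 32-bit hash identifiers,
#' typically the unfolded ECFP (Morgan) hashes of a molecule as produced by a
#' chemistry toolkit (see [ecfp_hashes_from_smiles()]). This is the control
#' fingerprint separating the effect of min-hashing from the effect of the
#' SMILES shingling; it is definitionally `minhash(hashes, params)`.
#'
#' @param hashes Numeric vector of distinct integers in `[0, 2^32 - 1]`;
#'   identifiers wider than 32 bits must be reduced mod 2^32 by the caller.
#' @param params A `minhash_params` object.
#' @return A `minhash_fp`.
#' @export
mhecfp_from_hashes <- function(hashes, params) {
  minhash(hashes, params)
}

#' Fold a hash set modulo a fingerprint length
#'
#' The folding operation of binary circular fingerprints: each hash sets bit
#' `h mod D`.
#'
#' @param hashes Numeric vector of integers in `[0, 2^32 - 1]`.
#' @param D Fingerprint length (>= 1).
#' @return Sorted unique 0-based bit indices in `[0, D)`.
#' @export
fold_hashes <- function(hashes, D) {
  stopifnot(D >= 1)
  hashes <- check_hash_values(hashes)
  sort(unique(hashes %% D))
}

#' SECFP: folded binary SMILES extended connectivity fingerprint
#'
#' The shingling hash set folded into a `D`-bit binary fingerprint by the
#' modulo operation, i.e. `set_bits = { sha1_32(s) mod D }` over the
#' molecular shingling. Defaults (`D = 2048`, `radius = 3`) give SECFP6.
#'
#' @inheritParams mhfp_from_smiles
#' @param D Fingerprint length in bits (default 2048).
#' @return An object of class `secfp` (fields `length`, `set_bits`), or a
#'   list of them for multiple inputs.
#' @export
secfp_from_smiles <- function(smiles, D = 2048, radius = 3, rings = TRUE,
                              min_radius = 1, isomeric = FALSE,
                              simplify = TRUE) {
  sh <- shingling_from_smiles(smiles, radius = radius, rings = rings,
                              min_radius = min_radius, isomeric = isomeric,
                              simplify = FALSE)
  fps <- lapply(sh, function(s) {
    new_secfp(fold_hashes(hash_string_32(s), D), D)
  })
  names(fps) <- names(smiles)
  if (simplify && length(fps) == 1L) fps[[1L]] else fps
}

new_secfp <- function(set_bits, D) {
  structure(list(length = as.integer(D),
                 set_bits = as.integer(sort(unique(set_bits)))),
            class = "secfp")
}

#' @export
print.secfp <- function(x, ...) {
  cat("SECFP binary fingerprint: D =", x$length, ",", length(x$set_bits),
      "bits set\n")
  invisible(x)
}

#' Jaccard similarity of two binary fingerprints
#'
#' @param a,b `secfp` objects of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_secfp <- function(a, b) {
  stopifnot(inherits(a, "secfp"), inherits(b, "secfp"),
            a$length == b$length)
  jaccard_exact(a$set_bits, b$set_bits)
}

secfp_to_hex <- function(fp) {
  nbytes <- ceiling(fp$length / 8)
  bits <- raw(nbytes * 8)
  bits[fp$set_bits + 1L] <- as.raw(1)
  # bit i lands in byte i %/% 8, MSB-first within the byte
  bytes <- vapply(seq_len(nbytes), function(j) {
    chunk <- as.integer(bits[((j - 1L) * 8L + 1L):(j * 8L)])
    sum(chunk * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L))
  }, numeric(1))
  paste(sprintf("%02x", bytes), collapse = "")
}

hex_to_secfp <- function(hex, D) {
  bytes <- strtoi(substring(hex, seq(1, nchar(hex), 2),
                            seq(2, nchar(hex), 2)), 16L)
  bits <- unlist(lapply(bytes, function(b) as.integer(intToBits(b))[8:1]))
  new_secfp(which(bits[seq_len(D)] == 1L) - 1L, D)
}

#' Write and read fingerprint files
#'
#' One record per line: the identifier, a tab, then either the `k`
#' comma-separated integer components (MinHash) or a `D`-bit hex string
#' (SECFP). A JSON sidecar `<path>.json` records the fingerprint type and,
#' for MinHash, the full hash family, so fingerprints read back are
#' comparable with newly computed ones.
#'
#' @param fps List of `minhash_fp` or of `secfp` objects (mixed lists are
#'   rejected).
#' @param path Output file; the sidecar goes to `paste0(path, ".json")`.
#' @param ids Identifiers; defaults to `names(fps)` or record numbers.
#' @param params The `minhash_params` shared by MinHash fingerprints
#'   (required for them, ignored for SECFP).
#' @return `write_fingerprints` returns `path` invisibly;
#'   `read_fingerprints` returns a named list of fingerprints with the
#'   hash-family parameters attached as attribute `params` when present.
#' @export
write_fingerprints <- function(fps, path, ids = NULL, params = NULL) {
  stopifnot(is.list(fps), length(fps) >= 1)
  if (is.null(ids)) ids <- names(fps)
  if (is.null(ids)) ids <- as.character(seq_along(fps))
  is_mh <- vapply(fps, inherits, logical(1), "minhash_fp")
  is_bin <- vapply(fps, inherits, logical(1), "secfp")
  if (all(is_mh)) {
    if (is.null(params)) stop("params required to write MinHash fingerprints",
                              call. = FALSE)
    fpr <- vapply(fps, attr, character(1), "params_fingerprint")
    if (!all(fpr == params$fingerprint)) {
      stop("fingerprints were not computed with the supplied hash family",
           call. = FALSE)
    }
    body <- vapply(fps, function(fp) {
      paste(format(unclass(fp), scientific = FALSE, trim = TRUE),
            collapse = ",")
    }, character(1))
    meta <- list(type = "minhash", k = params$k, seed = params$seed,
                 a = params$a, b = params$b)
  } else if (all(is_bin)) {
    D <- unique(vapply(fps, `[[`, integer(1), "length"))
    stopifnot(length(D) == 1)
    body <- vapply(fps, secfp_to_hex, character(1))
    meta <- list(type = "secfp", D = D)
  } else {
    stop("fps must be all minhash_fp or all secfp", call. = FALSE)
  }
  writeLines(paste(ids, body, sep = "\t"), path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (identical(meta$type, "minhash")) {
    params <- structure(
      list(a = as.numeric(meta$a), b = as.numeric(meta$b), p = MERSENNE_P61,
           k = as.integer(meta$k), seed = as.integer(meta$seed)),
      class = "minhash_params"
    )
    params$fingerprint <- params_digest(params)
    fps <- lapply(parts, function(p) {
      new_minhash_fp(as.numeric(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]]),
                     params)
    })
  } else if (identical(meta$type, "secfp")) {
    params <- NULL
    fps <- lapply(parts, function(p) hex_to_secfp(p[[2L]], meta$D))
  } else {
    stop("unknown fingerprint file type: ", meta$type, call. = FALSE)
  }
  names(fps) <- ids
  attr(fps, "params") <- params
  fps
}
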