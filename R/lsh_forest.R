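#' Create an LSH Forest index over MinHash fingerprints
#'
#' The index splits each k-component MinHash vector into `l` contiguous
#' blocks of `depth = k / l` components; block `t` is the key of the vector
#' in prefix tree `t`. Queries walk all trees from the deepest matching
#' prefix, relax the prefix depth until enough candidates are gathered, then
#' re-rank candidates by their estimated Jaccard distance to the query and
#' return the top hits (oversampling factor `kc`).
#'
#' The prefix trees are realized as sorted key arrays with binary search, a
#' contract-equivalent representation. Build with [lsh_add()] then
#' [lsh_freeze()]; query with [lsh_query()]. Indexes are mutable
#' (environment-backed) and must be frozen before querying.
#'
#' @param k Fingerprint dimensionality of the vectors to be indexed.
#' @param l Number of prefix trees; must divide `k` (typical values
#'   8 to 256).
#' @return An object of class `lsh_forest`.
#' @examples
#' \dontrun{
#' idx <- lsh_forest(k = 128, l = 8)
#' lsh_add(idx, "mol1", fp1)
#' lsh_freeze(idx)
#' lsh_query(idx, fp1, k_neighbors = 5)
#' }
#' @export
lsh_forest <- function(k, l = 32) {
  k <- as.integer(k); l <- as.integer(l)
  stopifnot(k >= 1, l >= 1)
  if (k %% l != 0) {
    stop("l (", l, ") must divide k (", k, ")", call. = FALSE)
  }
  index <- new.env(parent = emptyenv())
  index$k <- k
  index$l <- l
  index$depth <- k %/% l
  index$ids <- character(0)
  index$fps <- list()
  index$params_fingerprint <- NULL
  index$frozen <- FALSE
  index$store <- NULL
  index$trees <- NULL
  class(index) <- "lsh_forest"
  index
}

#' @export
print.lsh_forest <- function(x, ...) {
  cat("LSH Forest index: l =", x$l, "trees, depth =", x$depth,
      "(k =", x$k, ")\n  entries:", lsh_size(x),
      if (x$frozen) " [frozen]\n" else " [building]\n")
  invisible(x)
}

#' Number of indexed fingerprints
#' @param index An `lsh_forest`.
#' @return Integer count.
#' @export
lsh_size <- function(index) {
  if (index$frozen) length(index$ids) else length(index$fps)
}

#' Add a fingerprint to an LSH Forest index
#'
#' @param index An unfrozen `lsh_forest`.
#' @param id Record identifier, unused so far.
#' @param fp A `minhash_fp` of length `index$k`.
#' @return The index, invisibly (modified in place).
#' @export
lsh_add <- function(index, id, fp) {
  stopifnot(inherits(index, "lsh_forest"), inherits(fp, "minhash_fp"))
  if (index$frozen) stop("index is frozen; no further additions", call. = FALSE)
  id <- as.character(id)
  if (length(fp) != index$k) {
    stop("fingerprint has k = ", length(fp), " but index expects k = ",
         index$k, call. = FALSE)
  }
  if (!is.null(index$fps[[id]])) {
    stop("duplicate identifier: ", shQuote(id), call. = FALSE)
  }
  fpr <- attr(fp, "params_fingerprint")
  if (is.null(index$params_fingerprint)) {
    index$params_fingerprint <- fpr
  } else if (!identical(index$params_fingerprint, fpr)) {
    stop("fingerprint comes from a different hash family than the index",
         call. = FALSE)
  }
  index$fps[[id]] <- as.numeric(fp)
  invisible(index)
}

# Components are < 2^32 - 1, so 10 zero-padded decimal digits encode each
# one; lexicographic order of the concatenated digits equals numeric order
# of the component sequence.
KEY_W <- 10L

encode_keys <- function(block) {
  s <- matrix(sprintf("%010.0f", block), nrow = nrow(block))
  do.call(paste0, asplit(s, 1))
}

# First index i with keys[i] >= x (keys sorted ascending), length(keys)+1 if
# none. Keys and x are digit-only ASCII, so `<` is locale-safe here.
lower_bound <- function(keys, x) {
  lo <- 1L
  hi <- length(keys) + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (keys[mid] < x) lo <- mid + 1L else hi <- mid
  }
  lo
}

# Smallest key string strictly above every key starting with `pre`:
# increment the last component block by one (components stay < 10^10 - 1).
next_prefix <- function(pre) {
  d <- nchar(pre) %/% KEY_W
  last <- as.numeric(substr(pre, (d - 1L) * KEY_W + 1L, d * KEY_W))
  paste0(substr(pre, 1L, (d - 1L) * KEY_W), sprintf("%010.0f", last + 1))
}

#' Finalize an LSH Forest index for querying
#'
#' Builds the sorted prefix-key arrays of all `l` trees and the fingerprint
#' store used for re-ranking. After freezing, additions are rejected and
#' queries become available.
#'
#' @param index An `lsh_forest` with at least one entry.
#' @return The index, invisibly (modified in place).
#' @export
lsh_freeze <- function(index) {
  stopifnot(inherits(index, "lsh_forest"))
  if (index$frozen) return(invisible(index))
  n <- length(index$fps)
  index$ids <- if (n > 0) names(index$fps) else character(0)
  index$store <- if (n > 0) {
    matrix(unlist(index$fps, use.names = FALSE), nrow = index$k)
  } else {
    matrix(numeric(0), nrow = index$k)
  }
  index$trees <- lapply(seq_len(index$l), function(t) {
    rows <- ((t - 1L) * index$depth + 1L):(t * index$depth)
    if (n == 0) return(list(keys = character(0), ord = integer(0)))
    keys <- encode_keys(index$store[rows, , drop = FALSE])
    ord <- order(keys, method = "radix")
    list(keys = keys[ord], ord = ord)
  })
  index$fps <- NULL
  index$frozen <- TRUE
  invisible(index)
}

#' Query an LSH Forest index for approximate nearest neighbors
#'
#' Gathers candidates by walking all `l` prefix trees from the deepest
#' prefix of the query's key blocks, relaxing the depth one component at a
#' time until at least `kc * k_neighbors` distinct candidates are found (or
#' depth 0, i.e. the whole index, is reached). Candidates are then re-ranked
#' by estimated Jaccard distance to the query, ties broken by insertion
#' order, and the best `k_neighbors` returned. With
#' `kc * k_neighbors >= lsh_size(index)` the result equals brute-force
#' ranking ([linear_scan_knn()]).
#'
#' @param index A frozen `lsh_forest`.
#' @param fp Query `minhash_fp` from the same hash family.
#' @param k_neighbors Number of neighbors to return (>= 1).
#' @param kc Oversampling factor (default 10): `kc * k_neighbors` candidates
#'   are gathered internally before re-ranking.
#' @return A `data.frame` with columns `id` and `distance` (estimated
#'   Jaccard distance), in nondecreasing distance order.
#' @export
lsh_query <- function(index, fp, k_neighbors, kc = 10) {
  stopifnot(inherits(index, "lsh_forest"), inherits(fp, "minhash_fp"),
            k_neighbors >= 1, kc >= 1)
  if (!index$frozen) stop("index must be frozen before querying", call. = FALSE)
  n <- length(index$ids)
  if (n == 0) {
    return(data.frame(id = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (length(fp) != index$k) {
    stop("query fingerprint has k = ", length(fp), " but index expects k = ",
         index$k, call. = FALSE)
  }
  if (!identical(attr(fp, "params_fingerprint"), index$params_fingerprint)) {
    stop("query fingerprint comes from a different hash family than the index",
         call. = FALSE)
  }
  target <- min(kc * k_neighbors, n)
  q <- as.numeric(fp)
  qkeys <- vapply(seq_len(index$l), function(t) {
    rows <- ((t - 1L) * index$depth + 1L):(t * index$depth)
    paste(sprintf("%010.0f", q[rows]), collapse = "")
  }, character(1))

  seen <- logical(n)
  count <- 0L
  for (d in index$depth:1) {
    for (t in seq_len(index$l)) {
      pre <- substr(qkeys[t], 1L, d * KEY_W)
      tr <- index$trees[[t]]
      lo <- lower_bound(tr$keys, pre)
      hi <- lower_bound(tr$keys, next_prefix(pre))
      if (hi > lo) {
        hits <- tr$ord[lo:(hi - 1L)]
        new <- hits[!seen[hits]]
        if (length(new)) {
          seen[new] <- TRUE
          count <- count + length(new)
        }
      }
    }
    if (count >= target) break
  }
  if (count < target) {
    cand <- seq_len(n)          # depth 0: the empty prefix matches everything
  } else {
    cand <- which(seen)
  }
  dist <- 1 - colMeans(index$store[, cand, drop = FALSE] == q)
  top <- head(order(dist, cand), k_neighbors)
  data.frame(id = index$ids[cand[top]], distance = dist[top],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Brute-force k-nearest neighbors by estimated Jaccard distance
#'
#' Linear scan over every indexed fingerprint; the ground truth against
#' which approximate results are scored. Uses the same distance and the same
#' insertion-order tie-breaking as [lsh_query()].
#'
#' @inheritParams lsh_query
#' @return A `data.frame` with columns `id` and `distance`.
#' @export
linear_scan_knn <- function(index, fp, k_neighbors) {
  stopifnot(inherits(index, "lsh_forest"), k_neighbors >= 1)
  if (!index$frozen) stop("index must be frozen before querying", call. = FALSE)
  n <- length(index$ids)
  if (n == 0) {
    return(data.frame(id = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  dist <- 1 - colMeans(index$store == as.numeric(fp))
  top <- head(order(dist, seq_len(n)), k_neighbors)
  data.frame(id = index$ids[top], distance = dist[top],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Recovery rate of an approximate k-NN result
#'
#' Fraction of the true (brute-force) top-k identifiers present in the
#' approximate top-k.
#'
#' @param ann_ids Identifiers returned by the approximate search, best
#'   first.
#' @param exact_ids Identifiers from brute-force linear scan, best first;
#'   length >= `k_neighbors`.
#' @param k_neighbors Number of neighbors scored.
#' @return A number in `[0, 1]`.
#' @export
recovery_rate <- function(ann_ids, exact_ids, k_neighbors) {
  stopifnot(k_neighbors >= 1, length(exact_ids) >= k_neighbors)
  length(intersect(head(ann_ids, k_neighbors),
                   head(exact_ids, k_neighbors))) / k_neighbors
}

#' Save and restore an LSH Forest index
#'
#' The on-disk form is a single RDS archive holding a JSON header (l, depth,
#' k, hash-family fingerprint, n) plus identifiers and the fingerprint
#' store; prefix trees are rebuilt on load.
#'
#' @param index A frozen `lsh_forest`.
#' @param path File path.
#' @return `lsh_save` returns `path` invisibly; `lsh_load` returns a frozen
#'   `lsh_forest`.
#' @export
lsh_save <- function(index, path) {
  stopifnot(inherits(index, "lsh_forest"))
  if (!index$frozen) stop("freeze the index before saving", call. = FALSE)
  header <- jsonlite::toJSON(
    list(format = "minhashfp-lsh-forest", version = 1L, k = index$k,
         l = index$l, depth = index$depth,
         params_fingerprint = index$params_fingerprint,
         n = length(index$ids)),
    auto_unbox = TRUE
  )
  saveRDS(list(header = as.character(header), ids = index$ids,
               store = index$store), path)
  invisible(path)
}

#' @rdname lsh_save
#' @export
lsh_load <- function(path) {
  obj <- readRDS(path)
  header <- jsonlite::fromJSON(obj$header)
  if (!identical(header$format, "minhashfp-lsh-forest")) {
    stop("not a minhashfp LSH Forest archive", call. = FALSE)
  }
  index <- lsh_forest(k = header$k, l = header$l)
  index$params_fingerprint <- header$params_fingerprint
  fake_params <- list(fingerprint = header$params_fingerprint)
  for (i in seq_along(obj$ids)) {
    lsh_add(index, obj$ids[i], new_minhash_fp(obj$store[, i], fake_params))
  }
  lsh_freeze(index)
  index
}
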