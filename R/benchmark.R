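#' Generate reproducible synthetic 32-bit hash sets
#'
#' Stand-ins for molecular hash sets in chemistry-free evaluation: `n`
#' random integer sets over `[0, universe)`, sizes uniform in `size_range`.
#' With `n_clusters` set, the collection gets an analog-series-like
#' similarity structure: each set derives from one of `n_clusters` base sets
#' by swapping a random fraction (up to `swap_fraction`) of its elements for
#' fresh ones, so nearest neighbors are meaningful rather than an artifact
#' of tie-breaking among unrelated sets.
#'
#' @param n Number of sets (>= 1).
#' @param universe Size of the integer universe (default 2^32).
#' @param size_range Length-2 vector: inclusive bounds on set size.
#' @param seed Integer seed; same seed, same collection.
#' @param n_clusters Optional number of base sets for clustered generation.
#' @param swap_fraction Upper bound on the swapped fraction per derived set
#'   (default 0.3), used only with `n_clusters`.
#' @return List of `n` numeric vectors of distinct integers in
#'   `[0, universe)`.
#' @seealso [generate_planted_pairs()] for pairs of known exact Jaccard.
#' @export
generate_fixture_sets <- function(n, universe = 2^32, size_range = c(20, 60),
                                  seed = 1L, n_clusters = NULL,
                                  swap_fraction = 0.3) {
  stopifnot(n >= 1, length(size_range) == 2, size_range[1] >= 1,
            size_range[2] >= size_range[1], size_range[2] <= universe)
  with_local_seed(seed, {
    draw <- function(size) sort(sample.int(universe, size) - 1)
    if (is.null(n_clusters)) {
      sizes <- sample.int(size_range[2] - size_range[1] + 1L, n,
                          replace = TRUE) + size_range[1] - 1L
      lapply(sizes, draw)
    } else {
      stopifnot(n_clusters >= 1)
      base_sizes <- sample.int(size_range[2] - size_range[1] + 1L, n_clusters,
                               replace = TRUE) + size_range[1] - 1L
      bases <- lapply(base_sizes, draw)
      lapply(seq_len(n), function(i) {
        b <- bases[[sample.int(n_clusters, 1)]]
        n_swap <- floor(runif(1, 0, swap_fraction) * length(b))
        if (n_swap == 0) return(b)
        keep <- b[-sample.int(length(b), n_swap)]
        sort(unique(c(keep, sample.int(universe, n_swap) - 1)))
      })
    }
  })
}

#' Planted set pairs with known exact Jaccard similarity
#'
#' Builds each pair (A, B) of equal size `set_size` sharing
#' `c = round(2 * s * J / (1 + J))` elements, so the realized Jaccard
#' `c / (2s - c)` is as close to `jaccard` as integer counts allow. The
#' realized value is attached per pair, and should be recomputed with
#' [jaccard_exact()] by consumers; the target is a construction knob, not a
#' promise.
#'
#' @param n_pairs Number of pairs.
#' @param jaccard Target Jaccard similarity in (0, 1].
#' @param set_size Size of each set (default 40).
#' @param universe Integer universe size (default 2^32).
#' @param seed Integer seed.
#' @return List of `n_pairs` lists with fields `a`, `b` (numeric set
#'   vectors) and `jaccard` (the realized exact similarity).
#' @export
generate_planted_pairs <- function(n_pairs, jaccard, set_size = 40,
                                   universe = 2^32, seed = 1L) {
  stopifnot(n_pairs >= 1, jaccard > 0, jaccard <= 1, set_size >= 1)
  n_shared <- round(2 * set_size * jaccard / (1 + jaccard))
  stopifnot(n_shared >= 0, n_shared <= set_size)
  with_local_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      # one draw of distinct values, split into shared + private halves
      vals <- sample.int(universe, 2 * set_size - n_shared) - 1
      shared <- vals[seq_len(n_shared)]
      pa <- vals[n_shared + seq_len(set_size - n_shared)]
      pb <- vals[set_size + seq_len(set_size - n_shared)]
      a <- sort(c(shared, pa))
      b <- sort(c(shared, pb))
      list(a = a, b = b, jaccard = n_shared / (2 * set_size - n_shared))
    })
  })
}

#' Benchmark configuration for recovery-rate sweeps
#'
#' @param n_database Number of fingerprints to index.
#' @param n_queries Number of held-out query fingerprints (default 20).
#' @param k_list Neighbor counts to evaluate (default `c(5, 10)`).
#' @param kc_list Oversampling factors (default `c(1, 10, 20)`).
#' @param l_list Prefix-tree counts (default `c(8, 32)`).
#' @param seed Integer seed controlling query selection.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_database, n_queries = 20,
                             k_list = c(5, 10), kc_list = c(1, 10, 20),
                             l_list = c(8, 32), seed = 42L) {
  stopifnot(n_database >= 1, n_queries >= 1, all(k_list >= 1),
            all(kc_list >= 1), all(l_list >= 1))
  if (any(k_list > n_database)) {
    stop("k_list contains values larger than n_database", call. = FALSE)
  }
  structure(list(n_database = as.integer(n_database),
                 n_queries = as.integer(n_queries),
                 k_list = as.integer(k_list), kc_list = as.integer(kc_list),
                 l_list = as.integer(l_list), seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Recovery-rate benchmark of LSH Forest against brute-force search
#'
#' Mirrors the evaluation protocol of large-database similarity search at
#' reduced scale: hold out `n_queries` fingerprints, index the remaining
#' `n_database`, and for every `(k, kc, l)` cell query the index, compare
#' against brute-force linear scan over the same index, and average the
#' [recovery_rate()] across queries.
#'
#' The harness is pure vector-space evaluation: it touches no chemistry and
#' accepts any list of MinHash fingerprints sharing one hash family.
#'
#' @param config A [benchmark_config()].
#' @param fingerprints List of at least `n_database + n_queries` `minhash_fp`
#'   objects from one hash family.
#' @return A `data.frame` with columns `k`, `kc`, `l`, `mean_recovery`.
#' @export
run_recovery_benchmark <- function(config, fingerprints) {
  stopifnot(inherits(config, "benchmark_config"), is.list(fingerprints))
  need <- config$n_database + config$n_queries
  if (length(fingerprints) < need) {
    stop("need at least ", need, " fingerprints, got ", length(fingerprints),
         call. = FALSE)
  }
  kdim <- length(fingerprints[[1]])
  bad_l <- config$l_list[kdim %% config$l_list != 0]
  if (length(bad_l)) {
    stop("l values ", paste(bad_l, collapse = ", "), " do not divide k = ",
         kdim, call. = FALSE)
  }
  query_idx <- with_local_seed(config$seed,
                               sample.int(length(fingerprints),
                                          config$n_queries))
  db_idx <- setdiff(seq_along(fingerprints), query_idx)[
    seq_len(config$n_database)]

  grid <- expand.grid(k = config$k_list, kc = config$kc_list,
                      l = config$l_list, KEEP.OUT.ATTRS = FALSE)
  grid$mean_recovery <- NA_real_

  for (l in config$l_list) {
    index <- lsh_forest(k = kdim, l = l)
    for (i in db_idx) lsh_add(index, paste0("s", i), fingerprints[[i]])
    lsh_freeze(index)
    exact <- lapply(query_idx, function(qi) {
      linear_scan_knn(index, fingerprints[[qi]], max(config$k_list))$id
    })
    for (row in which(grid$l == l)) {
      k <- grid$k[row]; kc <- grid$kc[row]
      rates <- vapply(seq_along(query_idx), function(j) {
        ann <- lsh_query(index, fingerprints[[query_idx[j]]],
                         k_neighbors = k, kc = kc)
        recovery_rate(ann$id, exact[[j]], k)
      }, numeric(1))
      grid$mean_recovery[row] <- mean(rates)
    }
  }
  grid
}

#' Bundled fixture molecules
#'
#' Around fifty small, hand-checkable molecules (alkanes, alcohols, simple
#' aromatics and heteroaromatics, common drugs) shipped as a plain-text
#' SMILES file for chemistry-touching tests and examples.
#'
#' @return A `data.frame` with columns `smiles` and `id`.
#' @export
fixture_smiles <- function() {
  read_smiles_file(system.file("extdata", "fixture_molecules.smi",
                               package = "minhashfp"))
}

#' Bundled alternative-spelling SMILES pairs
#'
#' Pairs of distinct but equivalent SMILES spellings of the same molecule
#' (reordered atoms, alternative ring numbering, aromatic vs. kekulized
#' forms), used to exercise the graph invariance of the shingling.
#'
#' @return A `data.frame` with columns `smiles_a`, `smiles_b` and `id`.
#' @export
variant_smiles_pairs <- function() {
  path <- system.file("extdata", "variant_spellings.tsv",
                      package = "minhashfp")
  lines <- readLines(path, warn = FALSE)
  # '#' opens SMILES triple bonds, so only whole-line comments are stripped
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  utils::read.delim(text = lines, header = TRUE, comment.char = "",
                    stringsAsFactors = FALSE)
}
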