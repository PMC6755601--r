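#' Molecular shingling of one or more molecules
#'
#' A molecular shingling is the deduplicated set of canonical, kekulized
#' SMILES strings of all circular substructures around every heavy atom at
#' radii `min_radius..radius`, optionally together with one SMILES per ring
#' of the symmetrized smallest set of smallest rings (SSSR). Because every
#' substructure SMILES is canonicalized, the shingling is a graph invariant:
#' any two spellings of the same molecule yield the same set.
#'
#' Circular substructure SMILES are written rooted at their central atom;
#' ring SMILES are unrooted. Stereochemistry is stripped unless
#' `isomeric = TRUE`. A shingling of a molecule with n heavy atoms at maximum
#' radius r contains at most n*(r + 1) + rings distinct strings.
#'
#' @param smiles Character vector of SMILES strings.
#' @param radius Maximum substructure radius in bonds (>= 1). The diameter
#'   convention of circular fingerprints makes `radius = 3` the MHFP6
#'   shingling.
#' @param rings Include one SMILES per SSSR ring (default `TRUE`).
#' @param min_radius Smallest radius to enumerate; the default 1 starts at
#'   bonded environments, `0` additionally emits single-atom shingles.
#' @param isomeric Keep stereochemistry in substructure SMILES
#'   (default `FALSE`).
#' @param on_empty Either `"error"` (default) to fail on molecules whose
#'   shingling is empty (e.g. methane with `min_radius = 1`), or `"empty"`
#'   to return a zero-length character vector for them.
#' @param simplify If `TRUE` (default) and `smiles` has length 1, return the
#'   single shingling as a character vector instead of a length-1 list.
#'
#' @return A character vector (single molecule, `simplify = TRUE`) or a list
#'   of character vectors, one per input, each sorted and duplicate-free,
#'   with attributes `radius`, `min_radius` and `rings_included`.
#' @seealso [atom_environment_smiles()], [ring_smiles()],
#'   [mhfp_from_smiles()]
#' @examples
#' \dontrun{
#' shingling_from_smiles("c1ccccc1", radius = 1)  # one env + one ring SMILES
#' }
#' @export
shingling_from_smiles <- function(smiles, radius = 3, rings = TRUE,
                                  min_radius = 1, isomeric = FALSE,
                                  on_empty = c("error", "empty"),
                                  simplify = TRUE) {
  stopifnot(is.character(smiles), length(smiles) >= 1, radius >= 1,
            min_radius >= 0, min_radius <= radius)
  on_empty <- match.arg(on_empty)
  res <- run_chem_helper(list(
    op = "shingling", smiles = as.list(smiles), radius = radius,
    rings = rings, min_radius = min_radius, isomeric = isomeric
  ))
  out <- vector("list", length(smiles))
  for (i in seq_along(res)) {
    entry <- res[[i]]
    if (!is.null(entry$error)) stop(entry$error, call. = FALSE)
    sh <- as.character(unlist(entry$shingles))
    if (length(sh) == 0 && on_empty == "error") {
      stop("empty shingling for ", shQuote(smiles[i]),
           " (no bonded environment at min_radius >= 1 and no rings); ",
           "use on_empty = \"empty\" or min_radius = 0", call. = FALSE)
    }
    out[[i]] <- structure(sh, radius = radius, min_radius = min_radius,
                          rings_included = rings,
                          heavy_atoms = entry$heavy_atoms,
                          n_rings = entry$n_rings)
  }
  names(out) <- names(smiles)
  if (simplify && length(out) == 1L) out[[1L]] else out
}

#' Rooted SMILES of one atom's circular environment
#'
#' Returns the canonical kekulized SMILES of the subgraph formed by all bonds
#' within `radius` bonds of the chosen atom, written rooted at that atom.
#'
#' @param smiles A single SMILES string.
#' @param atom Atom index, 1-based over heavy atoms in SMILES order.
#' @param radius Environment radius in bonds (>= 1).
#' @param isomeric Keep stereochemistry (default `FALSE`).
#' @return A single string; `""` when the environment contains no bonds
#'   (e.g. any atom of methane).
#' @export
atom_environment_smiles <- function(smiles, atom, radius, isomeric = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1, atom >= 1, radius >= 1)
  res <- run_chem_helper(list(op = "atom_env", smiles = smiles,
                              atom = as.integer(atom) - 1L,
                              radius = as.integer(radius),
                              isomeric = isomeric))
  if (!is.null(res$error)) stop(res$error, call. = FALSE)
  res$smiles
}

#' Ring SMILES from the symmetrized SSSR
#'
#' One canonical kekulized SMILES per ring of the symmetrized smallest set of
#' smallest rings. Acyclic molecules yield a zero-length vector.
#'
#' @inheritParams atom_environment_smiles
#' @return Character vector of ring SMILES (possibly with duplicates removed
#'   only at the shingling stage; here each ring is reported).
#' @export
ring_smiles <- function(smiles, isomeric = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  res <- run_chem_helper(list(op = "rings", smiles = list(smiles),
                              isomeric = isomeric))
  entry <- res[[1L]]
  if (!is.null(entry$error)) stop(entry$error, call. = FALSE)
  as.character(unlist(entry$rings))
}

#' Canonical SMILES via the chemistry backend
#'
#' Convenience wrapper used in tests and the CLI; not part of the
#' fingerprint pipeline itself.
#'
#' @param smiles Character vector of SMILES.
#' @param isomeric Keep stereochemistry (default `FALSE`).
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles, isomeric = FALSE) {
  res <- run_chem_helper(list(op = "canonical", smiles = as.list(smiles),
                              isomeric = isomeric))
  vapply(res, function(e) {
    if (!is.null(e$error)) stop(e$error, call. = FALSE)
    e$smiles
  }, character(1))
}

#' Unfolded circular-fingerprint hash identifiers
#'
#' Extracts the unfolded ECFP (Morgan) hash identifiers of each molecule from
#' the chemistry toolkit, reduced modulo 2^32 so they live in the MinHash
#' universe. These are the input of the MHECFP control fingerprint; the
#' circular fingerprint itself is entirely the toolkit's.
#'
#' @param smiles Character vector of SMILES.
#' @param radius Morgan radius (default 2, i.e. ECFP4).
#' @return List of numeric vectors of distinct hash values in
#'   `[0, 2^32 - 1]`.
#' @export
ecfp_hashes_from_smiles <- function(smiles, radius = 2) {
  res <- run_chem_helper(list(op = "ecfp_hashes", smiles = as.list(smiles),
                              radius = as.integer(radius)))
  lapply(res, function(e) {
    if (!is.null(e$error)) stop(e$error, call. = FALSE)
    as.numeric(unlist(e$hashes))
  })
}

#' Read a SMILES file
#'
#' One record per line: a SMILES string, optionally followed by a tab and an
#' identifier. Blank lines and lines starting with `#` are skipped;
#' identifiers default to the (1-based) record number.
#'
#' @param path File path.
#' @return A `data.frame` with columns `smiles` and `id`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[[`, character(1), 1L)
  id <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2 && nzchar(parts[[i]][2])) parts[[i]][2]
    else as.character(i)
  }, character(1))
  data.frame(smiles = smiles, id = id, stringsAsFactors = FALSE)
}
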