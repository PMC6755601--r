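---
title: "MinHash molecular fingerprints: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MinHash molecular fingerprints: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`minhashfp` treats a molecule as a *set of substructure strings* and molecular
similarity as the Jaccard coefficient of such sets. Three stages turn a SMILES
into a fingerprint:

**Shingling.** Around every heavy atom, and for every radius from
`min_radius` to `radius`, the subgraph of all bonds within that many bonds of
the atom is written out as a canonical, kekulized SMILES rooted at the central
atom. Because small radii (and even large ones, for macrocycles) lose ring
membership information, one unrooted canonical SMILES per ring of the
symmetrized smallest set of smallest rings is added. Deduplication yields the
molecular shingling `S(A)`, at most `n * (r + 1) + rings` strings for `n`
heavy atoms. Canonicalization makes `S(A)` a graph invariant: any SMILES
spelling of the same molecule produces the same set (exercised over 24
hand-written spelling pairs in the test suite).

**Hashing.** MinHash operates on integers, so each shingle is mapped to
`[0, 2^32 - 1]` by taking the first four bytes (big-endian) of its SHA-1
digest. Any fixed 32-bit slice of a cryptographic digest would do; the first
four bytes are the documented choice. A 64-bit hash would essentially
eliminate collisions but pushes the MinHash arithmetic beyond 64-bit
registers; the 32-bit choice instead accepts a collision rate that the
birthday-problem estimate

\[ c(m, N) = m - N\left(1 - \left(\tfrac{N-1}{N}\right)^m\right) \]

shows to be negligible: about 4.5 expected collisions among the ~2 * 10^5
distinct shingles of a 1.7M-compound corpus at radius 2, and about 476 among
the ~2 * 10^6 at radius 3.

**MinHash.** Given coefficient vectors `a`, `b` of length `k` with entries
drawn without replacement from `[0, 2^32 - 1]` (`a` additionally nonzero: a
zero multiplier would make its hash function constant), component `i` of the
fingerprint is

\[ \min_{v \in S} \left(((a_i v + b_i) \bmod p) \bmod (2^{32} - 1)\right),
   \qquad p = 2^{61} - 1 . \]

The probability that two sets agree in a component equals their Jaccard
similarity, so the fraction of equal components is an unbiased estimator with
standard error `sqrt(J(1 - J) / k)`. The classical `1/sqrt(k)` error rate is
what the property tests assert.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `radius` | 3 | Maximum substructure radius in bonds. Fingerprint names use the diameter, so radius 3 is MHFP6, the variant with the best benchmark record; radius 2 (MHFP4) suits low-dimensional settings. |
| `k` | 2048 | Number of hash functions = fingerprint length. 2048 balances estimator error (~0.011 at J = 0.5) against memory; 128–4096 are the conventional sizes. |
| `min_radius` | 1 | Smallest radius enumerated. The default starts at bonded environments; `0` adds single-atom shingles, covering the alternative reading of the `O(n(r+1))` shingle count, which is retained as an upper bound only. |
| `D` | 2048 | SECFP length; folding is the same modulo operation classic binary circular fingerprints use. |
| `l` | 32 | Number of LSH Forest prefix trees; must divide `k`. More trees raise recovery at the cost of memory. |
| `kc` | 10 | Oversampling: `kc * k_neighbors` candidates are gathered and re-ranked before the top `k_neighbors` are returned. |
| `seed` | 42 | Hash-family seed; fingerprints are only comparable within one family, which is why every fingerprint carries a digest of its family and comparisons across digests raise errors. |

## Numerical choices

* The collision estimate is evaluated as `m + N * expm1(m * log1p(-1/N))`;
  naive powering of `(N-1)/N` at `N = 2^32 - 1` cancels catastrophically.
* The MinHash kernel computes `a_i * v + b_i` in 128-bit integer arithmetic
  (Rcpp): the product of two 32-bit values needs up to 64 bits, and R doubles
  are exact only through 2^53. Fingerprint components travel as doubles,
  which hold 32-bit values exactly; R's native integer type cannot.
* Hash-family generation samples without replacement under an explicitly
  pinned RNG kind (Mersenne-Twister / Rejection), so `(k, seed)` regenerates
  bit-identical coefficients, and the caller's RNG state is restored
  afterwards.
* LSH Forest "prefix trees" are sorted arrays of fixed-width decimal key
  strings with binary search — contract-equivalent to tries and simpler to
  make deterministic. Keys are digit-only ASCII, so string comparison is
  locale-safe.
* Queries relax the matching prefix depth one component at a time across all
  trees and deduplicate candidates across trees before counting them against
  `kc * k_neighbors`. If even depth 1 yields too few, depth 0 (the whole
  index) is used, which guarantees that an oversweeping query
  (`kc * k >= n`) reproduces brute-force ranking exactly.
* Re-ranking uses the estimated Jaccard distance between stored fingerprints,
  not a recomputation from shinglings: the index stores fingerprints, and the
  linear-scan ground truth is fingerprint-based too, so approximate and exact
  rankings are comparable. Ties are broken by insertion order in both paths,
  making recovery rates reproducible.

## Design decisions taken where the design was open

* Radii enumerate from 1 by default (no single-atom shingles); `min_radius`
  exposes the other convention rather than guessing.
* Stereochemistry is stripped before substructure extraction (plain kekulized
  SMILES); an `isomeric` flag restores it.
* Ring SMILES are written unrooted — rooting is only defined for
  atom-centered environments.
* Dot-separated multi-fragment SMILES are shingled as-is; every fragment's
  atoms contribute.
* `a` and `b` are each internally duplicate-free, but a value may occur in
  both vectors.
* MHECFP takes its hash identifiers as given (from
  `ecfp_hashes_from_smiles()` or elsewhere), reduced modulo 2^32 when the
  toolkit emits wider values; generating circular-fingerprint identifiers is
  the toolkit's job, not this package's.
* Kekulization failures, unparseable SMILES and empty shinglings are hard
  errors by default (`on_empty = "empty"` opts out of the last one): silently
  empty fingerprints would poison similarity searches.

## What the synthetic generator emulates

`generate_fixture_sets()` produces random 32-bit hash sets standing in for
hashed shinglings; `generate_planted_pairs()` constructs pairs with a known
exact Jaccard by sharing `c = round(2sJ/(1+J))` of `s` elements. Sizes default
to 20–60 elements, the shingling sizes of drug-like molecules at radius 3.
With `n_clusters`, sets derive from shared base sets with up to 30% of
elements swapped, giving the collection the analog-series structure of real
compound databases; with fully independent random sets, all pairwise
similarities are near zero and "nearest neighbors" are an artifact of
tie-breaking, which makes recovery curves meaningless rather than merely
noisy.

Passing vector-space tests on these sets shows the estimator, index and
evaluation harness are correct; it says nothing about chemistry. The
chemistry-touching tests use ~50 bundled hand-checkable molecules instead.
What the synthetic route cannot show: shingling quality on exotic chemistry
(organometallics, macrocycles beyond the SSSR basis), nor virtual-screening
performance, which is out of scope here.

## Simulation scales

The test suite calibrates the estimator on 200 planted pairs across
J ∈ {0.1, 0.25, 0.5, 0.75, 0.9} at k = 2048; checks exact brute-force
equivalence of oversweeping queries on a 1,000-vector index; and verifies
recovery-rate monotonicity in `kc` (1 → 10 → 20) and `l` (8 → 32) on a
10,000-vector index with 20 queries at k = 512 — sizes chosen so the whole
suite runs in about a minute on one core while leaving the stochastic
assertions comfortable margins.

## Known limitations

* The index is in-memory and single-threaded; millions of fingerprints fit,
  but there is no on-disk or sharded mode.
* Fingerprints from different hash families are incomparable by design;
  persist the family (`write_minhash_params()`) alongside any stored
  fingerprints.
* The shingling backend requires a Python with RDKit; the canonical SMILES
  dialect is RDKit's, so hash values are not portable across chemistry
  toolkits (the dialect is recorded in the fingerprint file sidecar).
* Only Jaccard similarity is supported — it is the metric MinHash estimates;
  cosine or Euclidean indexing is a different method family.
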