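# Shared fixtures, computed once per test run. Chemistry calls are batched
# so the RDKit backend is spawned only a handful of times.

fix_mols <- fixture_smiles()
variant_pairs <- variant_smiles_pairs()

# Shinglings of every fixture molecule at radii 1 and 3 (MHFP2 / MHFP6).
shingling_r3 <- shingling_from_smiles(fix_mols$smiles, radius = 3,
                                      simplify = FALSE)
names(shingling_r3) <- fix_mols$id
shingling_r1 <- shingling_from_smiles(fix_mols$smiles, radius = 1,
                                      simplify = FALSE)
names(shingling_r1) <- fix_mols$id

# Shinglings of both spellings of each variant pair.
variant_sh_a <- shingling_from_smiles(variant_pairs$smiles_a, radius = 3,
                                      simplify = FALSE)
variant_sh_b <- shingling_from_smiles(variant_pairs$smiles_b, radius = 3,
                                      simplify = FALSE)

# Small shared hash family for fingerprint-level tests.
params128 <- generate_permutations(128, seed = 42)

make_fp <- function(components, fingerprint = "testfam") {
  minhashfp:::new_minhash_fp(components, list(fingerprint = fingerprint))
}

build_index <- function(fps, l, ids = paste0("s", seq_along(fps))) {
  index <- lsh_forest(k = length(fps[[1]]), l = l)
  for (i in seq_along(fps)) lsh_add(index, ids[i], fps[[i]])
  lsh_freeze(index)
  index
}
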