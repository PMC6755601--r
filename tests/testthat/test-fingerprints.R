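test_that("exact Jaccard matches set arithmetic", {
  expect_identical(jaccard_exact(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_identical(jaccard_exact(letters[1:5], letters[1:5]), 1)
  expect_identical(jaccard_exact(1:3, 4:6), 0)
  expect_identical(jaccard_exact(c(1, 1, 2), c(2, 2)), 0.5)  # set semantics
  expect_error(jaccard_exact(numeric(0), numeric(0)), "undefined")
  expect_identical(jaccard_distance(c(1, 2, 3), c(2, 3, 4)), 0.5)
})

test_that("estimated Jaccard counts matching components", {
  u <- make_fp(c(1, 2, 3, 4))
  expect_identical(jaccard_estimated(u, u), 1)
  v <- make_fp(c(1, 2, 9, 9))
  expect_identical(jaccard_estimated(u, v), 0.5)
  expect_identical(jaccard_distance(u, v), 0.5)
})

test_that("estimates across hash families or lengths are rejected", {
  u <- make_fp(c(1, 2, 3, 4), "famA")
  v <- make_fp(c(1, 2, 3, 4), "famB")
  expect_error(jaccard_estimated(u, v), "different hash families")
  w <- make_fp(c(1, 2, 3), "famA")
  expect_error(jaccard_estimated(u, w), "different k")
})

test_that("estimator tracks the brute-force Jaccard oracle", {
  params <- generate_permutations(2048, seed = 42)
  for (J in c(0.25, 0.75)) {
    pairs <- generate_planted_pairs(10, jaccard = J, set_size = 40,
                                    seed = round(1000 * J))
    for (pair in pairs) {
      truth <- jaccard_exact(pair$a, pair$b)
      est <- jaccard_estimated(minhash(pair$a, params),
                               minhash(pair$b, params))
      expect_lt(abs(est - truth), 4 * sqrt(truth * (1 - truth) / 2048))
    }
  }
})

test_that("MHFP is the composition minhash(hash(shingling))", {
  sh <- shingling_r3[["aspirin"]]
  by_stages <- minhash(hash_string_32(as.character(sh)), params128)
  direct <- mhfp_from_smiles(fix_mols$smiles[fix_mols$id == "aspirin"],
                             params = params128)
  expect_identical(as.numeric(direct), as.numeric(by_stages))
  expect_identical(attr(direct, "params_fingerprint"), params128$fingerprint)
})

test_that("MHFP is a molecular graph invariant", {
  fa <- mhfp_from_smiles("CCO", params = params128)
  fb <- mhfp_from_smiles("OCC", params = params128)
  expect_identical(as.numeric(fa), as.numeric(fb))
})

test_that("MHFP honors the standard dimensionalities", {
  for (k in c(128, 1024, 2048, 4096)) {
    fp <- mhfp_from_smiles("CCO", k = k)
    expect_length(fp, k)
    expect_true(all(as.numeric(fp) >= 0 & as.numeric(fp) <= 2^32 - 2))
  }
})

test_that("MHECFP is a definitional alias of minhash", {
  hashes <- generate_fixture_sets(1, seed = 17)[[1]]
  expect_identical(as.numeric(mhecfp_from_hashes(hashes, params128)),
                   as.numeric(minhash(hashes, params128)))
  expect_error(mhecfp_from_hashes(numeric(0), params128), "empty set")
})

test_that("MHECFP similarity estimates the Jaccard of the raw hash sets", {
  params <- generate_permutations(2048, seed = 42)
  pair <- generate_planted_pairs(1, jaccard = 0.5, set_size = 50,
                                 seed = 4)[[1]]
  truth <- jaccard_exact(pair$a, pair$b)
  est <- jaccard_estimated(mhecfp_from_hashes(pair$a, params),
                           mhecfp_from_hashes(pair$b, params))
  expect_lt(abs(est - truth), 4 * sqrt(truth * (1 - truth) / 2048))
})

test_that("toolkit ECFP hashes feed MHECFP end to end", {
  hashes <- ecfp_hashes_from_smiles(c("CCO", "CC(=O)Oc1ccccc1C(=O)O"))
  expect_length(hashes, 2L)
  for (h in hashes) {
    expect_gt(length(h), 0)
    expect_true(all(h >= 0 & h < 2^32))
    expect_identical(anyDuplicated(h), 0L)
  }
  fp <- mhecfp_from_hashes(hashes[[1]], params128)
  expect_s3_class(fp, "minhash_fp")
})

test_that("SECFP folds shingle hashes modulo D", {
  expect_identical(fold_hashes(c(5, 2053), 2048), 5)
  sh <- shingling_r3[["caffeine"]]
  fp <- secfp_from_smiles(fix_mols$smiles[fix_mols$id == "caffeine"])
  expect_identical(fp$length, 2048L)
  expect_identical(fp$set_bits,
                   as.integer(fold_hashes(hash_string_32(as.character(sh)),
                                          2048)))
  expect_lte(length(fp$set_bits), length(sh))
  # identical molecules give identical SECFP across spellings
  a1 <- secfp_from_smiles("CC(=O)Oc1ccccc1C(=O)O")
  a2 <- secfp_from_smiles("OC(=O)c1ccccc1OC(C)=O")
  expect_identical(jaccard_secfp(a1, a2), 1)
})

test_that("fingerprint files round trip", {
  ids <- fix_mols$id[1:4]
  smiles <- fix_mols$smiles[1:4]
  fps <- mhfp_from_smiles(smiles, params = params128, simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".fp")
  write_fingerprints(fps, path, ids = ids, params = params128)
  back <- read_fingerprints(path)
  expect_identical(names(back), ids)
  for (i in 1:4) {
    expect_identical(as.numeric(back[[i]]), as.numeric(fps[[i]]))
    # read-back fingerprints are comparable with freshly computed ones
    expect_identical(jaccard_estimated(back[[i]], fps[[i]]), 1)
  }
  sfps <- secfp_from_smiles(smiles, D = 256, simplify = FALSE)
  spath <- withr::local_tempfile(fileext = ".fp")
  write_fingerprints(sfps, spath, ids = ids)
  sback <- read_fingerprints(spath)
  for (i in 1:4) expect_identical(sback[[i]]$set_bits, sfps[[i]]$set_bits)
})
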