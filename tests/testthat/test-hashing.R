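test_that("string hashing equals an independent SHA-1 oracle", {
  strings <- c("CC", "CCO", "C1=CC=CC=C1", "C(=C)C", "N#CC", "été")
  oracle <- vapply(strings, function(s) {
    hex <- digest::digest(enc2utf8(s), algo = "sha1", serialize = FALSE)
    strtoi(substr(hex, 1, 4), 16L) * 65536 + strtoi(substr(hex, 5, 8), 16L)
  }, numeric(1), USE.NAMES = FALSE)
  expect_identical(hash_string_32(strings), oracle)
})

test_that("string hashes are deterministic and 32-bit", {
  s <- c("CC", "a", paste(rep("x", 500), collapse = ""))
  h1 <- hash_string_32(s)
  expect_identical(h1, hash_string_32(s))
  expect_true(all(h1 >= 0 & h1 <= 2^32 - 1 & h1 == trunc(h1)))
  expect_error(hash_string_32(""), "nzchar")
})

test_that("collision estimate has birthday-problem behavior", {
  N <- 2^32 - 1
  expect_identical(estimate_collisions(0, N), 0)
  expect_identical(estimate_collisions(1, N), 0)
  m <- c(10, 1e3, 1e5, 1e7, 1e9)
  est <- estimate_collisions(m, N)
  expect_true(all(est >= 0 & est < m))
  expect_true(all(diff(est) > 0))            # monotone in m
  # m >> N: almost every insertion collides, c -> m - N
  expect_equal(estimate_collisions(1e12, N), 1e12 - N, tolerance = 1e-6)
})

test_that("collision estimate matches simulation at small N", {
  N <- 500; m <- 40
  sims <- with(list(), {
    set.seed(11)
    replicate(4000, m - length(unique(sample.int(N, m, replace = TRUE))))
  })
  expect_equal(estimate_collisions(m, N), mean(sims), tolerance = 0.05)
})

test_that("observed 32-bit collisions over random strings track the estimate", {
  # scaled-down analogue of hashing a large shingle corpus: fold the hashes
  # into a small universe so collisions are observable
  set.seed(7)
  m <- 20000; N <- 2^20
  strings <- paste0("shingle_", seq_len(m), "_",
                    sample.int(1e9, m, replace = TRUE))
  folded <- hash_string_32(strings) %% N
  observed <- m - length(unique(folded))
  expected <- estimate_collisions(m, N)
  expect_gt(observed, expected * 0.5)
  expect_lt(observed, expected * 1.5)
})

test_that("hash-family generation is reproducible and well-formed", {
  p1 <- generate_permutations(128, seed = 42)
  p2 <- generate_permutations(128, seed = 42)
  p3 <- generate_permutations(128, seed = 43)
  expect_identical(p1[c("a", "b", "p", "k", "seed")],
                   p2[c("a", "b", "p", "k", "seed")])
  expect_identical(p1$fingerprint, p2$fingerprint)
  expect_false(identical(p1$a, p3$a))
  expect_length(p1$a, 128L)
  expect_identical(anyDuplicated(p1$a), 0L)
  expect_identical(anyDuplicated(p1$b), 0L)
  expect_true(all(p1$a >= 1 & p1$a <= 2^32 - 1))   # nonzero multipliers
  expect_true(all(p1$b >= 0 & p1$b <= 2^32 - 1))
  expect_identical(p1$p, 2^61 - 1)
})

test_that("MinHash arithmetic is exact against a big-integer oracle", {
  params <- generate_permutations(16, seed = 7)
  values <- c(0, 1, 2^32 - 1, 123456789, 987654321, 2^31, 3141592653)
  fp <- minhash(values, params)
  script <- paste(
    "import json,sys",
    "d=json.load(sys.stdin)",
    "p=2**61-1",
    "out=[min(((int(a)*int(v)+int(b))%p)%(2**32-1) for v in d['v'])",
    "     for a,b in zip(d['a'],d['b'])]",
    "print(json.dumps(out))", sep = "\n")
  infile <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = params$a, b = params$b, v = values), infile,
                       digits = NA)
  oracle <- as.numeric(jsonlite::fromJSON(
    system2(find_python(), c("-c", shQuote(script)),
            stdin = infile, stdout = TRUE)))
  expect_identical(as.numeric(fp), oracle)
})

test_that("singleton MinHash equals the hash functions themselves", {
  # small multipliers keep a*v + b below 2^53 and below p, so plain double
  # arithmetic is an exact independent route
  params <- generate_permutations(8, seed = 1)
  params$a <- as.numeric(c(3, 7, 11, 19, 101, 1009, 65537, 2^20))
  params$b <- as.numeric(c(0, 1, 5, 99, 2^16, 123, 42, 7))
  params$fingerprint <- minhashfp:::params_digest(params)
  v <- 1048573
  expected <- ((params$a * v + params$b) %% (2^61 - 1)) %% (2^32 - 1)
  expect_identical(as.numeric(minhash(v, params)), expected)
})

test_that("MinHash of a union is the componentwise minimum", {
  params <- generate_permutations(64, seed = 5)
  set.seed(21)
  for (i in 1:10) {
    A <- sample.int(2^32, 30) - 1
    B <- sample.int(2^32, 45) - 1
    mu <- pmin(as.numeric(minhash(A, params)), as.numeric(minhash(B, params)))
    expect_identical(as.numeric(minhash(union(A, B), params)), mu)
  }
})

test_that("MinHash rejects empty and out-of-range inputs", {
  params <- generate_permutations(8, seed = 1)
  expect_error(minhash(numeric(0), params), "empty set")
  expect_error(minhash(-1, params), "\\[0, 2\\^32 - 1\\]")
  expect_error(minhash(2^32, params), "\\[0, 2\\^32 - 1\\]")
  expect_error(minhash(1.5, params), "integers")
})

test_that("MinHash component matches are an unbiased Jaccard estimator", {
  # random set pairs, many (pair, hash-family) draws: mean match fraction
  # within 3 binomial standard errors of the exact Jaccard
  set.seed(31)
  k <- 256; trials <- 8
  for (i in 1:4) {
    pair <- generate_planted_pairs(1, jaccard = runif(1, 0.2, 0.8),
                                   set_size = 30, seed = 100 + i)[[1]]
    J <- jaccard_exact(pair$a, pair$b)
    ests <- vapply(seq_len(trials), function(t) {
      pr <- generate_permutations(k, seed = 1000 + t)
      jaccard_estimated(minhash(pair$a, pr), minhash(pair$b, pr))
    }, numeric(1))
    se <- sqrt(J * (1 - J) / (k * trials))
    expect_lt(abs(mean(ests) - J), 3 * se)
  }
})

test_that("hash-family JSON round trip is bit-identical", {
  params <- generate_permutations(64, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_minhash_params(params, path)
  back <- read_minhash_params(path)
  expect_identical(back$a, params$a)
  expect_identical(back$b, params$b)
  expect_identical(back$fingerprint, params$fingerprint)
  fp1 <- minhash(c(1, 2, 3), params)
  fp2 <- minhash(c(1, 2, 3), back)
  expect_identical(jaccard_estimated(fp1, fp2), 1)
})

test_that("minhash_batch agrees with per-set minhash", {
  params <- generate_permutations(32, seed = 3)
  sets <- generate_fixture_sets(5, seed = 8)
  batch <- minhash_batch(sets, params)
  for (i in seq_along(sets)) {
    expect_identical(as.numeric(batch[[i]]),
                     as.numeric(minhash(sets[[i]], params)))
  }
})
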