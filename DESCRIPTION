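Package: minhashfp
Title: MinHash Molecular Fingerprints and LSH Forest Similarity Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes small molecules as MinHash fingerprints (MHFP) built
    from molecular shinglings: the set of canonical, kekulized SMILES of the
    circular substructures around every heavy atom, plus one SMILES per ring
    of the symmetrized smallest set of smallest rings. Shingle strings are
    hashed to 32-bit integers with SHA-1 and min-hashed with a family of
    universal hash functions over the Mersenne prime 2^61 - 1, so that the
    fraction of matching fingerprint components estimates the Jaccard
    (Tanimoto) similarity of the underlying substructure sets. Also provides
    the folded binary variant SECFP, MinHash over externally supplied
    unfolded circular-fingerprint hashes (MHECFP), an LSH Forest index with
    oversampled approximate k-nearest-neighbor queries, recovery-rate
    evaluation against brute-force linear scan, and a command-line interface.
    SMILES parsing and substructure extraction are delegated to RDKit through
    the system Python interpreter.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    openssl,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    digest,
    optparse,
    withr
SystemRequirements: Python (>= 3.8) with the rdkit package available on the
    PATH as 'python' (or pointed to by option 'minhashfp.python' /
    environment variable MINHASHFP_PYTHON).
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
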