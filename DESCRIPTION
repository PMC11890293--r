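Package: ppgc
Title: Privacy-Preserving Genomic Computation via Multi-Key Homomorphic
    Encryption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reference implementation of a privacy-preserving genomic
    computation framework built on a multi-key homomorphic encryption
    scheme over the ring learning-with-errors (RLWE) problem.  Provides
    exact polynomial arithmetic in Z_q[x]/(x^n+1) through a residue
    number system with negacyclic number-theoretic transforms, SIMD slot
    batching, per-party key generation with gadget-based relinearization
    keys, multi-key homomorphic addition and multiplication with
    distributed (N-of-N) decryption, four encrypted genomic test
    circuits (SNP disease-risk scoring, STR paternity testing, similar
    patient search, record linkage), a four-role protocol orchestration
    (key authority, certified institution, storage/processing unit, data
    owners) with dynamic join and withdrawal, and synthetic-data
    generators for SNP profiles, Mendelian STR trios and record tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
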