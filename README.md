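# ppgc — privacy-preserving genomic computation via multi-key homomorphic encryption

`ppgc` is a reference implementation of a framework in which several
mutually distrusting parties (patients, clinics, registries) store
**encrypted** genomic profiles at an untrusted storage-and-processing unit
(SPU), the SPU evaluates genomic tests directly on the ciphertexts, and
the result can only be opened when **every** involved party contributes a
partial decryption share (N-of-N access control). No single party — not
even the SPU — can decrypt anyone else's data alone.

The cryptographic core is a multi-key variant of an exact (BFV-style)
RLWE homomorphic encryption scheme over `R_q = Z_q[x]/(x^n + 1)`:

* each party generates its own key triple against a common reference
  string; ciphertexts under different keys can be combined on the fly,
* homomorphic addition and depth-bounded multiplication (with gadget-based
  relinearization) operate slot-wise on batched plaintext vectors mod a
  prime `t`,
* decryption is distributed: each party computes `c_j · s_j` plus
  statistical smudging noise, and only the sum of all shares reveals the
  plaintext.

All ring arithmetic is **exact**: elements live in a residue number
system over NTT-friendly word-size primes, and every multiprecision step
(base extension, rescaling, gadget digits, noise measurement) uses exact
integer reconstruction — no floating-point approximation anywhere in the
arithmetic path.

## The four genomic tests

| test | computation | encrypted depth |
|---|---|---|
| `pm` — personalized medicine | weighted SNP disease-risk score | 0 |
| `paternity` | STR allele comparison over 13 core loci | 2 |
| `sps` — similar patient search | capped genotype distance `min(\|a−b\|, c)` | 2 |
| `linkage` — record linkage | normalized Hamming distance over one-hot records | 1 |

Each test ships as a **plaintext oracle** (the exact published formula)
and an **encrypted circuit** whose decrypted output reproduces the oracle
— exactly for paternity/SPS/linkage, within the fixed-point quantization
bound `2/F` for the risk score. Comparisons that have no homomorphic
analogue (absolute value, min) are realized by exact low-degree
polynomial interpolation over the bounded genotype domain
(`abs_interp_coeffs()`); divisions are public normalizations applied
after decryption. The encrypted linkage circuit computes normalized
Hamming distance over one-hot padded records; the true Levenshtein
distance is provided as the plaintext reference semantic
(`linkage_plain_levenshtein()`).

## Worked example: encrypted paternity test

```r
library(ppgc)

s <- protocol_session("toy")                      # n=1024, log2(q)≈184, t≈2^33
run_setup_and_keygen(s, c("guardian", "alleged_father"), seed = 11)

spec <- paternity_spec()                          # 13 loci, alleles 5..50
pop    <- gen_str_population(2, spec, seed = 12)
father <- str_profile(pop, "S0001")
child  <- gen_child(str_profile(pop, "S0002"), father, spec, seed = 13)

sequence_and_encrypt(s, "guardian",       child,  "str", spec = spec)
sequence_and_encrypt(s, "alleged_father", father, "str", spec = spec)

q <- test_query("paternity", "guardian", c("guardian", "alleged_father"),
                spec, test_id = "demo")
run_encrypted_test(s, q)       # SPU: 4 subtractions, 3 multiplications, depth 2
res <- run_decryption(s, "demo")
res
#> <ppgc_scored_result:paternity> numerator=0 normalizer=13 scale=1 score=0
paternity_plain(child, father, spec)$score        # oracle agrees
#> [1] 0
scan_transcript(s)             # no plaintext or key material ever on the bus
#> [1] message   from      to        type      component matched
#> <0 rows> (or 0-length row.names)
```

A Mendelian child shares an allele with the true father at every locus,
so every per-locus product `(x1−y1)(x1−y2)(x2−y1)(x2−y2)` vanishes; an
unrelated man yields a large nonzero score. By default the SPU applies
zero-sum masking before release, so the querier learns only the
aggregate score, not per-locus values.

## Command line

```sh
ppgc demo --scenario paternity --seed 1 --out result.json   # end-to-end demo
ppgc gen --kind trio --out trio.csv                         # synthetic fixtures
ppgc setup --profile toy --dir state && ppgc keygen --party alice --dir state
```

(The launcher lives at `system.file("cli", "ppgc", package = "ppgc")`.)
Exit codes: 0 ok, 2 validation error, 3 crypto-correctness failure,
4 access-control refusal.

## Parameter profiles

* `mini` — n = 32: unit-test speed; same moduli as `toy`.
* `toy` (default) — n = 2^10, `q` ≈ 184 bits (4 NTT-friendly 46-bit
  primes), prime `t` ≈ 2^33: supports 2 multiplicative levels with a wide
  noise margin (measured ≈ 106 of 150 budget bits after depth 2). **Not
  cryptographically secure**; exists to exercise correctness.
* `paper` — n = 2^14, t = 65537, `q` = 432 bits: sized under the
  homomorphic-encryption-standard 128-bit classical bound.

## What this is not

A toy-to-research artifact: no network transport, no PKI or
malicious-adversary hardening, no GWAS-scale statistics, and the `toy`
profile is deliberately insecure. See the methods vignette
(`vignettes/`) for the scheme, parameter sizing, and design-decision
rationale.
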