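---
title: "Methods: the multi-key scheme, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multi-key scheme, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgc)
```

## 1. Model

Four roles. A **key authority** runs setup once and publishes the public
parameters (ring dimension $n$, ciphertext modulus $q$, plaintext prime
$t$, error width $\sigma$, and a common reference string published as a
seed). A **certified institution** "sequences" (here: parses and
validates) raw genomic profiles and encrypts them under the owning
party's public key. An untrusted **storage and processing unit** (SPU)
stores only ciphertexts and public key material and evaluates test
circuits homomorphically. **Data owners / queriers** each hold their own
key triple and participate in distributed decryption. The adversary is
semi-honest; confidentiality is enforced structurally: the package
records every inter-role message and `scan_transcript()` asserts that no
message carries a secret key or a plaintext payload.

## 2. The scheme

Plaintexts are length-$n$ vectors over $\mathbb{Z}_t$, batched into
polynomials of $R_t = \mathbb{Z}_t[x]/(x^n+1)$ by the inverse negacyclic
number-theoretic transform (so slot-wise $+,\times$ correspond to ring
operations). A ciphertext under parties $\{1,\dots,N\}$ is a tuple
$(c_0, c_1, \dots, c_N)$ decrypting via the concatenated secret
$(1, s_1, \dots, s_N)$:
$$c_0 + \sum_j c_j s_j = \Delta m + e \pmod q, \qquad \Delta = \lfloor q/t \rfloor.$$

* **Keys.** Each party samples a ternary secret $s$ and publishes a
  gadget-vector public key $b = -s\,a + e$ over the common reference
  vector $a$, plus a relinearization triple $(d_0, d_1, d_2)$ that is a
  gadget encryption of $s$ entangled with an auxiliary ternary $r$
  (the construction the underlying multi-key literature calls
  modulus/gadget-based relinearization).
* **Encryption** is standard RLWE: $c_0 = u b_1 + e_0 + \Delta m$,
  $c_1 = u a_1 + e_1$.
* **Extension.** A ciphertext extends to a superset of parties by
  inserting zero components; party order is canonical (sorted), making
  evaluation order-invariant.
* **Multiplication** forms the $(N+1)^2$ tensor of the two ciphertexts
  in an extended RNS basis, rescales each entry by $t/q$ with exact
  rounding, and relinearizes every $s_i s_j$ component back onto
  $(1, s_1, \dots, s_N)$ using the parties' gadget keys. Gadget
  decomposition (base $2^8$) keeps the key-noise contribution additive.
* **Distributed decryption.** Party $j$ releases
  $c_j s_j + e_{\text{smudge}}$ with smudging noise drawn uniformly from
  $[-2^{40}, 2^{40}]$ — large enough to statistically hide the
  evaluation noise, small enough to be absorbed by the rounding margin.
  Only the full set of $N$ shares opens the result (`mkh_fin_dec()`
  enforces N-of-N; the acceptance suite verifies that any $N-1$ shares
  force a decode mismatch).

### Exact arithmetic

No big-integer library is used. A ring element is stored in a residue
number system: one row of word-size residues per prime factor of $q$,
each prime NTT-friendly ($\equiv 1 \bmod 2n$). Every step that
conceptually needs $\mathbb{Z}$ — base extension into the tensor basis,
the $t/q$ rescaling, gadget digit extraction, decryption rounding, and
noise measurement — reconstructs exact mixed-radix (Garner) digits and
operates on 64-bit limbs. The test suite pins `ring_mul` against a
schoolbook negacyclic convolution and the batching against slot-wise
modular arithmetic.

## 3. Parameter profiles and noise budget

```{r}
ring_params("toy")
ring_params("paper")
```

The decryption threshold is $\log_2 q - \log_2 t - 1$ noise bits. With
the default prime $t \ge 2^{33}$ (chosen so the paternity payload bound
$t > 2K\,\Delta_{\max}^4$ holds for 13 loci and alleles in $[5,50]$),
measured noise at the `toy` profile is roughly 6 bits fresh, 70 bits
after one multiplication, 106 bits after depth 2 — against a threshold
of 150 bits. This is why `toy` carries a 184-bit $q$: a ~100-bit
modulus cannot hold two multiplicative levels once $t$ is 33 bits. The
`paper` profile matches the published evaluation setting ($n = 2^{14}$,
$t = 65537$, depth 2) with $\log_2 q = 432$, below the 438-bit
homomorphic-encryption-standard bound for 128-bit classical security
with ternary keys at that dimension. `mini` and `toy` are correctness
profiles only — at those dimensions a 184-bit modulus offers no
meaningful RLWE security.

## 4. The four tests under encryption

All divisions in the published score formulas ($1/\sum c_j$, $1/K$,
$1/L$, $1/\max(m,n)$) are public normalizations applied after
decryption; integer HE cannot divide.

**Personalized medicine (depth 0).** The printed risk factor
$pr^{s}(1-pr)^{1-s}$ is undefined at genotype 2, so the test consumes a
minor-allele presence bit $s \in \{0,1\}$ and evaluates the identical
degree-1 linearization $(1-pr) + s(2pr-1)$, quantized at fixed-point
scale $F = 2^{10}$: one plaintext multiplication and one addition per
slot. Decrypted, summed, and divided by $F^2 \sum c_j$, the score is
within $2/F$ of the exact formula.

**Paternity (depth 2).** Per locus,
$(x_1-y_1)(x_1-y_2)(x_2-y_1)(x_2-y_2)$: four homomorphic subtractions
and three multiplications arranged as a balanced tree. Exact; a
Mendelian child of the tested man scores 0 at every locus.

**Similar patient search (depth 2).** $\min(|a_i-b_i|, c)$ has no
homomorphic comparison, but on the genotype difference domain
$d \in [-2,2]$ it is the unique even quartic through the domain points
(`abs_interp_coeffs()`; for $c \ge 2$, $6^{-1}(7d^2-d^4)$). The circuit
squares twice and combines with *integer-scaled* coefficients
$12\min(|d|,c) = (16v_1-v_2)d^2 + (v_2-4v_1)d^4$, dividing 12 out after
decryption: multiplying a depth-2 ciphertext by the centered residue of
$6^{-1}$ ($\approx 2^{32}$) would burn ~32 noise bits, while the
small-integer form costs ~5.

**Record linkage (depth 1).** Full homomorphic Levenshtein DP is
incompatible with a depth-2 budget, so the encrypted circuit computes
the normalized Hamming distance over one-hot encoded, equal-padded
records — each mismatching position flips exactly two bits, so the slot
sum over $2 \cdot \text{pad\_len}$ is the normalized distance. The true
Levenshtein DP is shipped as the plaintext reference semantic and
cross-checked against `utils::adist`.

**Aggregate-only release.** The scheme has no rotation keys, so slot
sums happen after decryption. To avoid leaking per-slot (per-locus)
values, the SPU adds a mask that is uniform in every payload slot but
sums to zero over them (`mask_zero_sum()`); scoring therefore computes
the numerator from the slot sum mod $t$, which is invariant under the
mask.

## 5. Synthetic data

Generators are deliberately simple study conditions, not population
genetics: SNP genotypes are independent $\mathrm{Binomial}(2,
\text{maf})$ draws; STR alleles are uniform integer repeat counts in the
panel range with children inheriting one uniformly chosen allele per
parent per locus (which guarantees the paternity-zero property by
construction); linkage records are uniform strings corrupted by
per-character substitution typos. No linkage disequilibrium, allele
frequency spectra, or STR mutation models — independence suffices to
exercise the cryptographic pipeline, and classification results on this
data should not be read as forensic performance claims.

## 6. Design decisions and limitations

* **RNS-only modulus representation** (no bignum dependency); exactness
  is guaranteed by construction and pinned by brute-force oracles.
* **Gadget base $2^8$** (any power of two supported): digits are exact
  bit-slices of the mixed-radix reconstruction.
* **Serialization** is R-native RDS wrapped with a format tag and the
  parameter fingerprint; artifacts refuse to load against mismatched
  parameters, and secret-bearing key triples refuse to serialize unless
  explicitly allowed.
* **N-of-N, not threshold:** any party withholding its share blocks
  decryption — that is the intended access-control semantic, and also
  the availability cost (withdrawal of a party invalidates tests that
  include it).
* **Noise growth in $N$:** the acceptance suite measures the noise of a
  fixed squaring circuit as parties go $2 \to 5$ and asserts at-most-
  linear growth (with one bit of slack for max-statistics), matching
  the scheme's design goal and ruling out quadratic behaviour.
* Not implemented: networking, PKI, malicious security, GWAS-scale
  statistics, calibrated clinical interpretation of any score.
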