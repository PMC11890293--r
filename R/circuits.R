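# The four genomic test computations.  Each test exists in two forms: an
# exact plaintext oracle implementing the published formula, and an
# encrypted circuit over the multi-key scheme whose decrypted, centered,
# summed output reproduces the oracle's numerator.  All divisions
# (1/sum(c), 1/K, 1/L, 1/max(m,n)) are public-constant normalizations
# applied after decryption — integer homomorphic arithmetic cannot divide.

#' Test specifications
#'
#' Constructors for the public parameters of the four genomic tests.
#'
#' `pm_spec`: personalized-medicine risk score over `n_snps` SNPs with
#' per-SNP weights `c_j` and risk-allele probabilities `pr_j` in (0,1);
#' real-valued parameters are quantized as `round(F * x)` with fixed-point
#' scale `F = scale_F`.
#'
#' `paternity_spec`: STR comparison over `K` loci (default 13 core loci);
#' `allele_range` bounds the repeat counts and drives the exactness check
#' `t > 2 K (max allele difference)^4`.
#'
#' `sps_spec`: similar-patient search over genotype profiles of length `L`
#' in \{0,1,2\} with difference cap `cap_c`.
#'
#' `linkage_spec`: record linkage over strings drawn from `alphabet`,
#' one-hot encoded and padded to `pad_len` characters.
#'
#' @param weights,probs Numeric vectors of equal length (`pm_spec`).
#' @param scale_F Power-of-two fixed-point scale (default 2^10).
#' @param K,locus_names,allele_range STR panel shape (`paternity_spec`).
#' @param L,cap_c Profile length and difference cap (`sps_spec`).
#' @param alphabet,pad_len Symbol set and padded record length
#'   (`linkage_spec`).
#' @return A spec object of the corresponding class.
#' @name test_specs
NULL

#' @rdname test_specs
#' @export
pm_spec <- function(weights, probs, scale_F = 2^10) {
  stopifnot(length(weights) == length(probs), length(weights) >= 1)
  if (any(probs <= 0 | probs >= 1)) stop("probabilities must lie strictly inside (0,1)")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (log2(scale_F) != round(log2(scale_F))) stop("scale_F must be a power of two")
  structure(list(n_snps = length(weights), weights = weights, probs = probs,
                 scale_F = scale_F), class = "ppgc_pm_spec")
}

#' @rdname test_specs
#' @export
paternity_spec <- function(K = 13, locus_names = sprintf("locus_%02d", seq_len(K)),
                           allele_range = c(5, 50)) {
  stopifnot(K >= 1, length(locus_names) == K)
  structure(list(K = as.integer(K), locus_names = locus_names,
                 allele_range = allele_range), class = "ppgc_paternity_spec")
}

#' @rdname test_specs
#' @export
sps_spec <- function(L, cap_c = 2) {
  stopifnot(L >= 1, cap_c >= 0)
  structure(list(L = as.integer(L), cap_c = as.integer(cap_c)),
            class = "ppgc_sps_spec")
}

#' @rdname test_specs
#' @export
linkage_spec <- function(alphabet = c(letters, " "), pad_len = 16) {
  stopifnot(length(alphabet) >= 1, pad_len >= 1)
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be unique")
  structure(list(alphabet = alphabet, pad_len = as.integer(pad_len)),
            class = "ppgc_linkage_spec")
}

pad_slots <- function(values, n) {
  if (length(values) > n) stop("payload does not fit into the ", n, " slots")
  c(values, rep(0, n - length(values)))
}

# ---------------------------------------------------------------------------
# Personalized medicine (SNP disease-risk score)

#' Personalized-medicine risk score (plaintext oracle)
#'
#' Computes `(1/sum c_j) * sum_j c_j * pr_j^{s_j} (1-pr_j)^{1-s_j}` over the
#' minor-allele presence bits `s_j` in \{0,1\}.  Profiles coded \{0,1,2\}
#' should be reduced with [snp_presence()] first; the formula's exponent
#' form is undefined at genotype 2, and on \{0,1\} it equals the linear form
#' `(1-pr) + s (2 pr - 1)` evaluated by the encrypted circuit.
#'
#' @param genotypes Vector in \{0,1\} of length `n_snps`.
#' @param spec A `ppgc_pm_spec`.
#' @return The risk score in `[0,1]`.
#' @export
pm_risk_plain <- function(genotypes, spec) {
  stopifnot(length(genotypes) == spec$n_snps)
  if (any(!genotypes %in% c(0, 1))) {
    stop("personalized-medicine genotypes must be presence bits in {0,1}")
  }
  f <- spec$probs^genotypes * (1 - spec$probs)^(1 - genotypes)
  sum(spec$weights * f) / sum(spec$weights)
}

#' Reduce a \{0,1,2\} genotype to a minor-allele presence bit
#' @param genotypes Vector in \{0,1,2\}.
#' @export
snp_presence <- function(genotypes) as.integer(genotypes >= 1)

pm_plain_tables <- function(spec, pp) {
  t <- pp$ring$t; F <- spec$scale_F
  w <- round(F * spec$weights)
  a <- round(F * (2 * spec$probs - 1))   # signed
  b <- round(F * (1 - spec$probs))
  wa <- cpp_mulmod_vec(w, a %% t, t)
  wb <- cpp_mulmod_vec(w, b, t)
  list(wa = wa, wb = wb)
}

#' Personalized-medicine risk score (encrypted circuit)
#'
#' Evaluates the exact degree-1 linearization
#' `F*c_j * (F*(1-pr_j) + s_j * F*(2 pr_j - 1))` slot-wise: one plaintext
#' multiplication plus one plaintext addition, consuming zero
#' ciphertext-ciphertext multiplications.  After decryption, centering,
#' summing over the first `n_snps` slots and dividing by `F^2 * sum(c_j)`
#' ([pm_score()]), the result reproduces [pm_risk_plain()] to within the
#' fixed-point quantization bound `2/F`.
#'
#' @param ct Ciphertext with presence bits packed one per slot.
#' @param spec A `ppgc_pm_spec`.
#' @param pp Public parameters.
#' @export
pm_risk_circuit <- function(ct, spec, pp) {
  n <- pp$ring$n
  tb <- pm_plain_tables(spec, pp)
  out <- mkh_multiply_plain(ct, pad_slots(tb$wa, n), pp, scale = 1)
  mkh_add_plain(out, pad_slots(tb$wb, n), pp)
}

#' Post-process decrypted test slots into a scored result
#'
#' Centers the decrypted slot values mod t, sums the payload slots into the
#' test numerator and divides by the public normalizer and the carried
#' fixed-point scale.
#'
#' @param slots Decrypted slot vector in `[0, t)`.
#' @param spec The test spec.
#' @param pp Public parameters.
#' @return A `ppgc_scored_result` with fields `raw_slots` (centered),
#'   `numerator`, `normalizer`, `scale`, `score`.
#' @name scoring
NULL

new_scored <- function(raw, numerator, normalizer, scale, test) {
  structure(list(raw_slots = raw, numerator = numerator,
                 normalizer = normalizer, scale = scale,
                 score = numerator / (normalizer * scale), test = test),
            class = "ppgc_scored_result")
}

#' @export
print.ppgc_scored_result <- function(x, ...) {
  cat(sprintf("<ppgc_scored_result:%s> numerator=%.0f normalizer=%.0f scale=%.0f score=%.6g\n",
              x$test, x$numerator, x$normalizer, x$scale, x$score))
  invisible(x)
}

#' @rdname scoring
#' @export
pm_score <- function(slots, spec, pp) {
  raw <- center_mod(slots, pp$ring$t)[seq_len(spec$n_snps)]
  new_scored(raw, slot_aggregate(slots, seq_len(spec$n_snps), pp$ring$t),
             sum(round(spec$scale_F * spec$weights)), spec$scale_F, "pm")
}

# Aggregate payload slots modulo t, then center.  Equals sum(centered)
# whenever the true aggregate is below t/2, and — unlike the centered sum —
# remains correct after zero-sum masking randomizes the individual slots.
slot_aggregate <- function(slots, active, t) {
  center_mod(sum(slots[active]) %% t, t)
}

# ---------------------------------------------------------------------------
# Paternity testing (STR)

#' Paternity test score (plaintext oracle)
#'
#' Per locus computes
#' `f = (x1-y1)(x1-y2)(x2-y1)(x2-y2)` between the child's alleles (x) and
#' the alleged father's (y); `f = 0` exactly when they share at least one
#' allele value at the locus.  The score is `sum(f)/K`; a biological child
#' of the tested man scores 0 at every locus by Mendelian inheritance.
#'
#' @param child,father STR profiles: data frames with columns `locus`,
#'   `allele1`, `allele2` covering the spec's loci.
#' @param spec A `ppgc_paternity_spec`.
#' @return A `ppgc_scored_result`.
#' @export
paternity_plain <- function(child, father, spec) {
  cx <- str_alleles(child, spec); fx <- str_alleles(father, spec)
  f <- (cx$a1 - fx$a1) * (cx$a1 - fx$a2) * (cx$a2 - fx$a1) * (cx$a2 - fx$a2)
  new_scored(f, sum(f), spec$K, 1, "paternity")
}

#' Extract a spec-ordered allele-lane pair from an STR profile
#' @param profile STR profile data frame.
#' @param spec A `ppgc_paternity_spec`.
#' @return List with numeric lanes `a1`, `a2` ordered as `spec$locus_names`.
#' @export
str_alleles <- function(profile, spec) {
  idx <- match(spec$locus_names, profile$locus)
  if (anyNA(idx)) {
    stop("profile is missing loci: ",
         paste(spec$locus_names[is.na(idx)], collapse = ", "))
  }
  list(a1 = as.numeric(profile$allele1[idx]), a2 = as.numeric(profile$allele2[idx]))
}

check_paternity_bound <- function(spec, pp) {
  dmax <- diff(range(spec$allele_range))
  need <- 2 * spec$K * dmax^4
  if (pp$ring$t <= need) {
    stop(sprintf(
      "plaintext modulus too small for exact paternity arithmetic: need t > %g, have t = %g",
      need, pp$ring$t))
  }
  invisible(TRUE)
}

#' Paternity test (encrypted circuit)
#'
#' The child's two allele lanes and the father's two lanes are separate
#' ciphertexts (typically under the two parties' own keys), locus i in slot
#' i.  The circuit forms the four pairwise differences (4 homomorphic
#' subtractions) and multiplies them together (3 ciphertext-ciphertext
#' multiplications arranged as a balanced tree), consuming 2 multiplicative
#' levels.  Decrypted + centered + summed + divided by K
#' ([paternity_score()]) it equals [paternity_plain()] exactly.
#'
#' @param child_ct,father_ct Lists with elements `a1`, `a2`: ciphertexts of
#'   the two allele lanes.
#' @param spec A `ppgc_paternity_spec`.
#' @param pubkeys Named list of public key bundles.
#' @param pp Public parameters.
#' @export
paternity_circuit <- function(child_ct, father_ct, spec, pubkeys, pp) {
  check_paternity_bound(spec, pp)
  d11 <- mkh_sub(child_ct$a1, father_ct$a1, pp)
  d12 <- mkh_sub(child_ct$a1, father_ct$a2, pp)
  d21 <- mkh_sub(child_ct$a2, father_ct$a1, pp)
  d22 <- mkh_sub(child_ct$a2, father_ct$a2, pp)
  m1 <- mkh_multiply(d11, d12, pubkeys, pp)
  m2 <- mkh_multiply(d21, d22, pubkeys, pp)
  mkh_multiply(m1, m2, pubkeys, pp)
}

#' @rdname scoring
#' @export
paternity_score <- function(slots, spec, pp) {
  raw <- center_mod(slots, pp$ring$t)[seq_len(spec$K)]
  new_scored(raw, slot_aggregate(slots, seq_len(spec$K), pp$ring$t),
             spec$K, 1, "paternity")
}

# ---------------------------------------------------------------------------
# Similar patient search (SNP profile distance)

#' Similar-patient-search distance (plaintext oracle)
#'
#' `(1/L) * sum_i min(|a_i - b_i|, c)` over genotype profiles in \{0,1,2\}.
#'
#' @param a_profile,b_profile Genotype vectors of length `L` in \{0,1,2\}.
#' @param spec A `ppgc_sps_spec`.
#' @return A `ppgc_scored_result`.
#' @export
sps_plain <- function(a_profile, b_profile, spec) {
  stopifnot(length(a_profile) == spec$L, length(b_profile) == spec$L)
  check_genotypes(a_profile); check_genotypes(b_profile)
  f <- pmin(abs(a_profile - b_profile), spec$cap_c)
  new_scored(f, sum(f), spec$L, 1, "sps")
}

check_genotypes <- function(g) {
  if (any(!g %in% c(0, 1, 2))) stop("genotypes must be coded {0,1,2}")
  invisible(TRUE)
}

#' Exact polynomial interpolation of |d| on a bounded integer domain
#'
#' Returns the coefficients (over Z_t, even powers only) of the unique even
#' polynomial `p` of degree `2r` with `p(d) = |d|` for every integer
#' `d in [-r, r]`.  For `r = 1`, `p(d) = d^2`; for `r = 2`,
#' `p(d) = 6^{-1} (7 d^2 - d^4) mod t`.  This is how the absolute
#' difference of Eq.-style comparisons is realized arithmetically under
#' encryption, where no native comparison exists.
#'
#' @param domain_radius Integer radius `r >= 1`.
#' @param t Prime plaintext modulus; the interpolation denominators must be
#'   invertible mod t.
#' @return Numeric vector of length `r + 1`: coefficients of
#'   `d^0, d^2, ..., d^{2r}` as residues mod t.
#' @export
abs_interp_coeffs <- function(domain_radius, t) {
  interp_even_coeffs(0:domain_radius, 0:domain_radius, t)
}

# Lagrange interpolation in u = d^2 over nodes u_j = j^2 with values v_j,
# returning coefficients of u^0..u^r as residues mod t.
interp_even_coeffs <- function(j_nodes, values, t) {
  r <- length(j_nodes) - 1
  u <- (j_nodes^2) %% t
  coef <- numeric(r + 1)
  for (k in seq_along(j_nodes)) {
    # Lagrange basis polynomial for node k as coefficients in u
    num <- 1 # polynomial, constant 1
    den <- 1
    for (l in seq_along(j_nodes)) {
      if (l == k) next
      # num <- num * (u - u_l);  den <- den * (u_k - u_l)
      shifted <- c(0, num)                       # num * u
      scaled <- cpp_mulmod_vec(c(num, 0), rep((t - u[l]) %% t, length(num) + 1), t)
      num <- (shifted + scaled) %% t
      den <- cpp_mulmod_vec(den, (u[k] - u[l]) %% t, t)
    }
    lam <- cpp_mulmod_vec(values[k] %% t, cpp_invmod(den, t), t)
    contrib <- cpp_mulmod_vec(num, rep(lam, length(num)), t)
    coef[seq_along(contrib)] <- (coef[seq_along(contrib)] + contrib) %% t
  }
  coef
}

#' Evaluate even-power coefficients at integer points (testing helper)
#' @param coef Output of [abs_interp_coeffs()].
#' @param d Integer points.
#' @param t Modulus.
#' @export
eval_even_poly <- function(coef, d, t) {
  u <- (d * d) %% t
  out <- numeric(length(d))
  pw <- rep(1, length(d))
  for (k in seq_along(coef)) {
    out <- (out + cpp_mulmod_vec(pw, rep(coef[k], length(d)), t)) %% t
    pw <- cpp_mulmod_vec(pw, u, t)
  }
  out
}

#' Similar patient search (encrypted circuit)
#'
#' Computes `d = a - b` (one subtraction), squares it twice
#' (`d^2` then `d^4`, two ciphertext-ciphertext multiplications, depth 2)
#' and combines them with the plaintext interpolation coefficients of
#' `min(|d|, c)` on the genotype difference domain `[-2, 2]`.  For
#' `cap_c >= 2` the payload is exactly `|a_i - b_i|` per slot.
#'
#' @param enc_a,enc_b Genotype ciphertexts.
#' @param spec A `ppgc_sps_spec`.
#' @param pubkeys Named list of public key bundles.
#' @param pp Public parameters.
#' @export
sps_circuit <- function(enc_a, enc_b, spec, pubkeys, pp) {
  t <- pp$ring$t; n <- pp$ring$n
  v1 <- min(1, spec$cap_c); v2 <- min(2, spec$cap_c)
  # Integer-scaled interpolation: 12 * min(|d|, c) = (16 v1 - v2) d^2 +
  # (v2 - 4 v1) d^4 on d in [-2, 2].  Small integer coefficients keep the
  # plaintext-multiplication noise growth to a few bits; the factor 12 is
  # divided out exactly after decryption (see sps_score).
  alpha12 <- (16 * v1 - v2) %% t
  beta12 <- (v2 - 4 * v1) %% t
  d <- mkh_sub(enc_a, enc_b, pp)
  d2 <- mkh_multiply(d, d, pubkeys, pp)
  d4 <- mkh_multiply(d2, d2, pubkeys, pp)
  term2 <- mkh_multiply_plain(d2, rep(alpha12, n), pp)
  term4 <- mkh_multiply_plain(d4, rep(beta12, n), pp)
  mkh_add(term2, term4, pp)
}

sps_coeff_scale <- 12

#' @rdname scoring
#' @export
sps_score <- function(slots, spec, pp) {
  agg12 <- slot_aggregate(slots, seq_len(spec$L), pp$ring$t)
  if (agg12 %% sps_coeff_scale != 0) {
    stop("decrypted similar-patient aggregate is not a multiple of the coefficient scale")
  }
  raw12 <- center_mod(slots, pp$ring$t)[seq_len(spec$L)]
  raw <- if (all(raw12 %% sps_coeff_scale == 0)) raw12 / sps_coeff_scale
         else rep(NA_real_, spec$L) # slots are masked; only the aggregate is meaningful
  new_scored(raw, agg12 / sps_coeff_scale, spec$L, 1, "sps")
}

# ---------------------------------------------------------------------------
# Record linkage

#' Levenshtein edit distance (plaintext oracle)
#'
#' Standard dynamic-programming edit distance with unit costs, normalized
#' by `max(m, n)` — the reference semantic for record linkage.  The
#' encrypted circuit computes a normalized Hamming distance over one-hot
#' records instead (see [linkage_circuit()]); this oracle is the exact
#' published distance.
#'
#' @param rec_a,rec_b Character scalars.
#' @param spec A `ppgc_linkage_spec` (unused by the DP itself; kept for a
#'   uniform interface).
#' @return A `ppgc_scored_result` whose `numerator` is the edit distance
#'   and `normalizer` is `max(nchar(a), nchar(b))`.
#' @export
linkage_plain_levenshtein <- function(rec_a, rec_b, spec = NULL) {
  a <- strsplit(rec_a, "")[[1]]; b <- strsplit(rec_b, "")[[1]]
  m <- length(a); n <- length(b)
  D <- matrix(0, m + 1, n + 1)
  D[, 1] <- 0:m; D[1, ] <- 0:n
  for (i in seq_len(m)) for (j in seq_len(n)) {
    D[i + 1, j + 1] <- min(D[i, j + 1] + 1, D[i + 1, j] + 1,
                           D[i, j] + (a[i] != b[j]))
  }
  lev <- D[m + 1, n + 1]
  norm <- max(m, n, 1)
  new_scored(lev, lev, norm, 1, "linkage_lev")
}

#' One-hot encoding of a record
#'
#' Encodes `pad_len` characters over the spec alphabet as a 0/1 vector of
#' length `pad_len * |alphabet|`; records shorter than `pad_len` are padded
#' with the first alphabet symbol.
#'
#' @param record Character scalar.
#' @param spec A `ppgc_linkage_spec`.
#' @export
one_hot_record <- function(record, spec) {
  chars <- strsplit(record, "")[[1]]
  if (length(chars) > spec$pad_len) stop("record longer than pad_len")
  chars <- c(chars, rep(spec$alphabet[1], spec$pad_len - length(chars)))
  idx <- match(chars, spec$alphabet)
  if (anyNA(idx)) stop("record contains symbols outside the alphabet")
  bits <- numeric(spec$pad_len * length(spec$alphabet))
  bits[(seq_len(spec$pad_len) - 1) * length(spec$alphabet) + idx] <- 1
  bits
}

#' Record linkage (encrypted circuit)
#'
#' Over one-hot encoded, equal-padded records, computes `(a_bit - b_bit)^2`
#' per slot (one subtraction, one squaring: depth 1).  Each mismatching
#' character position flips exactly two bits, so the slot sum equals twice
#' the Hamming distance of the symbol streams; [linkage_score()] divides by
#' `2 * pad_len` to yield the normalized Hamming distance.
#'
#' @param enc_a,enc_b One-hot record ciphertexts of equal layout.
#' @param spec A `ppgc_linkage_spec`.
#' @param pubkeys Named list of public key bundles.
#' @param pp Public parameters.
#' @export
linkage_circuit <- function(enc_a, enc_b, spec, pubkeys, pp) {
  d <- mkh_sub(enc_a, enc_b, pp)
  mkh_multiply(d, d, pubkeys, pp)
}

#' @rdname scoring
#' @export
linkage_score <- function(slots, spec, pp) {
  nbits <- spec$pad_len * length(spec$alphabet)
  raw <- center_mod(slots, pp$ring$t)[seq_len(nbits)]
  new_scored(raw, slot_aggregate(slots, seq_len(nbits), pp$ring$t),
             2 * spec$pad_len, 1, "linkage")
}

#' Normalized Hamming distance over one-hot records (plaintext oracle)
#' @param rec_a,rec_b Character scalars.
#' @param spec A `ppgc_linkage_spec`.
#' @export
linkage_plain_hamming <- function(rec_a, rec_b, spec) {
  ha <- one_hot_record(rec_a, spec); hb <- one_hot_record(rec_b, spec)
  s <- sum((ha - hb)^2)
  new_scored(s, s, 2 * spec$pad_len, 1, "linkage")
}

# ---------------------------------------------------------------------------
# Aggregate-only release

#' Zero-sum masking of per-slot results
#'
#' Adds a plaintext mask `r` that is uniform mod t in every slot except
#' that it sums to zero (mod t) over `active_slots`; the slot aggregate
#' over the active slots is preserved while each individual slot becomes
#' uniformly distributed.  Used by the storage unit to release only the
#' aggregate score, since the scheme carries no rotation keys for
#' homomorphic slot summation.
#'
#' @param ct Evaluated ciphertext.
#' @param active_slots Integer indices of the payload slots.
#' @param pp Public parameters.
#' @param seed Optional integer seed.
#' @export
mask_zero_sum <- function(ct, active_slots, pp, seed = NULL) {
  n <- pp$ring$n; t <- pp$ring$t
  if (length(active_slots) == 0 || any(active_slots < 1 | active_slots > n)) {
    stop("invalid active slot set")
  }
  if (!is.null(seed)) set.seed(seed)
  r <- floor(stats::runif(n) * t)
  act <- sort(unique(active_slots))
  if (length(act) == 1) {
    r[act] <- 0
  } else {
    last <- act[length(act)]
    r[last] <- (t - sum(r[act[-length(act)]]) %% t) %% t
  }
  r[r == t] <- 0
  mkh_add_plain(ct, r, pp)
}
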