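# Multi-key homomorphic encryption (BFV-flavoured, exact integer plaintexts).
#
# A ciphertext under the parties (H_1, ..., H_N) is a tuple
# (c_0, c_1, ..., c_N) of ring elements decrypting through the secret vector
# (1, s_1, ..., s_N):   c_0 + sum_j c_j s_j  =  Delta * m + e   (mod q),
# Delta = floor(q/t).  Multiplication tensors two such tuples, scales the
# tensor by t/q, and relinearizes back to N+1 parts using each party's
# gadget-encrypted evaluation key against a common reference gadget vector.

#' Scheme setup
#'
#' Generates the public parameters shared by every party: the ring
#' parameters, the seed of the common reference polynomials (a
#' gadget-dimension vector of uniform ring elements that all public and
#' evaluation keys are built against), the smudging-noise bound used in
#' partial decryption, and the multiplicative depth budget.
#'
#' Deterministic given `seed`: the same seed reproduces byte-identical
#' parameters, and every party regenerates identical reference polynomials
#' from the embedded seed.
#'
#' @param profile Parameter profile name (see [ring_params()]) or a
#'   `ppgc_ring_params` object.
#' @param seed Integer seed for the common reference polynomials.
#' @param smudge_bound Magnitude bound of the uniform masking noise added to
#'   partial decryptions (default 2^40).
#' @param depth_budget Maximum nesting of ciphertext-ciphertext
#'   multiplications (default 2).
#' @return An object of class `ppgc_pp`.
#' @export
mkh_setup <- function(profile = "toy", seed = 1, smudge_bound = 2^40,
                      depth_budget = 2) {
  ring <- if (inherits(profile, "ppgc_ring_params")) profile else ring_params(profile)
  validate_ring_params(ring)
  pp <- structure(list(
    ring = ring,
    crs_seed = as.numeric(seed),
    smudge_bound = smudge_bound,
    depth_budget = depth_budget
  ), class = "ppgc_pp")
  pp$fingerprint <- params_fingerprint(pp)
  pp
}

params_fingerprint <- function(pp) {
  r <- pp$ring
  rlang::hash(list(r$n, r$q_primes, r$aux_primes, r$t, r$sigma_err,
                   r$gadget_base, pp$crs_seed, pp$smudge_bound, pp$depth_budget))
}

#' @export
print.ppgc_pp <- function(x, ...) {
  cat(sprintf("<ppgc_pp> crs_seed=%.0f smudge<=2^%.0f depth<=%d fp=%s\n",
              x$crs_seed, log2(max(x$smudge_bound, 1)), x$depth_budget,
              substr(x$fingerprint, 1, 8)))
  print(x$ring)
  invisible(x)
}

# common reference gadget vector: one uniform ring element per gadget digit
crs_vector <- function(pp) {
  r <- pp$ring
  lapply(seq_len(r$gadget_digits), function(j) {
    cpp_sample_uniform(pp$crs_seed * 131071 + j, r$q_primes, r$n)
  })
}

# residues of base^(j-1) modulo every q prime
gadget_scalars <- function(params, j) {
  vapply(params$q_primes, function(p) cpp_powmod(params$gadget_base, j - 1, p),
         numeric(1))
}

stack_ntt <- function(polys, params) {
  do.call(rbind, lapply(polys, function(m) cpp_ntt(m, params$q_primes, FALSE)))
}

#' Per-party key generation
#'
#' Produces the party's key triple: a ternary secret key `s`, a public key
#' `b = -s*a + e` against the common reference gadget vector `a`, and an
#' evaluation key — a gadget encryption `(d0, d1, d2)` of `s` under itself
#' (`d0 = -s*d1 + e + r*g`, `d2 = r*a + e + s*g` for ternary `r` and gadget
#' vector `g`) sufficient to relinearize products involving this party's
#' key.
#'
#' @param pp Public parameters from [mkh_setup()].
#' @param party_id Character id of the party.
#' @param seed Optional integer seed (deterministic keys for testing).
#' @param .force_sk Internal testing hook: use the supplied ring element as
#'   the secret key instead of sampling one.
#' @return An object of class `ppgc_keys` with fields `party_id`, `sk`,
#'   `pk` (list `b`, plus the shared `a` by reference through `pp`), `ek`.
#' @export
mkh_keygen <- function(pp, party_id, seed = NULL, .force_sk = NULL) {
  r <- pp$ring
  seed <- seed %||% rand_seed()
  d <- r$gadget_digits
  a <- crs_vector(pp)
  sk <- .force_sk %||% cpp_sample_ternary(seed * 977 + 1, r$n, r$q_primes)
  rr <- cpp_sample_ternary(seed * 977 + 2, r$n, r$q_primes)
  gauss <- function(tag) cpp_sample_gauss(seed * 977 + tag, r$sigma_err, r$n, r$q_primes)
  b <- vector("list", d); d0 <- vector("list", d); d1 <- vector("list", d); d2 <- vector("list", d)
  for (j in seq_len(d)) {
    g_j <- gadget_scalars(r, j)
    b[[j]] <- cpp_mat_add(cpp_mat_neg(cpp_negacyclic_mul(sk, a[[j]], r$q_primes), r$q_primes),
                          gauss(10 + j), r$q_primes)
    d1[[j]] <- cpp_sample_uniform(seed * 977 + 1000 + j, r$q_primes, r$n)
    d0[[j]] <- cpp_mat_add(
      cpp_mat_add(cpp_mat_neg(cpp_negacyclic_mul(sk, d1[[j]], r$q_primes), r$q_primes),
                  gauss(2000 + j), r$q_primes),
      cpp_scalar_mul(rr, g_j, r$q_primes), r$q_primes)
    d2[[j]] <- cpp_mat_add(
      cpp_mat_add(cpp_negacyclic_mul(rr, a[[j]], r$q_primes),
                  gauss(3000 + j), r$q_primes),
      cpp_scalar_mul(sk, g_j, r$q_primes), r$q_primes)
  }
  keys <- structure(list(
    party_id = as.character(party_id),
    sk = sk,
    pk = list(b = b),
    ek = list(d0 = d0, d1 = d1, d2 = d2),
    fingerprint = pp$fingerprint,
    cache = list(bntt = stack_ntt(b, r), d0ntt = stack_ntt(d0, r),
                 d1ntt = stack_ntt(d1, r), d2ntt = stack_ntt(d2, r))
  ), class = "ppgc_keys")
  keys
}

#' Public part of a key triple
#'
#' Strips the secret key, leaving only material safe to publish (public key,
#' evaluation key, NTT caches).
#' @param keys A `ppgc_keys`.
#' @export
public_bundle <- function(keys) {
  keys$sk <- NULL
  class(keys) <- c("ppgc_pubkeys", "ppgc_keys")
  keys
}

key_cache <- function(bundle, pp) {
  if (!is.null(bundle$cache)) return(bundle$cache)
  r <- pp$ring
  list(bntt = stack_ntt(bundle$pk$b, r), d0ntt = stack_ntt(bundle$ek$d0, r),
       d1ntt = stack_ntt(bundle$ek$d1, r), d2ntt = stack_ntt(bundle$ek$d2, r))
}

new_ct <- function(parts, parties, depth, scale, pp) {
  structure(list(parts = parts, parties = parties, mult_depth = depth,
                 plain_scale = scale, fingerprint = pp$fingerprint),
            class = "ppgc_ct")
}

#' @export
print.ppgc_ct <- function(x, ...) {
  cat(sprintf("<ppgc_ct> parties={%s} depth=%d scale=%.0f\n",
              paste(x$parties, collapse = ","), x$mult_depth, x$plain_scale))
  invisible(x)
}

check_ct <- function(ct, pp) {
  if (!inherits(ct, "ppgc_ct")) stop("not a ciphertext")
  if (!identical(ct$fingerprint, pp$fingerprint)) {
    stop("ciphertext was produced under different public parameters")
  }
  if (length(ct$parts) != length(ct$parties) + 1) stop("corrupt ciphertext")
  invisible(TRUE)
}

# Delta * plaintext-poly as a ring element; poly entries in [0, t)
delta_times_poly <- function(poly, pp) {
  r <- pp$ring
  del <- cpp_delta_mod(r$q_primes, r$t)
  pm <- matrix(rep(poly, each = length(r$q_primes)), nrow = length(r$q_primes))
  cpp_scalar_mul(pm, del, r$q_primes)
}

# signed plaintext poly (coefficients centered mod t) lifted into R_q
lift_signed_poly <- function(poly_centered, pp) {
  r <- pp$ring
  t(vapply(r$q_primes, function(p) poly_centered %% p, numeric(r$n)))
}

#' Encryption under a single party's public key
#'
#' Packs the slot vector into a plaintext polynomial and encrypts it:
#' `c0 = u*b + e0 + Delta*m`, `c1 = u*a + e1` with ternary `u` and Gaussian
#' errors, where `(b, a)` is the first row of the party's public key against
#' the common reference vector.
#'
#' @param m Length-n slot vector with entries in `[0, t)`.
#' @param keys The encrypting party's key bundle (public part suffices).
#' @param pp Public parameters.
#' @param seed Optional integer seed.
#' @return A fresh single-key `ppgc_ct` (two parts, depth 0, scale 1).
#' @export
mkh_encrypt <- function(m, keys, pp, seed = NULL) {
  r <- pp$ring
  seed <- seed %||% rand_seed()
  poly <- batch_encode(m, r)
  a1 <- crs_vector(pp)[[1]]
  u <- cpp_sample_ternary(seed * 677 + 1, r$n, r$q_primes)
  e0 <- cpp_sample_gauss(seed * 677 + 2, r$sigma_err, r$n, r$q_primes)
  e1 <- cpp_sample_gauss(seed * 677 + 3, r$sigma_err, r$n, r$q_primes)
  c0 <- cpp_mat_add(cpp_mat_add(cpp_negacyclic_mul(u, keys$pk$b[[1]], r$q_primes),
                                e0, r$q_primes),
                    delta_times_poly(poly, pp), r$q_primes)
  c1 <- cpp_mat_add(cpp_negacyclic_mul(u, a1, r$q_primes), e1, r$q_primes)
  new_ct(list(c0, c1), keys$party_id, 0L, 1, pp)
}

#' Extend a ciphertext to a larger party set
#'
#' Inserts zero parts for the added parties so the ciphertext decrypts to
#' the same plaintext under the extended secret vector.  Party order is
#' canonical (sorted ids), making evaluation order-invariant.
#'
#' @param ct A `ppgc_ct`.
#' @param parties Character vector of party ids; must be a superset of
#'   `ct$parties`.
#' @param pp Public parameters.
#' @export
mkh_extend <- function(ct, parties, pp) {
  check_ct(ct, pp)
  parties <- sort(unique(as.character(parties)))
  if (!all(ct$parties %in% parties)) stop("target set must contain the ciphertext's parties")
  if (identical(parties, ct$parties)) return(ct)
  zero <- ring_zero(pp$ring)
  parts <- c(list(ct$parts[[1]]),
             lapply(parties, function(id) {
               j <- match(id, ct$parties)
               if (is.na(j)) zero else ct$parts[[j + 1]]
             }))
  new_ct(parts, parties, ct$mult_depth, ct$plain_scale, pp)
}

#' Homomorphic addition and subtraction
#'
#' Operands are auto-extended to the union of their party sets; the result
#' decrypts to the slot-wise sum (difference) mod t.
#'
#' @param ct1,ct2 Ciphertexts with equal `plain_scale`.
#' @param pp Public parameters.
#' @export
mkh_add <- function(ct1, ct2, pp) {
  check_ct(ct1, pp); check_ct(ct2, pp)
  if (ct1$plain_scale != ct2$plain_scale) stop("plaintext scale mismatch")
  u <- sort(union(ct1$parties, ct2$parties))
  a <- mkh_extend(ct1, u, pp); b <- mkh_extend(ct2, u, pp)
  parts <- mapply(function(x, y) cpp_mat_add(x, y, pp$ring$q_primes),
                  a$parts, b$parts, SIMPLIFY = FALSE)
  new_ct(parts, u, max(a$mult_depth, b$mult_depth), a$plain_scale, pp)
}

#' @rdname mkh_add
#' @export
mkh_sub <- function(ct1, ct2, pp) {
  check_ct(ct2, pp)
  neg <- ct2
  neg$parts <- lapply(ct2$parts, function(m) cpp_mat_neg(m, pp$ring$q_primes))
  mkh_add(ct1, neg, pp)
}

#' Homomorphic multiplication of two multi-key ciphertexts
#'
#' Computes the scaled tensor product `round(t/q * ct1 (x) ct2)` and
#' relinearizes it back to a regular (N+1)-part ciphertext using the
#' parties' evaluation keys.  Consumes one multiplicative level; errors if
#' the depth budget would be exceeded or a needed key bundle is missing.
#'
#' @param ct1,ct2 Ciphertexts.
#' @param pubkeys Named list of public key bundles covering every party of
#'   both operands.
#' @param pp Public parameters.
#' @export
mkh_multiply <- function(ct1, ct2, pubkeys, pp) {
  check_ct(ct1, pp); check_ct(ct2, pp)
  r <- pp$ring
  depth <- 1L + max(ct1$mult_depth, ct2$mult_depth)
  if (depth > pp$depth_budget) {
    stop(sprintf("multiplicative depth budget exhausted (budget %d)", pp$depth_budget))
  }
  u <- sort(union(ct1$parties, ct2$parties))
  missing <- setdiff(u, names(pubkeys))
  if (length(missing)) stop("missing public/evaluation key for: ", paste(missing, collapse = ", "))
  a <- mkh_extend(ct1, u, pp); b <- mkh_extend(ct2, u, pp)
  N <- length(u); np <- N + 1L
  full <- c(r$q_primes, r$aux_primes)
  lift_full <- function(part) {
    cpp_ntt(rbind(part, cpp_lift(part, r$q_primes, r$aux_primes)), full, FALSE)
  }
  fa <- lapply(a$parts, lift_full)
  fb <- lapply(b$parts, lift_full)
  tensor <- vector("list", np * np)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    prod <- cpp_ntt(cpp_pointwise_mul(fa[[i]], fb[[j]], full), full, TRUE)
    tensor[[(i - 1) * np + j]] <- cpp_scale_round(prod, r$q_primes, r$aux_primes, r$t)
  }
  Tn <- function(i, j) tensor[[(i - 1) * np + j]] # 1-based, index 1 = constant slot
  out <- vector("list", np)
  out[[1]] <- Tn(1, 1)
  for (i in 2:np) out[[i]] <- cpp_mat_add(Tn(1, i), Tn(i, 1), r$q_primes)
  lb <- as.integer(log2(r$gadget_base)); nd <- r$gadget_digits
  caches <- lapply(u, function(id) key_cache(pubkeys[[id]], pp))
  names(caches) <- u
  for (i in 2:np) for (j in 2:np) {
    ci <- caches[[u[i - 1]]]; cj <- caches[[u[j - 1]]]
    cc <- Tn(i, j)
    r1 <- cpp_gadget_inner(cc, list(cj$bntt, ci$d2ntt), r$q_primes, lb, nd)
    out[[j]] <- cpp_mat_add(out[[j]], r1[[2]], r$q_primes)
    r2 <- cpp_gadget_inner(r1[[1]], list(ci$d0ntt, ci$d1ntt), r$q_primes, lb, nd)
    out[[1]] <- cpp_mat_add(out[[1]], r2[[1]], r$q_primes)
    out[[i]] <- cpp_mat_add(out[[i]], r2[[2]], r$q_primes)
  }
  new_ct(out, u, depth, ct1$plain_scale * ct2$plain_scale, pp)
}

#' Plaintext (slot-wise) multiplication and addition
#'
#' `mkh_multiply_plain` multiplies every ciphertext part by the encoded
#' plaintext polynomial (centered lift), so the result decrypts to the
#' slot-wise product mod t; it consumes no multiplicative level.
#' `mkh_add_plain` adds `Delta * p` to the constant part.
#'
#' @param ct A ciphertext.
#' @param p Length-n slot vector in `[0, t)`.
#' @param pp Public parameters.
#' @param scale Fixed-point scale carried by `p` (multiplies the
#'   ciphertext's `plain_scale`).
#' @export
mkh_multiply_plain <- function(ct, p, pp, scale = 1) {
  check_ct(ct, pp)
  r <- pp$ring
  poly <- center_mod(batch_encode(p, r), r$t)
  pm <- lift_signed_poly(poly, pp)
  parts <- lapply(ct$parts, function(m) cpp_negacyclic_mul(m, pm, r$q_primes))
  new_ct(parts, ct$parties, ct$mult_depth, ct$plain_scale * scale, pp)
}

#' @rdname mkh_multiply_plain
#' @export
mkh_add_plain <- function(ct, p, pp) {
  check_ct(ct, pp)
  poly <- batch_encode(p, pp$ring)
  ct$parts[[1]] <- cpp_mat_add(ct$parts[[1]], delta_times_poly(poly, pp), pp$ring$q_primes)
  ct
}

#' Partial decryption
#'
#' The party computes its decryption share `c_j * s_j + e_sm`, where `e_sm`
#' is smudging noise uniform in `[-smudge_bound, smudge_bound]` that hides
#' the secret key in the released share.
#'
#' @param ct The evaluated ciphertext (must include the party).
#' @param keys The party's full key triple (with secret key).
#' @param pp Public parameters.
#' @param seed Optional integer seed for the smudging noise.
#' @return A `ppgc_pdec` with fields `party_id` and `share`.
#' @export
mkh_part_dec <- function(ct, keys, pp, seed = NULL) {
  check_ct(ct, pp)
  j <- match(keys$party_id, ct$parties)
  if (is.na(j)) stop("party ", keys$party_id, " is not present in the ciphertext")
  if (is.null(keys$sk)) stop("partial decryption requires the secret key")
  r <- pp$ring
  sm <- cpp_sample_smudge((seed %||% rand_seed()), pp$smudge_bound, r$n, r$q_primes)
  share <- cpp_mat_add(cpp_negacyclic_mul(ct$parts[[j + 1]], keys$sk, r$q_primes),
                       sm, r$q_primes)
  structure(list(party_id = keys$party_id, share = share), class = "ppgc_pdec")
}

#' Final decryption from all partial shares
#'
#' Sums the constant part with every party's share, scales by `t/q` with
#' exact per-coefficient rounding, reduces mod t and decodes the slots.
#' Requires exactly one share per party of the ciphertext (N-of-N access
#' control); refusing otherwise is the scheme's access-control semantics.
#'
#' @param ct The evaluated ciphertext.
#' @param shares List of `ppgc_pdec`, one per party in `ct$parties`.
#' @param pp Public parameters.
#' @param .allow_incomplete Internal testing hook: skip the completeness
#'   check and decrypt with whatever shares were supplied.
#' @return Length-n slot vector in `[0, t)`.
#' @export
mkh_fin_dec <- function(ct, shares, pp, .allow_incomplete = FALSE) {
  check_ct(ct, pp)
  ids <- vapply(shares, function(s) s$party_id, character(1))
  if (!.allow_incomplete) {
    if (anyDuplicated(ids)) stop("duplicate decryption share")
    if (!setequal(ids, ct$parties) || length(ids) != length(ct$parties)) {
      stop("incomplete decryption: a share from every party in the ciphertext is required")
    }
  }
  r <- pp$ring
  v <- ct$parts[[1]]
  for (s in shares) v <- cpp_mat_add(v, s$share, r$q_primes)
  poly <- cpp_decrypt_scale(v, r$q_primes, r$t)
  batch_decode(poly, r)
}

# exact decryption with all secret keys in hand (testing / noise analysis)
decrypt_with_sks <- function(ct, sks, pp) {
  r <- pp$ring
  v <- ct$parts[[1]]
  for (j in seq_along(ct$parties)) {
    sk <- sks[[ct$parties[j]]]
    if (is.null(sk)) stop("missing secret key for ", ct$parties[j])
    v <- cpp_mat_add(v, cpp_negacyclic_mul(ct$parts[[j + 1]], sk, r$q_primes), r$q_primes)
  }
  v
}

#' Exact noise measurement (white-box)
#'
#' With every involved secret key available, computes the exact decryption
#' `v = c_0 + sum c_j s_j`, subtracts `Delta` times the decoded plaintext
#' polynomial and returns `log2` of the largest centered residual
#' coefficient.  Decryption is reliable while this stays below
#' `log2(q / (2t))`.
#'
#' @param ct A ciphertext.
#' @param sks Named list (by party id) of secret-key ring elements.
#' @param pp Public parameters.
#' @return Noise magnitude in bits (`-Inf` for a noiseless ciphertext).
#' @export
mkh_noise <- function(ct, sks, pp) {
  check_ct(ct, pp)
  r <- pp$ring
  v <- decrypt_with_sks(ct, sks, pp)
  poly <- cpp_decrypt_scale(v, r$q_primes, r$t)
  resid <- cpp_mat_sub(v, delta_times_poly(poly, pp), r$q_primes)
  max(cpp_noise_bits(resid, r$q_primes))
}

#' Decryption noise threshold in bits
#' @param pp Public parameters.
#' @return `log2(q / (2t))`.
#' @export
noise_threshold_bits <- function(pp) {
  pp$ring$q_bits - log2(pp$ring$t) - 1
}

#' Full decryption via the distributed protocol (convenience)
#'
#' Runs [mkh_part_dec()] for every party and [mkh_fin_dec()] on the shares.
#' @param ct Ciphertext.
#' @param all_keys Named list of full key triples covering `ct$parties`.
#' @param pp Public parameters.
#' @export
mkh_decrypt_all <- function(ct, all_keys, pp) {
  shares <- lapply(ct$parties, function(id) mkh_part_dec(ct, all_keys[[id]], pp))
  mkh_fin_dec(ct, shares, pp)
}
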