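#' @useDynLib ppgc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Ring elements are numeric matrices: one row per prime factor of q, one
# column per polynomial coefficient, every entry the residue of that
# coefficient modulo the row's prime.  A plaintext polynomial (mod t) is a
# plain numeric vector of length n.

#' Zero and constant ring elements
#' @param params A `ppgc_ring_params`.
#' @return A ring element (numeric matrix).
#' @export
ring_zero <- function(params) {
  matrix(0, nrow = length(params$q_primes), ncol = params$n)
}

#' @rdname ring_zero
#' @param value Integer constant (may be negative), placed in coefficient 0.
#' @export
ring_const <- function(params, value) {
  x <- ring_zero(params)
  x[, 1] <- value %% params$q_primes
  x
}

#' Build a ring element from signed integer coefficients
#' @param coeffs Length-n integer vector (|coeffs| < 2^52).
#' @param params A `ppgc_ring_params`.
#' @export
ring_from_coeffs <- function(coeffs, params) {
  stopifnot(length(coeffs) == params$n)
  t(vapply(params$q_primes, function(p) coeffs %% p, numeric(params$n)))
}

check_elem <- function(x, params) {
  if (!is.matrix(x) || nrow(x) != length(params$q_primes) || ncol(x) != params$n) {
    stop("ring element does not conform to the parameter set")
  }
  invisible(TRUE)
}

#' Negacyclic number-theoretic transform
#'
#' Forward transform into the evaluation domain (and its inverse).  The
#' transform is the length-n NTT twisted by a primitive 2n-th root of unity,
#' so pointwise products in the evaluation domain correspond to
#' multiplication modulo `x^n + 1`.
#'
#' @param x Ring element.
#' @param params A `ppgc_ring_params`.
#' @param modulus `"q"` (default) to transform residues modulo the ciphertext
#'   primes, `"t"` to transform a length-n plaintext vector modulo t.
#' @return Same shape as the input.
#' @export
ntt_forward <- function(x, params, modulus = c("q", "t")) {
  modulus <- match.arg(modulus)
  if (modulus == "q") {
    check_elem(x, params)
    cpp_ntt(x, params$q_primes, FALSE)
  } else {
    cpp_ntt(matrix(x, nrow = 1), params$t, FALSE)[1, ]
  }
}

#' @rdname ntt_forward
#' @export
ntt_inverse <- function(x, params, modulus = c("q", "t")) {
  modulus <- match.arg(modulus)
  if (modulus == "q") {
    check_elem(x, params)
    cpp_ntt(x, params$q_primes, TRUE)
  } else {
    cpp_ntt(matrix(x, nrow = 1), params$t, TRUE)[1, ]
  }
}

#' Ring arithmetic in R_q
#'
#' Exact addition, subtraction, negation and (negacyclic NTT-based)
#' multiplication modulo `(x^n + 1, q)`.
#'
#' @param x,y Ring elements under the same `params`.
#' @param params A `ppgc_ring_params`.
#' @return A ring element.
#' @export
ring_add <- function(x, y, params) {
  check_elem(x, params); check_elem(y, params)
  cpp_mat_add(x, y, params$q_primes)
}

#' @rdname ring_add
#' @export
ring_sub <- function(x, y, params) {
  check_elem(x, params); check_elem(y, params)
  cpp_mat_sub(x, y, params$q_primes)
}

#' @rdname ring_add
#' @export
ring_neg <- function(x, params) {
  check_elem(x, params)
  cpp_mat_neg(x, params$q_primes)
}

#' @rdname ring_add
#' @export
ring_mul <- function(x, y, params) {
  check_elem(x, params); check_elem(y, params)
  cpp_negacyclic_mul(x, y, params$q_primes)
}

#' @rdname ring_add
#' @param s Integer scalar (may be negative) or per-prime residue vector.
#' @export
ring_scalar_mul <- function(x, s, params) {
  check_elem(x, params)
  cpp_scalar_mul(x, s, params$q_primes)
}

#' Randomness samplers over the ring
#'
#' `sample_error` draws each coefficient from a rounded continuous Gaussian
#' of standard deviation `sigma_err`, rejecting beyond `6 * sigma_err`.
#' `sample_key` draws ternary coefficients uniform on \{-1, 0, 1\} (the key
#' distribution).  `sample_uniform` draws a uniform element of R_q and is
#' the sampler used for the public common reference polynomials, so it is
#' reproducible from a public seed.
#'
#' All samplers are deterministic given `seed`; when `seed` is `NULL` one is
#' drawn from R's RNG stream (so `set.seed()` governs reproducibility).
#'
#' @param params A `ppgc_ring_params`.
#' @param seed Integer seed (< 2^48), or `NULL`.
#' @return A ring element.
#' @export
sample_error <- function(params, seed = NULL) {
  cpp_sample_gauss(seed %||% rand_seed(), params$sigma_err, params$n, params$q_primes)
}

#' @rdname sample_error
#' @export
sample_key <- function(params, seed = NULL) {
  cpp_sample_ternary(seed %||% rand_seed(), params$n, params$q_primes)
}

#' @rdname sample_error
#' @export
sample_uniform <- function(params, seed = NULL) {
  cpp_sample_uniform(seed %||% rand_seed(), params$q_primes, params$n)
}

#' Signed coefficients of a ring element
#'
#' Returns the centered representative of each coefficient, computed by an
#' exact lift into an auxiliary prime.  Exact whenever the centered
#' magnitude is below half that prime (about 2^45); ring elements with
#' larger coefficients are better inspected through [noise_bits_of()].
#' @param x Ring element.
#' @param params A `ppgc_ring_params`.
#' @export
ring_centered <- function(x, params) {
  check_elem(x, params)
  p_aux <- params$aux_primes[1]
  lifted <- cpp_lift(x, params$q_primes, p_aux)[1, ]
  ifelse(lifted > p_aux / 2, lifted - p_aux, lifted)
}

#' Gadget decomposition
#'
#' Writes each coefficient's canonical representative in `[0, q)` in base
#' `gadget_base`: `x = sum_j base^j * part_j (mod q)` with every digit in
#' `[0, base)`.  Used to keep noise growth additive when multiplying by
#' (noisy) key material.
#'
#' @param x Ring element.
#' @param params A `ppgc_ring_params`.
#' @return List of `gadget_digits` ring elements.
#' @export
gadget_decompose <- function(x, params) {
  check_elem(x, params)
  cpp_gadget_decompose(x, params$q_primes, as.integer(log2(params$gadget_base)),
                       params$gadget_digits)
}

#' @rdname gadget_decompose
#' @param parts List of digit ring elements.
#' @export
gadget_recompose <- function(parts, params) {
  cpp_gadget_recompose(parts, params$q_primes, as.integer(log2(params$gadget_base)))
}

#' Batching between slot vectors and plaintext polynomials
#'
#' `batch_encode` maps a length-n vector of slot values in `[0, t)` to a
#' plaintext polynomial mod t (the inverse negacyclic NTT), `batch_decode`
#' inverts it.  Slot-wise addition and multiplication mod t correspond
#' exactly to polynomial addition and multiplication mod `(x^n + 1, t)`.
#'
#' @param slots Length-n numeric vector with entries in `[0, t)`.
#' @param params A `ppgc_ring_params`.
#' @return Length-n plaintext polynomial (coefficients mod t).
#' @export
batch_encode <- function(slots, params) {
  if (length(slots) != params$n) stop("slot vector must have length n")
  if (any(slots < 0 | slots >= params$t)) stop("slot values must lie in [0, t)")
  cpp_ntt(matrix(slots, nrow = 1), params$t, TRUE)[1, ]
}

#' @rdname batch_encode
#' @param poly Length-n plaintext polynomial.
#' @export
batch_decode <- function(poly, params) {
  if (length(poly) != params$n) stop("plaintext polynomial must have length n")
  cpp_ntt(matrix(poly, nrow = 1), params$t, FALSE)[1, ]
}

#' Centered lift modulo t
#'
#' Maps residues in `[0, t)` to signed representatives in `(-t/2, t/2]`.
#' @param x Numeric vector of residues mod `t`.
#' @param t Modulus.
#' @export
center_mod <- function(x, t) {
  ifelse(x > t / 2, x - t, x)
}

#' Exact bit size of each centered coefficient
#' @param x Ring element.
#' @param params A `ppgc_ring_params`.
#' @return Length-n vector of `log2 |coefficient|` (`-Inf` for zeros).
#' @export
noise_bits_of <- function(x, params) {
  check_elem(x, params)
  cpp_noise_bits(x, params$q_primes)
}
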