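#' Ring parameter sets for the encryption scheme
#'
#' Constructs the arithmetic parameters for the polynomial ring
#' \eqn{R_q = Z_q[x]/(x^n+1)}: the ring dimension `n` (a power of two), the
#' ciphertext modulus `q` (internally a product of word-sized primes, each
#' congruent to 1 mod 2n so a negacyclic number-theoretic transform exists),
#' the plaintext modulus `t` (a prime with `t = 1 (mod 2n)` so plaintext
#' vectors can be batched into polynomial slots), the error distribution
#' width `sigma_err`, and the gadget decomposition base used by
#' relinearization keys.
#'
#' Three named profiles are provided:
#' \describe{
#'   \item{`mini`}{n = 32; a small ring for fast unit-level work. Same
#'     modulus sizes as `toy` so noise behaviour is comparable.}
#'   \item{`toy`}{n = 1024, `q` about 184 bits (four 46-bit primes),
#'     `t` the smallest prime at least 2^33 with `t = 1 (mod 2n)`. Supports
#'     two multiplicative levels with a wide margin. Not a secure parameter
#'     set; it exists to exercise correctness.}
#'   \item{`paper`}{n = 2^14, `t = 65537`, `q` of 432 bits (nine 48-bit
#'     primes), sized under the homomorphic-encryption-standard 128-bit
#'     classical bound (log2 q <= 438 at this dimension with ternary keys).}
#' }
#'
#' @param profile One of `"mini"`, `"toy"`, `"paper"`.
#' @param n,t,q_primes,aux_primes,sigma_err,gadget_base Optional overrides of
#'   the profile values. `q_primes`/`aux_primes` are vectors of distinct
#'   primes, each `= 1 (mod 2n)`; the auxiliary primes are only used
#'   internally to hold tensor products during homomorphic multiplication.
#' @return An object of class `ppgc_ring_params`.
#' @export
ring_params <- function(profile = c("toy", "mini", "paper"),
                        n = NULL, t = NULL, q_primes = NULL, aux_primes = NULL,
                        sigma_err = NULL, gadget_base = NULL) {
  profile <- match.arg(profile)
  def <- switch(profile,
    mini  = list(n = 32L,    qbits = 46, nq = 4L, naux = 6L,  t = NULL),
    toy   = list(n = 1024L,  qbits = 46, nq = 4L, naux = 6L,  t = NULL),
    paper = list(n = 16384L, qbits = 48, nq = 9L, naux = 10L, t = 65537)
  )
  n <- as.integer(n %||% def$n)
  if (n < 2 || bitwAnd(n, n - 1L) != 0L) stop("n must be a power of two")
  twon <- 2 * n
  if (is.null(q_primes)) {
    q_primes <- cpp_find_primes_below(def$qbits, twon, def$nq, numeric(0))
  }
  if (is.null(aux_primes)) {
    aux_primes <- cpp_find_primes_below(def$qbits, twon, def$naux, q_primes)
  }
  if (anyDuplicated(c(q_primes, aux_primes))) stop("q and auxiliary primes must be distinct")
  if (is.null(t)) {
    t <- def$t %||% cpp_next_prime_congruent(2^33, twon)
  }
  if (!cpp_is_prime(t)) stop("plaintext modulus t must be prime")
  if ((t - 1) %% twon != 0) stop("t must be congruent to 1 mod 2n (needed for slot batching)")
  sigma_err <- sigma_err %||% 3.2
  gadget_base <- gadget_base %||% 256
  lb <- log2(gadget_base)
  if (lb != round(lb) || lb < 1 || lb > 30) {
    stop("gadget_base must be a power of two between 2 and 2^30")
  }
  q_bits <- cpp_q_bits(q_primes)
  if (t >= prod(q_primes)) stop("t must be smaller than q")
  gadget_digits <- as.integer(ceiling(q_bits / lb))
  structure(list(
    n = n, q_primes = as.numeric(sort(q_primes, decreasing = TRUE)),
    aux_primes = as.numeric(sort(aux_primes, decreasing = TRUE)),
    t = as.numeric(t), sigma_err = sigma_err, key_dist = "ternary",
    gadget_base = as.numeric(gadget_base), gadget_digits = gadget_digits,
    q_bits = q_bits, profile = profile
  ), class = "ppgc_ring_params")
}

#' @export
print.ppgc_ring_params <- function(x, ...) {
  cat(sprintf(
    "<ppgc_ring_params> profile=%s n=%d log2(q)=%.0f t=%.0f sigma=%.2f base=2^%d digits=%d\n",
    x$profile, x$n, x$q_bits, x$t, x$sigma_err, log2(x$gadget_base), x$gadget_digits))
  invisible(x)
}

#' Validate a ring parameter object
#'
#' Checks the structural invariants: `n` a power of two, `t` a prime
#' congruent to 1 mod 2n and smaller than `q`, and the gadget digits
#' covering `q`.
#'
#' @param params A `ppgc_ring_params`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_ring_params <- function(params) {
  stopifnot(inherits(params, "ppgc_ring_params"))
  n <- params$n
  if (bitwAnd(n, n - 1L) != 0L) stop("n not a power of two")
  if (!cpp_is_prime(params$t)) stop("t not prime")
  if ((params$t - 1) %% (2 * n) != 0) stop("t != 1 mod 2n")
  if (params$q_bits <= log2(params$t)) stop("t not smaller than q")
  if (params$gadget_digits * log2(params$gadget_base) < params$q_bits) {
    stop("gadget digits do not cover q")
  }
  for (p in c(params$q_primes, params$aux_primes)) {
    if (!cpp_is_prime(p)) stop("non-prime ciphertext modulus factor")
    if ((p - 1) %% (2 * n) != 0) stop("modulus factor lacks a 2n-th root of unity")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Error tail bound of the error sampler
#'
#' Samples are rejected beyond `6 * sigma_err`, so every error coefficient
#' has magnitude at most `floor(6 * sigma_err)`.
#' @param params A `ppgc_ring_params`.
#' @return Integer bound.
#' @export
error_tail_bound <- function(params) floor(6 * params$sigma_err)

# deterministic but R-RNG-driven seed for the C++ samplers
rand_seed <- function() floor(stats::runif(1) * 2^48) + 1
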