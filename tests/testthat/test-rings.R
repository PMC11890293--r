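test_that("ring parameter profiles satisfy their invariants", {
  for (prof in c("mini", "toy")) {
    pr <- ring_params(prof)
    expect_true(validate_ring_params(pr))
    expect_true(all(pr$q_primes %% (2 * pr$n) == 1))
    expect_true(all(pr$aux_primes %% (2 * pr$n) == 1))
    expect_gt(pr$t, 2^33 - 1)
  }
  pr <- ring_params("paper")
  expect_true(validate_ring_params(pr))
  expect_identical(pr$n, 16384L)
  expect_identical(pr$t, 65537)
  expect_lte(pr$q_bits, 438) # 128-bit-classical bound at n = 2^14, ternary keys
})

test_that("invalid parameters are rejected", {
  expect_error(ring_params("mini", n = 48), "power of two")
  expect_error(ring_params("mini", t = 2^33 + 1), "prime")
  # 8589934609 is prime but 17 mod 64, so not NTT-friendly for n = 32
  expect_error(ring_params("mini", t = 8589934609), "mod 2n")
  expect_error(ring_params("mini", gadget_base = 3), "power of two")
})

test_that("ring arithmetic matches signed-integer semantics", {
  pr <- fixture_pp("mini")$ring
  set.seed(1)
  a <- sample(-50:50, pr$n, replace = TRUE)
  b <- sample(-50:50, pr$n, replace = TRUE)
  ea <- ring_from_coeffs(a, pr); eb <- ring_from_coeffs(b, pr)
  expect_equal(ring_centered(ring_add(ea, eb, pr), pr), a + b)
  expect_equal(ring_centered(ring_sub(ea, eb, pr), pr), a - b)
  expect_equal(ring_centered(ring_neg(ea, pr), pr), -a)
  expect_equal(ring_centered(ring_scalar_mul(ea, -7, pr), pr), -7 * a)
  expect_equal(ring_centered(ring_mul(ea, eb, pr), pr), schoolbook_negacyclic(a, b))
})

test_that("x^(n-1) * x = -1 in the negacyclic ring", {
  pr <- fixture_pp("mini")$ring
  xn1 <- ring_from_coeffs(c(rep(0, pr$n - 1), 1), pr)
  x <- ring_from_coeffs(c(0, 1, rep(0, pr$n - 2)), pr)
  expect_equal(ring_centered(ring_mul(xn1, x, pr), pr), c(-1, rep(0, pr$n - 1)))
})

test_that("NTT round-trips and diagonalizes multiplication", {
  pr <- fixture_pp("mini")$ring
  set.seed(2)
  a <- ring_from_coeffs(sample(-100:100, pr$n, TRUE), pr)
  expect_equal(ntt_inverse(ntt_forward(a, pr), pr), a)
  b <- ring_from_coeffs(sample(-100:100, pr$n, TRUE), pr)
  pw <- ppgc:::cpp_pointwise_mul(ntt_forward(a, pr), ntt_forward(b, pr), pr$q_primes)
  expect_equal(ntt_inverse(pw, pr), ring_mul(a, b, pr))
})

test_that("samplers are deterministic, bounded, and seed-sensitive", {
  pr <- fixture_pp("mini")$ring
  e1 <- sample_error(pr, seed = 7); e2 <- sample_error(pr, seed = 7)
  expect_identical(e1, e2)
  expect_false(identical(e1, sample_error(pr, seed = 8)))
  expect_lte(max(abs(ring_centered(e1, pr))), error_tail_bound(pr))
  k <- sample_key(pr, seed = 7)
  expect_true(all(ring_centered(k, pr) %in% -1:1))
  u1 <- sample_uniform(pr, seed = 7)
  expect_true(all(u1 >= 0) && all(u1 < pr$q_primes))
  # set.seed drives the NULL-seed path
  set.seed(99); s1 <- sample_error(pr)
  set.seed(99); s2 <- sample_error(pr)
  expect_identical(s1, s2)
})

test_that("gadget decomposition recomposes exactly and digits are bounded", {
  pr <- fixture_pp("mini")$ring
  set.seed(3)
  x <- sample_uniform(pr, seed = 31)
  parts <- gadget_decompose(x, pr)
  expect_length(parts, pr$gadget_digits)
  for (p in parts) {
    expect_true(all(ring_centered(p, pr) >= 0 &
                    ring_centered(p, pr) < pr$gadget_base))
  }
  expect_equal(gadget_recompose(parts, pr), x)
})

test_that("gadget digits of a known value are the base-256 digits", {
  pr <- fixture_pp("mini")$ring
  x <- ring_from_coeffs(c(123456789, rep(0, pr$n - 1)), pr)
  parts <- gadget_decompose(x, pr)
  d <- vapply(parts, function(p) ring_centered(p, pr)[1], numeric(1))
  expect_equal(d[1:4], c(21, 205, 91, 7)) # 123456789 = 0x075BCD15
  expect_true(all(d[-(1:4)] == 0))
})

test_that("batching is a slot-wise ring isomorphism", {
  pr <- fixture_pp("mini")$ring
  set.seed(4)
  v <- floor(runif(pr$n) * pr$t)
  w <- floor(runif(pr$n) * pr$t)
  expect_equal(batch_decode(batch_encode(v, pr), pr), v)
  pv <- batch_encode(v, pr); pw <- batch_encode(w, pr)
  expect_equal(batch_decode((pv + pw) %% pr$t, pr), (v + w) %% pr$t)
  prod_poly <- ppgc:::cpp_negacyclic_mul(matrix(pv, 1), matrix(pw, 1), pr$t)[1, ]
  expect_equal(batch_decode(prod_poly, pr), mulmod(v, w, pr$t))
})

test_that("slot payloads out of range are rejected", {
  pr <- fixture_pp("mini")$ring
  expect_error(batch_encode(rep(-1, pr$n), pr), "lie in")
  expect_error(batch_encode(rep(0, pr$n + 1), pr), "length n")
})

test_that("noise_bits_of reports exact magnitudes", {
  pr <- fixture_pp("mini")$ring
  x <- ring_from_coeffs(c(0, 1, -1024, 5, rep(0, pr$n - 4)), pr)
  nb <- noise_bits_of(x, pr)
  expect_equal(nb[1:4], c(-Inf, 0, 10, log2(5)))
})
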