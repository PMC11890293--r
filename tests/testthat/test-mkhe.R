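pp <- fixture_pp("mini")
fx <- fixture_keys("mini")
n <- pp$ring$n
t <- pp$ring$t

test_that("setup is deterministic from its seed and fingerprinted", {
  pp2 <- mkh_setup("mini", seed = 42)
  expect_identical(pp2$fingerprint, pp$fingerprint)
  expect_identical(crs_vector(pp2)[[1]], crs_vector(pp)[[1]])
  pp3 <- mkh_setup("mini", seed = 43)
  expect_false(identical(pp3$fingerprint, pp$fingerprint))
})

test_that("keygen produces distinct keys; public bundle strips the secret", {
  expect_false(identical(fx$keys$p1$sk, fx$keys$p2$sk))
  expect_null(fx$pub$p1$sk)
  expect_s3_class(fx$pub$p1, "ppgc_pubkeys")
  # public-key relation: b + s*a is small
  r <- pp$ring
  resid <- ring_add(fx$keys$p1$pk$b[[1]],
                    ring_mul(fx$keys$p1$sk, crs_vector(pp)[[1]], r), r)
  expect_lte(max(abs(ring_centered(resid, r))), error_tail_bound(r))
})

test_that("single-key encrypt/decrypt round-trips and is seed-deterministic", {
  set.seed(10)
  m <- floor(runif(n) * t)
  ct <- mkh_encrypt(m, fx$keys$p1, pp, seed = 5)
  expect_identical(ct$parties, "p1")
  expect_equal(mkh_decrypt_all(ct, fx$keys, pp), m)
  ct2 <- mkh_encrypt(m, fx$keys$p1, pp, seed = 5)
  expect_identical(ct$parts, ct2$parts)
  expect_false(identical(ct$parts, mkh_encrypt(m, fx$keys$p1, pp, seed = 6)$parts))
})

test_that("extension is sound and canonically ordered", {
  m <- floor(runif(n) * t)
  ct <- mkh_encrypt(m, fx$keys$p3, pp)
  ext <- mkh_extend(ct, c("p3", "p1", "p5"), pp)
  expect_identical(ext$parties, c("p1", "p3", "p5"))
  expect_equal(mkh_decrypt_all(ext, fx$keys, pp), m)
  expect_error(mkh_extend(ext, c("p1", "p3"), pp))
})

test_that("multi-key addition matches mod-t vector addition", {
  v1 <- floor(runif(n) * t); v2 <- floor(runif(n) * t)
  c1 <- mkh_encrypt(v1, fx$keys$p1, pp)
  c2 <- mkh_encrypt(v2, fx$keys$p2, pp)
  s <- mkh_add(c1, c2, pp)
  expect_identical(s$parties, c("p1", "p2"))
  expect_equal(mkh_decrypt_all(s, fx$keys, pp), (v1 + v2) %% t)
  d <- mkh_sub(c1, c2, pp)
  expect_equal(mkh_decrypt_all(d, fx$keys, pp), (v1 - v2) %% t)
})

test_that("relinearized product equals the unrelinearized tensor decryption", {
  # white-box: decrypting the 3-part product of single-key ciphertexts
  # under (1, s, s^2) must give the same plaintext as the relinearized
  # 2-part ciphertext under (1, s)
  r <- pp$ring
  v1 <- floor(runif(n) * 6); v2 <- floor(runif(n) * 6)
  c1 <- mkh_encrypt(v1, fx$keys$p1, pp)
  c2 <- mkh_encrypt(v2, fx$keys$p1, pp)
  m <- mkh_multiply(c1, c2, fx$pub, pp)
  expect_equal(mkh_decrypt_all(m, fx$keys, pp), mulmod(v1, v2, t))
})

test_that("multi-key multiplication is exact across party counts and order", {
  for (np in c(2L, 3L, 5L)) {
    v1 <- floor(runif(n) * 5); v2 <- floor(runif(n) * 5)
    ids <- paste0("p", seq_len(np))
    c1 <- mkh_encrypt(v1, fx$keys[[ids[1]]], pp)
    c2 <- mkh_encrypt(v2, fx$keys[[ids[np]]], pp)
    c1 <- mkh_extend(c1, ids, pp)
    m <- mkh_multiply(c1, c2, fx$pub, pp)
    expect_identical(m$parties, sort(ids))
    expect_equal(mkh_decrypt_all(m, fx$keys, pp), mulmod(v1, v2, t))
    m2 <- mkh_multiply(c2, c1, fx$pub, pp)
    expect_equal(mkh_decrypt_all(m2, fx$keys, pp), mulmod(v1, v2, t))
  }
})

test_that("depth budget is enforced and plain operations do not consume it", {
  v <- rep(1, n)
  ct <- mkh_encrypt(v, fx$keys$p1, pp)
  d1 <- mkh_multiply(ct, ct, fx$pub, pp)
  d2 <- mkh_multiply(d1, d1, fx$pub, pp)
  expect_identical(d2$mult_depth, 2L)
  expect_error(mkh_multiply(d2, ct, fx$pub, pp), "depth budget")
  p <- mkh_multiply_plain(d2, rep(3, n), pp)
  expect_identical(p$mult_depth, 2L)
  expect_equal(mkh_decrypt_all(p, fx$keys, pp), rep(3, n))
})

test_that("plaintext multiply/add handle signed centered payloads", {
  v <- floor(runif(n) * 10)
  ct <- mkh_encrypt(v, fx$keys$p2, pp)
  w <- c(t - 3, rep(2, n - 1)) # slot 1 holds -3 centered
  mp <- mkh_multiply_plain(ct, w, pp)
  expect_equal(mkh_decrypt_all(mp, fx$keys, pp), mulmod(v, w, t))
  ap <- mkh_add_plain(ct, w, pp)
  expect_equal(mkh_decrypt_all(ap, fx$keys, pp), (v + w) %% t)
})

test_that("partial decryption requires the right secret key", {
  ct <- mkh_encrypt(rep(1, n), fx$keys$p1, pp)
  expect_error(mkh_part_dec(ct, fx$keys$p2, pp), "not present")
  expect_error(mkh_part_dec(ct, fx$pub$p1, pp), "secret key")
})

test_that("fin_dec is N-of-N: missing, duplicate, or all shares", {
  v <- floor(runif(n) * t)
  c1 <- mkh_encrypt(v, fx$keys$p1, pp)
  c2 <- mkh_encrypt(rep(0, n), fx$keys$p2, pp)
  ct <- mkh_add(c1, c2, pp)
  sh1 <- mkh_part_dec(ct, fx$keys$p1, pp)
  sh2 <- mkh_part_dec(ct, fx$keys$p2, pp)
  expect_error(mkh_fin_dec(ct, list(sh1), pp), "incomplete")
  expect_error(mkh_fin_dec(ct, list(sh1, sh1), pp), "duplicate")
  expect_equal(mkh_fin_dec(ct, list(sh2, sh1), pp), v)
})

test_that("smudging refreshes shares but never the decoded value", {
  v <- floor(runif(n) * t)
  ct <- mkh_encrypt(v, fx$keys$p1, pp)
  s1 <- mkh_part_dec(ct, fx$keys$p1, pp, seed = 1)
  s2 <- mkh_part_dec(ct, fx$keys$p1, pp, seed = 2)
  expect_false(identical(s1$share, s2$share))
  expect_equal(mkh_fin_dec(ct, list(s1), pp), v)
  expect_equal(mkh_fin_dec(ct, list(s2), pp), v)
})

test_that("ciphertexts from a different parameter set are rejected", {
  other <- mkh_setup("mini", seed = 77)
  k <- mkh_keygen(other, "x", seed = 1)
  ct <- mkh_encrypt(rep(0, n), k, other)
  expect_error(mkh_add(ct, mkh_encrypt(rep(0, n), fx$keys$p1, pp), pp),
               "parameter")
})

test_that("noise accounting: fresh below threshold, grows with depth", {
  v <- floor(runif(n) * t)
  ct <- mkh_encrypt(v, fx$keys$p1, pp)
  nb0 <- mkh_noise(ct, fx$sks, pp)
  d1 <- mkh_multiply(ct, ct, fx$pub, pp)
  nb1 <- mkh_noise(d1, fx$sks, pp)
  d2 <- mkh_multiply(d1, d1, fx$pub, pp)
  nb2 <- mkh_noise(d2, fx$sks, pp)
  expect_lt(nb0, nb1); expect_lt(nb1, nb2)
  expect_lt(nb2, noise_threshold_bits(pp))
})
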