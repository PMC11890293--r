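pp <- fixture_pp("mini")
fx <- fixture_keys("mini")
n <- pp$ring$n
t <- pp$ring$t

test_that("pm oracle reproduces the published formula on hand cases", {
  expect_equal(pm_risk_plain(1, pm_spec(1, 0.75)), 0.75)
  expect_equal(pm_risk_plain(0, pm_spec(1, 0.75)), 0.25)
  expect_equal(pm_risk_plain(c(1, 0, 1), pm_spec(c(1, 2, 1), c(0.9, 0.5, 0.1))), 0.5)
  expect_error(pm_risk_plain(2, pm_spec(1, 0.5)), "presence bits")
  expect_equal(snp_presence(c(0, 1, 2)), c(0L, 1L, 1L))
})

test_that("pm circuit: depth 0, oracle match, degenerate cases", {
  set.seed(20)
  L <- 16
  spec <- pm_spec(runif(L, 0.1, 3), runif(L, 0.05, 0.95))
  g <- sample(0:1, L, TRUE)
  ct <- mkh_encrypt(pad_n(g, n), fx$keys$p1, pp)
  out <- pm_risk_circuit(ct, spec, pp)
  expect_identical(out$mult_depth, 0L)
  res <- pm_score(mkh_decrypt_all(out, fx$keys, pp), spec, pp)
  expect_lte(abs(res$score - pm_risk_plain(g, spec)), 2 / spec$scale_F)
  # all probs 1/2 -> score 1/2 regardless of genotype
  sp5 <- pm_spec(runif(L, 0.1, 3), rep(0.5, L))
  out5 <- pm_risk_circuit(ct, sp5, pp)
  r5 <- pm_score(mkh_decrypt_all(out5, fx$keys, pp), sp5, pp)
  expect_lte(abs(r5$score - 0.5), 2 / sp5$scale_F)
  # zero-weight SNPs contribute nothing
  spz <- pm_spec(c(spec$weights[1:8], rep(0, 8)), spec$probs)
  expect_equal(pm_risk_plain(g, spz),
               sum(spz$weights[1:8] * (spec$probs^g * (1 - spec$probs)^(1 - g))[1:8]) /
                 sum(spz$weights))
})

test_that("paternity oracle matches hand-evaluated loci", {
  spec1 <- paternity_spec(K = 1, locus_names = "L1")
  prof <- function(a1, a2) data.frame(locus = "L1", allele1 = a1, allele2 = a2)
  expect_equal(paternity_plain(prof(12, 14), prof(14, 17), spec1)$numerator, 0)
  expect_equal(paternity_plain(prof(12, 14), prof(15, 17), spec1)$numerator, 45)
  expect_error(paternity_plain(prof(1, 2), data.frame(locus = "L2", allele1 = 1, allele2 = 2), spec1),
               "missing loci")
})

test_that("paternity circuit: exactness, twin identity, hand value", {
  spec <- paternity_spec()
  pop <- gen_str_population(2, spec, seed = 21)
  a <- str_profile(pop, "S0001"); b <- str_profile(pop, "S0002")
  enc <- function(prof, keys) {
    ax <- str_alleles(prof, spec)
    list(a1 = mkh_encrypt(pad_n(ax$a1, n), keys, pp),
         a2 = mkh_encrypt(pad_n(ax$a2, n), keys, pp))
  }
  ca <- enc(a, fx$keys$p1); cb <- enc(b, fx$keys$p2)
  res <- paternity_circuit(ca, cb, spec, fx$pub, pp)
  expect_identical(res$mult_depth, 2L)
  sc <- paternity_score(mkh_decrypt_all(res, fx$keys, pp), spec, pp)
  oracle <- paternity_plain(a, b, spec)
  expect_equal(sc$raw_slots, oracle$raw_slots)
  expect_equal(sc$score, oracle$score)
  # identical twin vs self: all slots zero
  cself <- enc(a, fx$keys$p2)
  rr <- paternity_circuit(ca, cself, spec, fx$pub, pp)
  expect_true(all(paternity_score(mkh_decrypt_all(rr, fx$keys, pp), spec, pp)$raw_slots == 0))
})

test_that("paternity exactness bound on t is enforced", {
  big <- paternity_spec(allele_range = c(5, 5000))
  expect_error(check_paternity_bound(big, pp), "too small")
})

test_that("abs interpolation is exact on its domain", {
  expect_equal(center_mod(eval_even_poly(abs_interp_coeffs(1, t), -1:1, t), t),
               c(1, 0, 1)) # r=1: p(d) = d^2
  co2 <- abs_interp_coeffs(2, t)
  expect_equal(center_mod(eval_even_poly(co2, -2:2, t), t), c(2, 1, 0, 1, 2))
  # r=2 closed form: 6^{-1} (7 d^2 - d^4)
  inv6 <- ppgc:::cpp_invmod(6, t)
  expect_equal(co2, c(0, mulmod(inv6, 7, t), mulmod(inv6, t - 1, t)))
})

test_that("sps oracle and circuit agree exactly, including caps", {
  expect_equal(sps_plain(c(0, 2, 1), c(2, 2, 0), sps_spec(3, 2))$score, 1)
  expect_equal(sps_plain(c(0, 2), c(2, 0), sps_spec(2, 0))$score, 0)
  expect_error(sps_plain(c(0, 3), c(0, 0), sps_spec(2)), "0,1,2")
  set.seed(22)
  for (cap in 0:2) {
    spec <- sps_spec(L = 20, cap_c = cap)
    a <- sample(0:2, 20, TRUE); b <- sample(0:2, 20, TRUE)
    ca <- mkh_encrypt(pad_n(a, n), fx$keys$p1, pp)
    cb <- mkh_encrypt(pad_n(b, n), fx$keys$p2, pp)
    out <- sps_circuit(ca, cb, spec, fx$pub, pp)
    expect_identical(out$mult_depth, 2L)
    sc <- sps_score(mkh_decrypt_all(out, fx$keys, pp), spec, pp)
    oracle <- sps_plain(a, b, spec)
    expect_equal(sc$raw_slots, oracle$raw_slots)
    expect_equal(sc$score, oracle$score)
  }
})

test_that("levenshtein oracle matches textbook values and utils::adist", {
  expect_equal(linkage_plain_levenshtein("kitten", "sitting")$numerator, 3)
  expect_equal(linkage_plain_levenshtein("kitten", "sitting")$score, 3 / 7)
  expect_equal(linkage_plain_levenshtein("abc", "abc")$numerator, 0)
  expect_equal(linkage_plain_levenshtein("abcde", "")$numerator, 5)
  set.seed(23)
  spec <- linkage_spec(alphabet = letters[1:5], pad_len = 8)
  for (i in 1:20) {
    a <- paste(sample(letters[1:5], sample(1:8, 1), TRUE), collapse = "")
    b <- paste(sample(letters[1:5], sample(1:8, 1), TRUE), collapse = "")
    expect_equal(linkage_plain_levenshtein(a, b)$numerator,
                 as.numeric(utils::adist(a, b)))
  }
})

test_that("one-hot encoding and the linkage circuit", {
  spec <- linkage_spec(alphabet = c("a", "b", "c", "d"), pad_len = 8)
  bits <- one_hot_record("ab", spec)
  expect_length(bits, 32)
  expect_equal(sum(bits), 8) # every padded position has exactly one bit
  expect_error(one_hot_record("xyz", spec), "outside the alphabet")
  expect_error(one_hot_record(strrep("a", 9), spec), "pad_len")
  a <- "abcadbca"; b <- "abdadbca" # one substitution
  ca <- mkh_encrypt(pad_n(one_hot_record(a, spec), n), fx$keys$p1, pp)
  cb <- mkh_encrypt(pad_n(one_hot_record(b, spec), n), fx$keys$p2, pp)
  out <- linkage_circuit(ca, cb, spec, fx$pub, pp)
  expect_identical(out$mult_depth, 1L)
  sc <- linkage_score(mkh_decrypt_all(out, fx$keys, pp), spec, pp)
  expect_equal(sc$score, linkage_plain_hamming(a, b, spec)$score)
  expect_equal(sc$score, 1 / 8)
  # identical records -> 0; disjoint symbols -> 1
  expect_equal(linkage_plain_hamming(a, a, spec)$score, 0)
  expect_equal(linkage_plain_hamming(strrep("a", 8), strrep("b", 8), spec)$score, 1)
})

test_that("zero-sum masking preserves aggregates and randomizes slots", {
  set.seed(24)
  spec <- paternity_spec()
  pop <- gen_str_population(2, spec, seed = 25)
  a <- str_profile(pop, "S0001"); b <- str_profile(pop, "S0002")
  ax <- str_alleles(a, spec); bx <- str_alleles(b, spec)
  ca <- list(a1 = mkh_encrypt(pad_n(ax$a1, n), fx$keys$p1, pp),
             a2 = mkh_encrypt(pad_n(ax$a2, n), fx$keys$p1, pp))
  cb <- list(a1 = mkh_encrypt(pad_n(bx$a1, n), fx$keys$p2, pp),
             a2 = mkh_encrypt(pad_n(bx$a2, n), fx$keys$p2, pp))
  ct <- paternity_circuit(ca, cb, spec, fx$pub, pp)
  plainr <- paternity_score(mkh_decrypt_all(ct, fx$keys, pp), spec, pp)
  m1 <- mask_zero_sum(ct, seq_len(spec$K), pp, seed = 1)
  m2 <- mask_zero_sum(ct, seq_len(spec$K), pp, seed = 2)
  s1 <- paternity_score(mkh_decrypt_all(m1, fx$keys, pp), spec, pp)
  s2 <- paternity_score(mkh_decrypt_all(m2, fx$keys, pp), spec, pp)
  expect_equal(s1$numerator, plainr$numerator)
  expect_equal(s2$numerator, plainr$numerator)
  expect_false(identical(s1$raw_slots, s2$raw_slots))
  # single active slot stays untouched
  m3 <- mask_zero_sum(ct, 1L, pp, seed = 3)
  expect_equal(center_mod(mkh_decrypt_all(m3, fx$keys, pp), t)[1],
               plainr$raw_slots[1])
})

test_that("test spec JSON round-trips", {
  tmp <- withr::local_tempfile(fileext = ".json")
  sp <- pm_spec(c(rs1 = 1.5, rs2 = 0.25), c(0.3, 0.7))
  write_test_spec_json(sp, tmp)
  back <- read_test_spec_json(tmp)
  expect_equal(unname(back$weights), unname(sp$weights))
  expect_equal(back$probs, sp$probs)
  for (sp2 in list(paternity_spec(), sps_spec(10, 1),
                   linkage_spec(letters[1:6], 9))) {
    write_test_spec_json(sp2, tmp)
    expect_equal(read_test_spec_json(tmp), sp2)
  }
})

test_that("scored results export to JSON", {
  tmp <- withr::local_tempfile(fileext = ".json")
  r <- sps_plain(c(0, 1), c(2, 1), sps_spec(2))
  write_result_json(r, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$score, r$score)
  expect_null(back$raw_slots)
  write_result_json(r, tmp, raw_slots = TRUE)
  expect_equal(jsonlite::read_json(tmp, simplifyVector = TRUE)$raw_slots, r$raw_slots)
})
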