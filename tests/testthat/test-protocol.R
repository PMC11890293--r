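# End-to-end protocol behaviour at mini parameters.

make_paternity_session <- function(seed = 11, masking = TRUE) {
  s <- protocol_session("mini", config = list(masking = masking))
  run_setup_and_keygen(s, c("alice", "bob"), seed = seed)
  spec <- paternity_spec()
  pop <- gen_str_population(3, spec, seed = seed + 1)
  father <- str_profile(pop, "S0001")
  child <- gen_child(str_profile(pop, "S0002"), father, spec, seed = seed + 2)
  sequence_and_encrypt(s, "alice", child, "str", spec = spec)
  sequence_and_encrypt(s, "bob", father, "str", spec = spec)
  list(s = s, spec = spec, child = child, father = father, pop = pop)
}

test_that("setup and keygen: distinct keys, shared pp, late join, duplicates", {
  s <- protocol_session("mini")
  run_setup_and_keygen(s, c("a", "b"), seed = 1)
  expect_false(identical(s$parties$a$keys$sk, s$parties$b$keys$sk))
  expect_identical(s$parties$a$keys$fingerprint, s$pp$fingerprint)
  expect_error(run_setup_and_keygen(s, "a", seed = 2), "duplicate party id")
  # deterministic public material
  s2 <- protocol_session("mini")
  run_setup_and_keygen(s2, c("a", "b"), seed = 1)
  expect_identical(s2$spu$pubkeys$a$pk$b[[1]], s$spu$pubkeys$a$pk$b[[1]])
  # late join uses the published pp
  run_setup_and_keygen(s, "late", seed = 3)
  expect_identical(s$parties$late$keys$fingerprint, s$pp$fingerprint)
  expect_length(s$spu$pubkeys, 3)
})

test_that("sequence_and_encrypt stores ciphertexts only; round-trips via decryption", {
  s <- protocol_session("mini", config = list(masking = FALSE))
  run_setup_and_keygen(s, "owner", seed = 21)
  g <- c(0, 1, 2, 1, 0, 2, 1, 1)
  sequence_and_encrypt(s, "owner", g, "snp")
  prof <- s$spu$profiles[["owner/default"]]
  expect_named(prof$cts, c("genotype", "presence"))
  slots <- mkh_decrypt_all(prof$cts$genotype, list(owner = s$parties$owner$keys), s$pp)
  expect_equal(slots[seq_along(g)], g)
  expect_equal(nrow(scan_spu_store(s)), 0)
  expect_error(sequence_and_encrypt(s, "ghost", g, "snp"), "unregistered party")
  expect_error(sequence_and_encrypt(s, "owner", c(0, 3), "snp"), "0,1,2")
})

test_that("a single party cannot decrypt another party's stored profile", {
  s <- protocol_session("mini")
  run_setup_and_keygen(s, c("a", "b"), seed = 31)
  sequence_and_encrypt(s, "a", c(1, 2, 0), "snp")
  ct <- s$spu$profiles[["a/default"]]$cts$genotype
  # b's share is not even accepted; and using b's key via the white-box
  # decryptor yields garbage, not the plaintext
  expect_error(mkh_part_dec(ct, s$parties$b$keys, s$pp), "not present")
  wrong <- ppgc:::decrypt_with_sks(ct, list(a = s$parties$b$keys$sk), s$pp)
  wrong_slots <- batch_decode(ppgc:::cpp_decrypt_scale(wrong, s$pp$ring$q_primes,
                                                       s$pp$ring$t), s$pp$ring)
  expect_false(all(wrong_slots[1:3] == c(1, 2, 0)))
})

test_that("paternity end-to-end: masked aggregate equals oracle; result only at querier", {
  ps <- make_paternity_session()
  q <- test_query("paternity", "alice", c("alice", "bob"), ps$spec, test_id = "T1")
  run_encrypted_test(ps$s, q)
  stored <- ps$s$spu$tests$T1
  expect_identical(sort(stored$cts[[1]]$parties), c("alice", "bob"))
  res <- run_decryption(ps$s, "T1")
  oracle <- paternity_plain(ps$child, ps$father, ps$spec)
  expect_equal(res$numerator, oracle$numerator)
  expect_equal(res$score, 0)
  expect_identical(ps$s$parties$alice$results$T1, res)
  expect_null(ps$s$parties$bob$results$T1)
  # masking hid the per-slot values
  expect_false(identical(res$raw_slots, oracle$raw_slots))
})

test_that("pm query over one party yields a single-key ciphertext", {
  s <- protocol_session("mini", config = list(masking = FALSE))
  run_setup_and_keygen(s, "pat", seed = 41)
  spec <- pm_spec(runif(10, 0.5, 2), runif(10, 0.1, 0.9))
  g <- sample(0:2, 10, TRUE)
  sequence_and_encrypt(s, "pat", g, "snp")
  q <- test_query("pm", "pat", "pat", spec, test_id = "PM1")
  run_encrypted_test(s, q)
  expect_identical(s$spu$tests$PM1$cts[[1]]$parties, "pat")
  res <- run_decryption(s, "PM1")
  expect_lte(abs(res$score - pm_risk_plain(snp_presence(g), spec)), 2 / spec$scale_F)
})

test_that("sps database query returns per-pair scores matching oracles", {
  s <- protocol_session("mini", config = list(masking = TRUE))
  ids <- c("q", "d1", "d2", "d3")
  run_setup_and_keygen(s, ids, seed = 51)
  spec <- sps_spec(12, cap_c = 2)
  geno <- lapply(seq_along(ids), function(i) {
    set.seed(500 + i); sample(0:2, 12, TRUE)
  })
  for (i in seq_along(ids)) sequence_and_encrypt(s, ids[i], geno[[i]], "snp")
  q <- test_query("sps", "q", ids, spec, test_id = "S1")
  run_encrypted_test(s, q)
  res <- run_decryption(s, "S1")
  expect_named(res, c("d1", "d2", "d3"))
  for (i in 2:4) {
    expect_equal(res[[ids[i]]]$numerator,
                 sps_plain(geno[[1]], geno[[i]], spec)$numerator)
  }
})

test_that("linkage query end-to-end", {
  s <- protocol_session("mini")
  run_setup_and_keygen(s, c("ra", "rb"), seed = 61)
  spec <- linkage_spec(alphabet = letters[1:4], pad_len = 8)
  sequence_and_encrypt(s, "ra", "abcd", "record", spec = spec)
  sequence_and_encrypt(s, "rb", "abdd", "record", spec = spec)
  q <- test_query("linkage", "ra", c("ra", "rb"), spec, test_id = "L1")
  run_encrypted_test(s, q)
  res <- run_decryption(s, "L1")
  expect_equal(res$score, linkage_plain_hamming("abcd", "abdd", spec)$score)
})

test_that("N-of-N: withholding any share refuses output; full set succeeds", {
  ps <- make_paternity_session(seed = 71)
  q <- test_query("paternity", "alice", c("alice", "bob"), ps$spec, test_id = "T2")
  run_encrypted_test(ps$s, q)
  expect_error(run_decryption(ps$s, "T2", .withhold = "bob"), "incomplete decryption")
  expect_error(run_decryption(ps$s, "T2", .withhold = "alice"), "incomplete decryption")
  res <- run_decryption(ps$s, "T2")
  expect_equal(res$numerator, paternity_plain(ps$child, ps$father, ps$spec)$numerator)
})

test_that("consent allow-list refuses unauthorized queriers", {
  s <- protocol_session("mini")
  run_setup_and_keygen(s, c("owner", "friend", "stranger"), seed = 81)
  sequence_and_encrypt(s, "owner", c(1, 0, 2), "snp", consent = "friend")
  spec <- sps_spec(3)
  sequence_and_encrypt(s, "friend", c(1, 1, 1), "snp")
  sequence_and_encrypt(s, "stranger", c(2, 0, 0), "snp")
  qs <- test_query("sps", "stranger", c("stranger", "owner"), spec, test_id = "X1")
  expect_error(run_encrypted_test(s, qs), "access refused")
  qf <- test_query("sps", "friend", c("friend", "owner"), spec, test_id = "X2")
  expect_silent(run_encrypted_test(s, qf))
})

test_that("withdrawal removes a party's material and is idempotent", {
  ps <- make_paternity_session(seed = 91)
  s <- ps$s
  run_setup_and_keygen(s, "carol", seed = 92)
  sequence_and_encrypt(s, "carol", c(1, 1), "snp")
  withdraw(s, "bob")
  expect_null(s$spu$profiles[["bob/default"]])
  expect_null(s$spu$pubkeys$bob)
  # other parties' data untouched
  expect_false(is.null(s$spu$profiles[["alice/default"]]))
  expect_false(is.null(s$spu$profiles[["carol/default"]]))
  q <- test_query("paternity", "alice", c("alice", "bob"), ps$spec, test_id = "T3")
  expect_error(run_encrypted_test(s, q), "withdrawn")
  expect_warning(withdraw(s, "bob"), "already withdrawn")
  expect_error(withdraw(s, "nobody"), "unregistered party")
})

test_that("flush_spu_cache clears evaluated tests", {
  ps <- make_paternity_session(seed = 95)
  q <- test_query("paternity", "alice", c("alice", "bob"), ps$spec, test_id = "T4")
  run_encrypted_test(ps$s, q)
  expect_length(ps$s$spu$tests, 1)
  flush_spu_cache(ps$s)
  expect_length(ps$s$spu$tests, 0)
  expect_error(run_decryption(ps$s, "T4"), "no evaluated test")
})

test_that("transcript scanner: clean on honest runs, fires on planted leaks", {
  ps <- make_paternity_session(seed = 99)
  q <- test_query("paternity", "alice", c("alice", "bob"), ps$spec, test_id = "T5")
  run_encrypted_test(ps$s, q)
  run_decryption(ps$s, "T5")
  expect_equal(nrow(scan_transcript(ps$s)), 0)
  expect_equal(nrow(scan_spu_store(ps$s)), 0)
  # plant a secret key
  ps$s$transcript[[length(ps$s$transcript) + 1]] <-
    list(from = "alice", to = "SPU", type = "oops",
         payload = list(deep = list(k = ps$s$parties$alice$keys$sk)))
  f <- scan_transcript(ps$s)
  expect_gt(nrow(f), 0)
  expect_true(any(f$matched == "secret_key"))
  ps$s$transcript[[length(ps$s$transcript)]] <- NULL
  # plant a plaintext payload
  ps$s$transcript[[length(ps$s$transcript) + 1]] <-
    list(from = "CI", to = "SPU", type = "oops2",
         payload = ps$s$secrets$plaintexts[[1]])
  f2 <- scan_transcript(ps$s)
  expect_true(any(f2$matched == "plaintext_payload"))
})

test_that("artifact serialization round-trips and guards misuse", {
  pp <- fixture_pp("mini")
  fx <- fixture_keys("mini")
  tmp <- withr::local_tempfile(fileext = ".rds")
  ct <- mkh_encrypt(rep(1, pp$ring$n), fx$keys$p1, pp)
  ppgc_save(ct, tmp)
  back <- ppgc_load(tmp, pp)
  expect_equal(back$parts, ct$parts)
  expect_error(ppgc_save(fx$keys$p1, tmp), "refusing to serialize a secret key")
  ppgc_save(fx$keys$p1, tmp, allow_secret = TRUE)
  expect_identical(ppgc_load(tmp, pp)$sk, fx$keys$p1$sk)
  ppgc_save(fx$pub$p2, tmp)
  expect_s3_class(ppgc_load(tmp, pp), "ppgc_pubkeys")
  other <- mkh_setup("mini", seed = 1234)
  ppgc_save(ct, tmp)
  expect_error(ppgc_load(tmp, other), "different parameter set")
  saveRDS(list(1, 2), tmp)
  expect_error(ppgc_load(tmp), "not a protocol artifact")
})
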