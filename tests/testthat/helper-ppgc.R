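# Shared fixtures.  Parameter setup and key generation are the expensive
# steps, so one mini-profile deployment and one toy-profile deployment are
# built lazily and shared across test files.

.fixtures <- new.env(parent = emptyenv())

fixture_pp <- function(profile = "mini") {
  key <- paste0("pp_", profile)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- mkh_setup(profile, seed = 42)
  }
  .fixtures[[key]]
}

# Five parties p1..p5 with full key triples, plus their public bundles.
fixture_keys <- function(profile = "mini") {
  key <- paste0("keys_", profile)
  if (is.null(.fixtures[[key]])) {
    pp <- fixture_pp(profile)
    ids <- paste0("p", 1:5)
    keys <- lapply(seq_along(ids), function(i) mkh_keygen(pp, ids[i], seed = 1000 + i))
    names(keys) <- ids
    .fixtures[[key]] <- list(keys = keys, pub = lapply(keys, public_bundle),
                             sks = lapply(keys, function(k) k$sk))
  }
  .fixtures[[key]]
}

pad_n <- function(v, n) c(v, rep(0, n - length(v)))

mulmod <- function(a, b, t) ppgc:::cpp_mulmod_vec(a, b, t)

# Exact schoolbook negacyclic convolution oracle over small signed
# coefficients (|a_i|, |b_i| small enough that double arithmetic is exact).
schoolbook_negacyclic <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k <- i + j - 2
    if (k < n) out[k + 1] <- out[k + 1] + a[i] * b[j]
    else out[k - n + 1] <- out[k - n + 1] - a[i] * b[j]
  }
  out
}

# Random homomorphic circuit of multiplicative depth <= the budget,
# evaluated in parallel on ciphertexts and on the slot-wise plaintext
# oracle (mod t).  Returns the final node; exactness of the decryption is
# the property under test.
rand_circuit <- function(pp, fx, n_parties, n_ops = sample(2:6, 1), value_max = 4) {
  n <- pp$ring$n; t <- pp$ring$t
  ids <- names(fx$keys)[seq_len(n_parties)]
  leaf <- function() {
    v <- floor(stats::runif(n) * (value_max + 1))
    id <- sample(ids, 1)
    list(ct = mkh_encrypt(v, fx$keys[[id]], pp), pt = v)
  }
  node <- leaf()
  for (i in seq_len(n_ops)) {
    op <- sample(c("add", "sub", "mult", "mult", "mplain", "aplain"), 1)
    if (op == "mult" && node$ct$mult_depth >= pp$depth_budget) op <- "add"
    node <- switch(op,
      add = { o <- leaf(); list(ct = mkh_add(node$ct, o$ct, pp), pt = (node$pt + o$pt) %% t) },
      sub = { o <- leaf(); list(ct = mkh_sub(node$ct, o$ct, pp), pt = (node$pt - o$pt) %% t) },
      mult = { o <- leaf(); list(ct = mkh_multiply(node$ct, o$ct, fx$pub, pp),
                                 pt = mulmod(node$pt, o$pt, t)) },
      mplain = { # constant slot vector: encodes to one small coefficient,
                 # so it is noise-safe at any depth
                 w <- rep(sample(0:3, 1), n)
                 list(ct = mkh_multiply_plain(node$ct, w, pp), pt = mulmod(node$pt, w, t)) },
      aplain = { w <- floor(stats::runif(n) * 3)
                 list(ct = mkh_add_plain(node$ct, w, pp), pt = (node$pt + w) %% t) })
  }
  node
}

decrypt_all_parties <- function(ct, fx, pp) {
  mkh_decrypt_all(ct, fx$keys, pp)
}
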