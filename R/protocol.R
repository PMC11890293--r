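# Four-role protocol orchestration: a key authority (KA) generates public
# parameters, a certified institution (CI) sequences and encrypts genomic
# profiles, a storage and processing unit (SPU) stores ciphertexts and
# evaluates test circuits, and the data owners/queriers hold their own key
# triples and partially decrypt.  All roles run in-process and communicate
# through a recorded message bus, so the complete transcript can be
# audited: no message other than the final querier delivery may contain
# plaintext genotype values or secret keys.

#' Create a protocol session
#'
#' A session holds the shared state of one protocol deployment: the public
#' parameters (once the key authority has run setup), the SPU store, the
#' registered parties, the message transcript, and the configuration.
#'
#' @param profile Parameter profile (see [ring_params()]).
#' @param config List: `masking` (apply zero-sum masking before release,
#'   default `TRUE`), `encrypt_by` (`"ci"`: the certified institution
#'   encrypts on behalf of the party; `"party"`: the owner encrypts via an
#'   interface — the ciphertexts are identical, only the sending role
#'   differs).
#' @return A `ppgc_session` environment.
#' @export
protocol_session <- function(profile = "toy",
                             config = list(masking = TRUE, encrypt_by = "ci")) {
  s <- new.env(parent = emptyenv())
  s$profile <- profile
  s$config <- utils::modifyList(list(masking = TRUE, encrypt_by = "ci"), config)
  if (!s$config$encrypt_by %in% c("ci", "party")) {
    stop("config$encrypt_by must be 'ci' or 'party'")
  }
  s$pp <- NULL
  s$parties <- list()      # id -> env(id, keys, results, withdrawn)
  s$spu <- new.env(parent = emptyenv())
  s$spu$pubkeys <- list()  # id -> public bundle
  s$spu$profiles <- list() # "party/profile" -> stored encrypted profile
  s$spu$tests <- list()    # test_id -> evaluated record (flushable cache)
  s$transcript <- list()
  s$secrets <- list(sks = list(), plaintexts = list())
  class(s) <- "ppgc_session"
  s
}

#' @export
print.ppgc_session <- function(x, ...) {
  cat(sprintf("<ppgc_session> profile=%s parties=%d profiles=%d tests=%d messages=%d\n",
              x$profile, length(x$parties), length(x$spu$profiles),
              length(x$spu$tests), length(x$transcript)))
  invisible(x)
}

bus_send <- function(session, from, to, type, payload) {
  session$transcript[[length(session$transcript) + 1]] <-
    list(from = from, to = to, type = type, payload = payload)
  invisible(payload)
}

get_party <- function(session, id, allow_withdrawn = FALSE) {
  p <- session$parties[[id]]
  if (is.null(p)) stop("unregistered party: ", id)
  if (!allow_withdrawn && isTRUE(p$withdrawn)) stop("party has withdrawn: ", id)
  p
}

note_secret <- function(session, kind, value) {
  session$secrets[[kind]][[length(session$secrets[[kind]]) + 1]] <- value
  invisible(NULL)
}

#' Setup and key generation (Algorithm 1)
#'
#' The key authority generates the public parameters (first call only;
#' later calls reuse them, which is what lets parties join dynamically
#' after deployment), each named party generates its own key triple
#' locally, and registers the public and evaluation keys at the SPU.
#' Secret keys never leave the party.
#'
#' @param session A `ppgc_session`.
#' @param party_ids Character vector of new party identifiers.
#' @param seed Integer seed; drives both setup (first call) and the
#'   per-party key generation deterministically.
#' @return The session, invisibly.
#' @export
run_setup_and_keygen <- function(session, party_ids, seed = NULL) {
  stopifnot(inherits(session, "ppgc_session"))
  if (anyDuplicated(party_ids)) stop("duplicate party id in request")
  seed <- seed %||% rand_seed()
  if (is.null(session$pp)) {
    session$pp <- mkh_setup(session$profile, seed = seed)
    bus_send(session, "KA", "*", "public_params", session$pp)
  }
  for (i in seq_along(party_ids)) {
    id <- party_ids[i]
    if (!is.null(session$parties[[id]])) stop("duplicate party id: ", id)
    keys <- mkh_keygen(session$pp, id, seed = seed * 131 + i)
    p <- new.env(parent = emptyenv())
    p$id <- id; p$keys <- keys; p$results <- list(); p$withdrawn <- FALSE
    session$parties[[id]] <- p
    note_secret(session, "sks", keys$sk)
    bundle <- public_bundle(keys)
    bus_send(session, id, "SPU", "register_keys", bundle)
    session$spu$pubkeys[[id]] <- bundle
  }
  invisible(session)
}

profile_key <- function(party_id, profile_id) paste(party_id, profile_id, sep = "/")

# "Sequencing" is mocked as parsing + validating the raw profile; it
# yields the slot payloads that get encrypted.
sequence_profile <- function(raw_profile, kind, spec, n) {
  switch(kind,
    snp = {
      g <- if (is.data.frame(raw_profile)) {
        if (!"genotype" %in% names(raw_profile)) {
          stop("malformed SNP profile: no 'genotype' column")
        }
        as.numeric(raw_profile$genotype)
      } else as.numeric(raw_profile)
      check_genotypes(g)
      if (length(g) > n) stop("profile has more variants than available slots")
      list(genotype = pad_slots(g, n), presence = pad_slots(snp_presence(g), n))
    },
    str = {
      stopifnot(inherits(spec, "ppgc_paternity_spec"))
      ax <- str_alleles(raw_profile, spec)
      rng <- spec$allele_range
      if (any(c(ax$a1, ax$a2) < rng[1] | c(ax$a1, ax$a2) > rng[2])) {
        stop("allele repeat count outside the configured range [",
             rng[1], ", ", rng[2], "]")
      }
      list(a1 = pad_slots(ax$a1, n), a2 = pad_slots(ax$a2, n))
    },
    record = {
      stopifnot(inherits(spec, "ppgc_linkage_spec"))
      list(bits = pad_slots(one_hot_record(raw_profile, spec), n))
    },
    stop("unknown profile kind: ", kind)
  )
}

#' Sequence and encrypt a genomic profile (Algorithm 2)
#'
#' Validates the raw profile ("sequencing" is mocked as parsing), encrypts
#' the slot payloads under the owning party's public key — by the CI or by
#' the party itself per the session config — and stores the ciphertexts at
#' the SPU under `(party_id, profile_id)`.  The raw plaintext never
#' crosses the message bus: the sequencing role holds it locally and only
#' ciphertexts are sent.
#'
#' @param session A `ppgc_session`.
#' @param party_id Owning party.
#' @param raw_profile The raw data: a long-format SNP data frame (or
#'   genotype vector) for `kind = "snp"`, an STR profile data frame for
#'   `"str"`, a character scalar for `"record"`.
#' @param kind One of `"snp"`, `"str"`, `"record"`.
#' @param spec The test spec governing the encoding (required for `str`
#'   and `record`).
#' @param profile_id Identifier of this profile within the party.
#' @param consent Optional character vector of querier ids allowed to run
#'   tests over this profile (`NULL` = any registered party).
#' @param seed Optional integer seed for encryption randomness.
#' @return The session, invisibly.
#' @export
sequence_and_encrypt <- function(session, party_id, raw_profile,
                                 kind = c("snp", "str", "record"),
                                 spec = NULL, profile_id = "default",
                                 consent = NULL, seed = NULL) {
  kind <- match.arg(kind)
  p <- get_party(session, party_id)
  payloads <- sequence_profile(raw_profile, kind, spec, session$pp$ring$n)
  for (v in payloads) note_secret(session, "plaintexts", v)
  seed <- seed %||% rand_seed()
  cts <- list()
  for (i in seq_along(payloads)) {
    cts[[names(payloads)[i]]] <-
      mkh_encrypt(payloads[[i]], p$keys, session$pp, seed = seed * 31 + i)
  }
  stored <- list(party_id = party_id, profile_id = profile_id, kind = kind,
                 cts = cts, spec = spec, consent = consent)
  sender <- if (session$config$encrypt_by == "ci") "CI" else party_id
  bus_send(session, sender, "SPU", "store_profile", stored)
  session$spu$profiles[[profile_key(party_id, profile_id)]] <- stored
  invisible(session)
}

#' Construct a test query
#'
#' @param test One of `"pm"`, `"paternity"`, `"sps"`, `"linkage"`.
#' @param querier Party id that starts the protocol and receives the
#'   result.
#' @param participants Party ids whose profiles enter the test.  For
#'   `sps` the first participant is the query profile and the remaining
#'   ones the database profiles; for `paternity` the order is (child,
#'   alleged father).
#' @param spec The test spec.
#' @param profile_ids Profile id per participant (recycled).
#' @param test_id Unique identifier for this test run.
#' @return A `ppgc_test_query`.
#' @export
test_query <- function(test = c("pm", "paternity", "sps", "linkage"),
                       querier, participants, spec,
                       profile_ids = "default", test_id = NULL) {
  test <- match.arg(test)
  profile_ids <- rep_len(profile_ids, length(participants))
  test_id <- test_id %||% paste0(test, "-", length(participants), "-",
                                 as.integer(stats::runif(1) * 1e9))
  structure(list(test = test, querier = querier, participants = participants,
                 profile_ids = profile_ids, spec = spec, test_id = test_id),
            class = "ppgc_test_query")
}

fetch_profile <- function(session, party_id, profile_id, kind, querier) {
  key <- profile_key(party_id, profile_id)
  prof <- session$spu$profiles[[key]]
  if (is.null(prof)) stop("missing profile at SPU: ", key)
  if (prof$kind != kind) {
    stop("profile ", key, " has kind '", prof$kind, "', test needs '", kind, "'")
  }
  if (!is.null(prof$consent) && !querier %in% prof$consent) {
    stop("access refused: party ", party_id,
         " has not consented to queries by ", querier)
  }
  prof
}

#' Evaluate an encrypted test at the SPU (Algorithm 3)
#'
#' The SPU selects the referenced encrypted profiles, checks consent,
#' evaluates the test circuit with the registered evaluation keys, and —
#' when masking is configured — applies zero-sum masking over the payload
#' slots so only the aggregate score is released.  The result ciphertext
#' is encrypted under the union of the participants' keys; the SPU itself
#' decrypts nothing.
#'
#' @param session A `ppgc_session`.
#' @param query A `ppgc_test_query`.
#' @param mask Override the session masking config.
#' @return The test id, invisibly; the evaluated ciphertexts stay cached
#'   at the SPU until [run_decryption()] or [flush_spu_cache()].
#' @export
run_encrypted_test <- function(session, query, mask = NULL) {
  stopifnot(inherits(query, "ppgc_test_query"))
  mask <- mask %||% session$config$masking
  pp <- session$pp
  bus_send(session, query$querier, "SPU", "test_query", query)
  for (id in query$participants) get_party(session, id)
  pub <- session$spu$pubkeys
  spec <- query$spec
  getp <- function(i, kind) fetch_profile(session, query$participants[i],
                                          query$profile_ids[i], kind,
                                          query$querier)
  out <- switch(query$test,
    pm = {
      stopifnot(length(query$participants) == 1)
      prof <- getp(1, "snp")
      list(ct = list(pm_risk_circuit(prof$cts$presence, spec, pp)),
           active = seq_len(spec$n_snps))
    },
    paternity = {
      stopifnot(length(query$participants) == 2)
      child <- getp(1, "str"); father <- getp(2, "str")
      list(ct = list(paternity_circuit(child$cts, father$cts, spec, pub, pp)),
           active = seq_len(spec$K))
    },
    sps = {
      if (length(query$participants) < 2) stop("sps needs a query profile and >= 1 database profile")
      qp <- getp(1, "snp")
      cts <- lapply(seq_along(query$participants)[-1], function(i) {
        db <- getp(i, "snp")
        sps_circuit(qp$cts$genotype, db$cts$genotype, spec, pub, pp)
      })
      names(cts) <- query$participants[-1]
      list(ct = cts, active = seq_len(spec$L))
    },
    linkage = {
      stopifnot(length(query$participants) == 2)
      a <- getp(1, "record"); b <- getp(2, "record")
      list(ct = list(linkage_circuit(a$cts$bits, b$cts$bits, spec, pub, pp)),
           active = seq_len(spec$pad_len * length(spec$alphabet)))
    }
  )
  if (mask) out$ct <- lapply(out$ct, mask_zero_sum, active_slots = out$active,
                             pp = pp)
  session$spu$tests[[query$test_id]] <-
    list(query = query, cts = out$ct, masked = mask)
  bus_send(session, "SPU", query$querier, "test_ready",
           list(test_id = query$test_id))
  invisible(query$test_id)
}

score_slots <- function(slots, query, pp) {
  switch(query$test,
    pm = pm_score(slots, query$spec, pp),
    paternity = paternity_score(slots, query$spec, pp),
    sps = sps_score(slots, query$spec, pp),
    linkage = linkage_score(slots, query$spec, pp))
}

#' Distributed decryption and result delivery (Algorithm 4)
#'
#' For each evaluated ciphertext, every involved party computes its
#' partial decryption share (smudged with fresh noise) and returns it to
#' the SPU; the querier's own share is computed locally.  The SPU forwards
#' the ciphertext and all shares to the querier, who finalizes decryption
#' and post-processes the slots into a [scoring] result.  Only the querier
#' ever sees plaintext; withholding any single share makes finalization
#' fail (N-of-N access control).
#'
#' @param session A `ppgc_session`.
#' @param test_id Id of an evaluated test.
#' @param .withhold Testing hook: party id whose share is withheld.
#' @return A `ppgc_scored_result`, or a named list of them for `sps`
#'   database queries.
#' @export
run_decryption <- function(session, test_id, .withhold = NULL) {
  rec <- session$spu$tests[[test_id]]
  if (is.null(rec)) stop("no evaluated test with id ", test_id)
  query <- rec$query
  pp <- session$pp
  querier <- get_party(session, query$querier)
  results <- lapply(rec$cts, function(ct) {
    shares <- list()
    for (id in ct$parties) {
      if (!is.null(.withhold) && id == .withhold) next
      p <- get_party(session, id)
      if (id == query$querier) {
        # Algorithm 4: the querier partially decrypts its own entry locally
        shares[[length(shares) + 1]] <- mkh_part_dec(ct, p$keys, pp)
      } else {
        bus_send(session, "SPU", id, "partdec_request", list(test_id = test_id, ct = ct))
        sh <- mkh_part_dec(ct, p$keys, pp)
        shares[[length(shares) + 1]] <- bus_send(session, id, "SPU", "partdec_share", sh)
      }
    }
    bus_send(session, "SPU", query$querier, "shares_delivery",
             list(test_id = test_id, ct = ct, shares = shares))
    slots <- mkh_fin_dec(ct, shares, pp)
    score_slots(slots, query, pp)
  })
  out <- if (query$test == "sps") results else results[[1]]
  querier$results[[test_id]] <- out
  out
}

#' Withdraw a party (right-to-be-forgotten)
#'
#' Deletes the party's encrypted profiles, registered public keys and any
#' cached evaluated tests it participated in from the SPU.  Other parties'
#' data is untouched.  A second withdrawal of the same party is a no-op
#' with a warning.
#'
#' @param session A `ppgc_session`.
#' @param party_id Party to withdraw.
#' @return The session, invisibly.
#' @export
withdraw <- function(session, party_id) {
  p <- get_party(session, party_id, allow_withdrawn = TRUE)
  if (isTRUE(p$withdrawn)) {
    warning("party ", party_id, " already withdrawn; no-op")
    return(invisible(session))
  }
  bus_send(session, party_id, "SPU", "withdraw", list(party_id = party_id))
  owned <- vapply(session$spu$profiles, function(pr) pr$party_id == party_id,
                  logical(1))
  session$spu$profiles[owned] <- NULL
  involved <- vapply(session$spu$tests, function(tr)
    party_id %in% tr$query$participants || tr$query$querier == party_id,
    logical(1))
  session$spu$tests[involved] <- NULL
  session$spu$pubkeys[[party_id]] <- NULL
  p$withdrawn <- TRUE
  invisible(session)
}

#' Flush the SPU's evaluated-test cache
#' @param session A `ppgc_session`.
#' @export
flush_spu_cache <- function(session) {
  session$spu$tests <- list()
  invisible(session)
}

# ---------------------------------------------------------------------------
# Transcript hygiene

# Recursively collect every numeric leaf (vector or matrix) of an object.
numeric_leaves <- function(x, path = "") {
  if (is.environment(x)) x <- as.list(x)
  if (is.list(x)) {
    nm <- names(x) %||% rep("", length(x))
    out <- list()
    for (i in seq_along(x)) {
      out <- c(out, numeric_leaves(x[[i]], paste0(path, "/", if (nzchar(nm[i])) nm[i] else i)))
    }
    out
  } else if (is.numeric(x)) {
    stats::setNames(list(x), path)
  } else list()
}

leaf_matches <- function(leaf, secret) {
  identical(unname(leaf), unname(secret)) ||
    (is.matrix(secret) && identical(unname(leaf), unname(secret[1, ])))
}

#' Scan the protocol transcript for confidentiality violations
#'
#' Walks every recorded inter-role message and flags any numeric component
#' that equals a registered secret key (any residue row of it) or any
#' plaintext slot payload that was encrypted during the session.  The
#' final plaintext result exists only at the querier and never crosses
#' the bus, so a clean session yields zero findings.
#'
#' @param session A `ppgc_session`.
#' @return Data frame of findings (zero rows when clean): message index,
#'   from, to, type, component path, and what it matched.
#' @export
scan_transcript <- function(session) {
  findings <- list()
  secrets <- c(lapply(session$secrets$sks, identity),
               lapply(session$secrets$plaintexts, identity))
  labels <- c(rep("secret_key", length(session$secrets$sks)),
              rep("plaintext_payload", length(session$secrets$plaintexts)))
  for (m in seq_along(session$transcript)) {
    msg <- session$transcript[[m]]
    leaves <- numeric_leaves(msg$payload)
    for (l in seq_along(leaves)) {
      for (s in seq_along(secrets)) {
        if (leaf_matches(leaves[[l]], secrets[[s]])) {
          findings[[length(findings) + 1]] <- data.frame(
            message = m, from = msg$from, to = msg$to, type = msg$type,
            component = names(leaves)[l], matched = labels[s],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(findings) == 0) {
    data.frame(message = integer(0), from = character(0), to = character(0),
               type = character(0), component = character(0),
               matched = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, findings)
}

#' Scan the SPU store for plaintext or key material
#'
#' Same matching as [scan_transcript()], applied to everything the SPU
#' holds (profiles, cached tests, registered public bundles).
#' @param session A `ppgc_session`.
#' @export
scan_spu_store <- function(session) {
  fake <- new.env(parent = emptyenv())
  fake$transcript <- list(list(from = "SPU", to = "SPU", type = "store",
                               payload = list(profiles = session$spu$profiles,
                                              tests = session$spu$tests,
                                              pubkeys = session$spu$pubkeys)))
  fake$secrets <- session$secrets
  class(fake) <- "ppgc_session"
  scan_transcript(fake)
}
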