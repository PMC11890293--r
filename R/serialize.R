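# On-disk artifact format.  Artifacts (public parameters, key material,
# ciphertexts, decryption shares) are stored as RDS payloads wrapped with
# a format tag and the parameter fingerprint, so loading against the
# wrong parameter set fails loudly instead of corrupting arithmetic.

ppgc_format_version <- 1L

artifact_kind <- function(obj) {
  if (inherits(obj, "ppgc_pp")) "public_params"
  else if (inherits(obj, "ppgc_pubkeys")) "public_keys"
  else if (inherits(obj, "ppgc_keys")) "key_triple"
  else if (inherits(obj, "ppgc_ct")) "ciphertext"
  else if (inherits(obj, "ppgc_pdec")) "decryption_share"
  else if (inherits(obj, "ppgc_scored_result")) "scored_result"
  else stop("not a serializable artifact: ", paste(class(obj), collapse = "/"))
}

#' Save and load protocol artifacts
#'
#' `ppgc_save` writes any protocol artifact (parameters, key triples or
#' public bundles, ciphertexts, decryption shares, scored results) with a
#' format version and the originating parameter fingerprint.  `ppgc_load`
#' restores it, optionally checking it against a parameter set: a
#' fingerprint mismatch is an error.  Key triples containing a secret key
#' refuse to save unless `allow_secret = TRUE`, as a guard against
#' accidentally shipping secret material through shared directories.
#'
#' @param obj The artifact.
#' @param path File path.
#' @param allow_secret Permit writing a secret-key-bearing key triple.
#' @return `ppgc_save` returns `path` invisibly; `ppgc_load` the object.
#' @export
ppgc_save <- function(obj, path, allow_secret = FALSE) {
  kind <- artifact_kind(obj)
  if (kind == "key_triple" && !is.null(obj$sk) && !allow_secret) {
    stop("refusing to serialize a secret key; pass allow_secret = TRUE for a ",
         "party's own key store, or save public_bundle(keys) instead")
  }
  wrapper <- list(format = "ppgc", version = ppgc_format_version,
                  kind = kind, fingerprint = obj$fingerprint, payload = obj)
  saveRDS(wrapper, path)
  invisible(path)
}

#' @rdname ppgc_save
#' @param pp Optional `ppgc_pp` to validate the artifact against.
#' @export
ppgc_load <- function(path, pp = NULL) {
  if (!file.exists(path)) stop("no such artifact: ", path)
  w <- readRDS(path)
  if (!is.list(w) || !identical(w$format, "ppgc")) {
    stop(path, " is not a protocol artifact")
  }
  if (w$version > ppgc_format_version) {
    stop(path, " uses artifact format version ", w$version,
         "; this build reads up to ", ppgc_format_version)
  }
  if (!is.null(pp) && !is.null(w$fingerprint) &&
      !identical(w$fingerprint, pp$fingerprint)) {
    stop(path, " was produced under a different parameter set")
  }
  w$payload
}
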