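# JSON import/export of test parameter files and scored results.

#' Read and write test parameter files (JSON)
#'
#' Test specs are serialized as JSON with a `test` discriminator:
#' `pm` carries a weight/probability table keyed by variant id, `paternity`
#' the locus panel and allele range, `sps` the profile length and cap, and
#' `linkage` the alphabet and one-hot field layout.
#'
#' @param spec A test spec object (see [test_specs]).
#' @param path File path.
#' @return `read_test_spec_json` returns the spec object; the writer
#'   returns `path` invisibly.
#' @export
write_test_spec_json <- function(spec, path) {
  obj <- switch(class(spec)[1],
    ppgc_pm_spec = list(
      test = "pm",
      variants = data.frame(
        variant_id = names(spec$weights) %||% sprintf("rs%06d", seq_len(spec$n_snps)),
        weight = as.numeric(spec$weights), prob = as.numeric(spec$probs)),
      scale_F = spec$scale_F),
    ppgc_paternity_spec = list(
      test = "paternity", K = spec$K, locus_names = spec$locus_names,
      allele_range = spec$allele_range),
    ppgc_sps_spec = list(test = "sps", L = spec$L, cap_c = spec$cap_c),
    ppgc_linkage_spec = list(
      test = "linkage", alphabet = paste(spec$alphabet, collapse = ""),
      pad_len = spec$pad_len),
    stop("not a test spec object")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_test_spec_json
#' @export
read_test_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$test)) stop(path, ": missing 'test' discriminator")
  switch(as.character(obj$test),
    pm = {
      w <- obj$variants$weight
      names(w) <- obj$variants$variant_id
      pm_spec(w, obj$variants$prob, obj$scale_F %||% 2^10)
    },
    paternity = paternity_spec(obj$K, unlist(obj$locus_names),
                               unlist(obj$allele_range)),
    sps = sps_spec(obj$L, obj$cap_c %||% 2),
    linkage = linkage_spec(strsplit(obj$alphabet, "")[[1]], obj$pad_len),
    stop(path, ": unknown test type '", obj$test, "'")
  )
}

#' Export a scored result as JSON
#'
#' Writes `test`, `numerator`, `normalizer`, `scale` and `score`;
#' per-slot raw values are included only on request (they are per-site
#' information the aggregate-only release mode exists to withhold).
#'
#' @param result A `ppgc_scored_result`.
#' @param path File path.
#' @param raw_slots Include the raw per-slot values.
#' @export
write_result_json <- function(result, path, raw_slots = FALSE) {
  stopifnot(inherits(result, "ppgc_scored_result"))
  obj <- list(test = result$test, numerator = result$numerator,
              normalizer = result$normalizer, scale = result$scale,
              score = result$score)
  if (raw_slots) obj$raw_slots <- result$raw_slots
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
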