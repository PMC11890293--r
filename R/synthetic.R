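# Synthetic genomic data generators and plain-text file IO.  The
# generators are study-condition defaults: SNP genotypes are binomial in
# the minor-allele frequency, STR alleles are uniform over the panel's
# repeat-count range, children inherit one allele per locus from each
# parent (Mendelian), and record pairs are corrupted by per-character
# typos at a configurable rate.

#' Generate SNP genotype profiles
#'
#' Draws `n_profiles` profiles of `L` biallelic SNPs; each genotype is
#' `Binomial(2, maf_j)` (minor-allele dosage in \{0,1,2\}) with per-SNP
#' minor-allele frequencies `maf` (recycled, default uniform on
#' `[0.05, 0.5]`).
#'
#' @param n_profiles Number of individuals.
#' @param L Number of SNP sites.
#' @param maf Optional length-L minor-allele frequency vector.
#' @param seed Optional integer seed.
#' @return Data frame: `id`, then columns `snp_0001...`; attribute `"maf"`.
#' @export
gen_snp_profiles <- function(n_profiles, L, maf = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maf <- maf %||% stats::runif(L, 0.05, 0.5)
  stopifnot(length(maf) == L, all(maf > 0 & maf < 1))
  g <- vapply(seq_len(L), function(j) stats::rbinom(n_profiles, 2, maf[j]),
              numeric(n_profiles))
  g <- matrix(g, nrow = n_profiles)
  colnames(g) <- sprintf("snp_%04d", seq_len(L))
  out <- data.frame(id = sprintf("P%04d", seq_len(n_profiles)), g,
                    stringsAsFactors = FALSE)
  attr(out, "maf") <- maf
  attr(out, "variants") <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(L)),
    chromosome = sample(1:22, L, replace = TRUE),
    position = sort(sample.int(2^27, L)),
    stringsAsFactors = FALSE)
  out
}

#' Long-format view of one individual's SNP profile
#'
#' Converts one row of a [gen_snp_profiles()] table into the file dialect:
#' one row per variant with columns `variant_id`, `chromosome`, `position`,
#' `genotype`.
#'
#' @param profiles Output of [gen_snp_profiles()].
#' @param id Individual identifier.
#' @export
snp_long <- function(profiles, id) {
  row <- profiles[profiles$id == id, , drop = FALSE]
  if (nrow(row) != 1) stop("no SNP profile with id ", id)
  g <- as.integer(row[1, setdiff(names(profiles), "id")])
  meta <- attr(profiles, "variants") %||% data.frame(
    variant_id = sprintf("rs%06d", seq_along(g)),
    chromosome = rep(1L, length(g)), position = seq_along(g))
  data.frame(meta, genotype = g, stringsAsFactors = FALSE)
}

#' Generate an STR allele population
#'
#' Draws `n_profiles` short-tandem-repeat profiles over the spec's loci;
#' each of the two alleles per locus is a uniform integer repeat count in
#' `spec$allele_range`.
#'
#' @param n_profiles Number of individuals.
#' @param spec A `ppgc_paternity_spec`.
#' @param seed Optional integer seed.
#' @return Long-format data frame: `id`, `locus`, `allele1`, `allele2`.
#' @export
gen_str_population <- function(n_profiles, spec = paternity_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- spec$allele_range[1]; hi <- spec$allele_range[2]
  ids <- sprintf("S%04d", seq_len(n_profiles))
  data.frame(
    id = rep(ids, each = spec$K),
    locus = rep(spec$locus_names, times = n_profiles),
    allele1 = sample(lo:hi, n_profiles * spec$K, replace = TRUE),
    allele2 = sample(lo:hi, n_profiles * spec$K, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Extract one individual's STR profile from a population table
#' @param population Long-format STR data frame.
#' @param id Individual identifier.
#' @export
str_profile <- function(population, id) {
  out <- population[population$id == id, , drop = FALSE]
  if (nrow(out) == 0) stop("no STR profile with id ", id)
  out
}

#' Generate a Mendelian child from two STR profiles
#'
#' At each locus the child receives one uniformly chosen allele from each
#' parent, so the child shares at least one allele value with each parent
#' at every locus and a paternity comparison against either true parent
#' scores exactly zero.
#'
#' @param mother,father STR profiles (data frames with `locus`, `allele1`,
#'   `allele2` covering the spec's loci).
#' @param spec A `ppgc_paternity_spec`.
#' @param id Child identifier.
#' @param seed Optional integer seed.
#' @return STR profile data frame for the child.
#' @export
gen_child <- function(mother, father, spec = paternity_spec(), id = "CHILD",
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- str_alleles(mother, spec); f <- str_alleles(father, spec)
  pick <- function(a1, a2) ifelse(stats::runif(spec$K) < 0.5, a1, a2)
  data.frame(id = id, locus = spec$locus_names,
             allele1 = pick(m$a1, m$a2), allele2 = pick(f$a1, f$a2),
             stringsAsFactors = FALSE)
}

#' Generate record pairs for linkage experiments
#'
#' Draws `n_pairs` base records (uniform characters over the alphabet,
#' lengths uniform in `len_range`) and a partner for each: with
#' probability `match_rate` the partner is the same underlying record
#' corrupted by independent per-character substitution typos at
#' `typo_rate`; otherwise it is an independent fresh record.
#'
#' @param n_pairs Number of pairs.
#' @param spec A `ppgc_linkage_spec`.
#' @param typo_rate Per-character substitution probability for true matches.
#' @param match_rate Fraction of pairs that are true matches.
#' @param len_range Record length range (capped at `spec$pad_len`).
#' @param seed Optional integer seed.
#' @return Data frame: `pair_id`, `record_a`, `record_b`, `is_match`.
#' @export
gen_record_pairs <- function(n_pairs, spec = linkage_spec(), typo_rate = 0.05,
                             match_rate = 0.5, len_range = c(6, 12),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len_range <- pmin(len_range, spec$pad_len)
  rand_record <- function() {
    len <- sample(len_range[1]:len_range[2], 1)
    paste(sample(spec$alphabet, len, replace = TRUE), collapse = "")
  }
  corrupt <- function(rec) {
    ch <- strsplit(rec, "")[[1]]
    hit <- stats::runif(length(ch)) < typo_rate
    ch[hit] <- sample(spec$alphabet, sum(hit), replace = TRUE)
    paste(ch, collapse = "")
  }
  a <- vapply(seq_len(n_pairs), function(i) rand_record(), character(1))
  is_match <- stats::runif(n_pairs) < match_rate
  b <- ifelse(is_match, vapply(a, corrupt, character(1)),
              vapply(seq_len(n_pairs), function(i) rand_record(), character(1)))
  data.frame(pair_id = sprintf("R%04d", seq_len(n_pairs)),
             record_a = a, record_b = b, is_match = is_match,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# File IO.  Formats are plain delimited text with a header line; lines
# starting with '#' are comments.  Validation reports the offending line
# number (header = line 1 after comments).

read_table_checked <- function(path, sep, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: header is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  df
}

data_line_numbers <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  which(keep)[-1] # drop header; positions are 1-based file line numbers
}

check_cells <- function(df, path, col, ok, what) {
  bad <- which(!ok)
  if (length(bad) > 0) {
    lineno <- data_line_numbers(path)[bad[1]]
    stop(sprintf("%s: line %d: column '%s' %s (value '%s')",
                 path, lineno, col, what, df[[col]][bad[1]]))
  }
  invisible(TRUE)
}

#' Read and write a single SNP profile file
#'
#' Tab-separated, one row per variant, header
#' `variant_id chromosome position genotype` — resembling consumer-genomics
#' exports.  Genotypes must be 0, 1 or 2 (minor-allele dosage);
#' `#`-prefixed lines are comments.  Malformed files raise an error naming
#' the offending line number and column.
#'
#' @param path File path.
#' @return Data frame as produced by [snp_long()].
#' @export
read_snp_tsv <- function(path) {
  df <- read_table_checked(path, "\t",
                           c("variant_id", "chromosome", "position", "genotype"))
  v <- suppressWarnings(as.numeric(df$genotype))
  check_cells(df, path, "genotype", !is.na(v) & v %in% c(0, 1, 2),
              "is not a genotype in {0,1,2}")
  df$genotype <- as.integer(v)
  if (anyDuplicated(df$variant_id)) {
    stop(path, ": duplicate variant_id '",
         df$variant_id[duplicated(df$variant_id)][1], "'")
  }
  df
}

#' @rdname read_snp_tsv
#' @param profile Long-format SNP data frame ([snp_long()]).
#' @export
write_snp_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write STR profile tables
#'
#' Comma-separated, header `id,locus,allele1,allele2`; allele repeat
#' counts must be positive integers.
#'
#' @param path File path.
#' @export
read_str_csv <- function(path) {
  df <- read_table_checked(path, ",", c("id", "locus", "allele1", "allele2"))
  for (col in c("allele1", "allele2")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    check_cells(df, path, col, !is.na(v) & v == round(v) & v > 0,
                "is not a positive integer repeat count")
    df[[col]] <- as.integer(v)
  }
  df
}

#' @rdname read_str_csv
#' @param profiles Long-format STR data frame.
#' @export
write_str_csv <- function(profiles, path) {
  utils::write.table(profiles, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write record-pair tables
#'
#' Comma-separated, header `pair_id,record_a,record_b` (optional
#' `is_match`); records must be non-empty.
#'
#' @param path File path.
#' @export
read_records_csv <- function(path) {
  df <- read_table_checked(path, ",", c("pair_id", "record_a", "record_b"))
  for (col in c("record_a", "record_b")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
    check_cells(df, path, col, nzchar(df[[col]]), "is empty")
  }
  df
}

#' @rdname read_records_csv
#' @param pairs Record-pair data frame.
#' @export
write_records_csv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
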