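#' Read an HLA typing table
#'
#' Expects a TSV with a `sample_id` column and two allele columns per locus,
#' named `<locus>_1` / `<locus>_2` for the six loci A, B, C, DRB1, DQB1,
#' DPB1. Allele names are normalized to two-field resolution.
#'
#' @param path Path to the TSV file.
#' @return A tibble of class `hla_typings`.
#' @export
read_hla_typings <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", paste0(rep(HLA_LOCI, each = 2L), "_", 1:2))
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    stop("HLA typing table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(need, "sample_id")) tbl[[col]] <- normalize_hla_allele(tbl[[col]])
  structure(tbl[need], class = c("hla_typings", class(tbl)))
}

#' Extract one subject's typing as a locus-keyed allele list
#'
#' @param typings An `hla_typings` tibble.
#' @param sample_id Subject id.
#' @param loci Loci to return (default all six).
#' @return A list of class `hla_typing`: `sample_id` plus `alleles`, a named
#'   list locus -> character(2).
#' @export
hla_typing_of <- function(typings, sample_id, loci = HLA_LOCI) {
  row <- typings[typings$sample_id == sample_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("expected exactly one typing row for sample '", sample_id, "', found ",
         nrow(row), call. = FALSE)
  }
  alleles <- lapply(loci, function(l) c(row[[paste0(l, "_1")]], row[[paste0(l, "_2")]]))
  names(alleles) <- loci
  incomplete <- vapply(alleles, function(a) any(is.na(a)), logical(1))
  if (any(incomplete)) {
    stop("incomplete typing for sample '", sample_id, "' at locus ",
         paste(loci[incomplete], collapse = ", "), call. = FALSE)
  }
  structure(list(sample_id = sample_id, alleles = alleles), class = "hla_typing")
}

#' All alleles carried by a subject
#'
#' @param typing An `hla_typing` object.
#' @param loci Loci to include.
#' @param unique_only Drop duplicated alleles.
#' @return Character vector of allele names.
#' @export
typing_alleles <- function(typing, loci = HLA_LOCI, unique_only = FALSE) {
  a <- unlist(typing$alleles[intersect(loci, names(typing$alleles))], use.names = FALSE)
  if (unique_only) unique(a) else a
}

#' Count identical HLA alleles between a donor-recipient pair
#'
#' Per locus the multiset intersection of the two allele pairs contributes 0,
#' 1 or 2; the sum over the six loci gives the 0-12 matching count (a donor
#' homozygous A*01:01/A*01:01 against a recipient A*01:01/A*02:01 contributes
#' 1 at HLA-A).
#'
#' @param donor,recipient `hla_typing` objects covering all six loci.
#' @return Integer in 0-12.
#' @export
count_hla_matches <- function(donor, recipient) {
  missing_loci <- setdiff(HLA_LOCI, intersect(names(donor$alleles), names(recipient$alleles)))
  if (length(missing_loci)) {
    stop("typing missing locus ", paste(missing_loci, collapse = ", "), call. = FALSE)
  }
  sum(vapply(HLA_LOCI, function(l) {
    d <- donor$alleles[[l]]; r <- recipient$alleles[[l]]
    sum(vapply(unique(r), function(a) min(sum(d == a), sum(r == a)), numeric(1)))
  }, numeric(1)))
}

#' Cohort-frequency HLA covariates for a recipient
#'
#' Computes the two covariates guarding against ligand-database
#' under-representation of rare HLA types: the sum over the recipient's
#' distinct alleles of their cohort frequency, and the number of distinct
#' alleles the recipient carries across the six loci. Frequency modes:
#' `"carrier"` (default) counts the fraction of cohort recipients carrying
#' the allele; `"allele_count"` counts allele copies over `2 * n` chromosomes
#' per locus.
#'
#' @param cohort_typings An `hla_typings` tibble restricted to the cohort's
#'   recipients.
#' @param recipient An `hla_typing` object.
#' @param mode `"carrier"` or `"allele_count"`.
#' @return A list with `hla_freq_sum` and `n_unique_hla`.
#' @export
compute_hla_covariates <- function(cohort_typings, recipient, mode = c("carrier", "allele_count")) {
  mode <- match.arg(mode)
  if (nrow(cohort_typings) == 0L) stop("empty cohort typing table", call. = FALSE)
  allele_cols <- paste0(rep(HLA_LOCI, each = 2L), "_", 1:2)
  mat <- as.matrix(cohort_typings[allele_cols])
  n <- nrow(mat)
  rec_alleles <- typing_alleles(recipient, unique_only = TRUE)
  freq <- vapply(rec_alleles, function(a) {
    if (mode == "carrier") {
      sum(apply(mat == a, 1L, any)) / n
    } else {
      sum(mat == a) / (2 * n)
    }
  }, numeric(1))
  list(hla_freq_sum = sum(freq), n_unique_hla = length(rec_alleles))
}
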