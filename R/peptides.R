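#' Sliding-window peptide extraction
#'
#' Splits a protein into all overlapping k-mers (step 1) and deduplicates.
#' Windows containing the unknown residue `X` are dropped, since they cannot
#' be matched against experimental ligands.
#'
#' @param protein Amino-acid string.
#' @param k Peptide length (default 9, the HLA class I ligand core length).
#' @return Character vector of unique k-mers (possibly empty).
#' @export
extract_nine_mers <- function(protein, k = 9L) {
  stopifnot(k >= 1L)
  n <- nchar(protein)
  if (n < k) return(character(0))
  w <- stringi::stri_sub(protein, seq_len(n - k + 1L), length = k)
  unique(w[!stringi::stri_detect_fixed(w, "X")])
}

#' Transcripts whose protein products differ between two subjects
#'
#' Compares the per-transcript protein sets of two proteomes built against the
#' same reference and returns the transcripts with at least one amino-acid
#' difference (set semantics: order and duplication are ignored).
#'
#' @param donor,recipient `individual_proteome` objects.
#' @return Character vector of transcript ids.
#' @export
differing_transcripts <- function(donor, recipient) {
  if (!setequal(names(donor$proteins), names(recipient$proteins))) {
    stop("donor and recipient proteomes were not built against the same reference",
         call. = FALSE)
  }
  tx <- names(donor$proteins)
  differs <- vapply(tx, function(t) {
    !setequal(donor$proteins[[t]], recipient$proteins[[t]])
  }, logical(1))
  tx[differs]
}

#' Recipient-unique mismatched peptides
#'
#' Over the transcripts whose protein products differ between donor and
#' recipient, both subjects' proteins are split into k-mers; peptides present
#' in the recipient's union but absent from the donor's are the
#' recipient-unique (candidate alloantigen) set. Provenance (source
#' transcripts and genes) is merged across transcripts yielding the same
#' peptide.
#'
#' @param donor,recipient `individual_proteome` objects built on the same
#'   reference.
#' @param k Peptide length (default 9).
#' @param strict_donor_union If `TRUE`, subtract the donor's whole-proteome
#'   k-mer union rather than only k-mers from differing transcripts. Off by
#'   default: the pipeline first excludes identical proteins, then splits and
#'   subtracts.
#' @return A tibble of class `mismatched_peptides` with columns `peptide`,
#'   `source_transcripts` (list), `source_genes` (list).
#' @export
recipient_unique_peptides <- function(donor, recipient, k = 9L,
                                      strict_donor_union = FALSE) {
  diff_tx <- differing_transcripts(donor, recipient)
  if (length(diff_tx) == 0L) return(empty_mismatched_peptides())

  rec <- lapply(diff_tx, function(t) {
    peps <- unique(unlist(lapply(recipient$proteins[[t]], extract_nine_mers, k = k),
                          use.names = FALSE))
    if (length(peps)) tibble::tibble(peptide = peps, transcript_id = t) else NULL
  })
  rec_tbl <- dplyr::bind_rows(rec)
  if (nrow(rec_tbl) == 0L) return(empty_mismatched_peptides())

  donor_tx <- if (isTRUE(strict_donor_union)) names(donor$proteins) else diff_tx
  donor_peps <- unique(unlist(
    lapply(donor_tx, function(t) {
      unlist(lapply(donor$proteins[[t]], extract_nine_mers, k = k), use.names = FALSE)
    }),
    use.names = FALSE
  ))

  uniq <- rec_tbl[!(rec_tbl$peptide %in% donor_peps), , drop = FALSE]
  if (nrow(uniq) == 0L) return(empty_mismatched_peptides())
  genes <- recipient$genes
  out <- uniq |>
    dplyr::summarise(
      source_transcripts = list(sort(unique(.data$transcript_id))),
      source_genes = list(sort(unique(unname(genes[.data$transcript_id])))),
      .by = "peptide"
    )
  new_mismatched_peptides(out)
}

new_mismatched_peptides <- function(tbl) {
  structure(tbl, class = c("mismatched_peptides", setdiff(class(tbl), "mismatched_peptides")))
}

empty_mismatched_peptides <- function() {
  new_mismatched_peptides(tibble::tibble(
    peptide = character(), source_transcripts = list(), source_genes = list()
  ))
}

#' Write mismatched peptides to TSV
#'
#' @param peptides A `mismatched_peptides` tibble.
#' @param path Output TSV path; provenance columns are comma-joined.
#' @return `path`, invisibly.
#' @export
write_mismatched_peptides <- function(peptides, path) {
  flat <- tibble::tibble(
    peptide = peptides$peptide,
    source_transcripts = vapply(peptides$source_transcripts, paste, character(1), collapse = ","),
    source_genes = vapply(peptides$source_genes, paste, character(1), collapse = ",")
  )
  readr::write_tsv(flat, path)
  invisible(path)
}
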