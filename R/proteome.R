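#' Apply variants of one haplotype to a coding sequence
#'
#' Edits a reference CDS with a set of non-overlapping variants in VCF-style
#' left-anchored representation (CDS coordinates, 1-based). Variants are
#' applied in descending position order so earlier coordinates stay valid
#' after indels.
#'
#' @param cds Reference coding sequence (A/C/G/T/N string).
#' @param variants A data frame with columns `cds_pos`, `ref`, `alt`
#'   restricted to one haplotype.
#' @param transcript_id Used in error messages only.
#' @return The mutated CDS string; with zero variants the reference itself.
#' @export
apply_variants_to_cds <- function(cds, variants, transcript_id = "<cds>") {
  if (is.null(variants) || nrow(variants) == 0L) return(cds)
  v <- variants[order(variants$cds_pos), , drop = FALSE]
  ends <- v$cds_pos + nchar(v$ref) - 1L
  if (any(v$cds_pos < 1L) || any(ends > nchar(cds))) {
    stop("variant outside CDS bounds on ", transcript_id, call. = FALSE)
  }
  if (nrow(v) > 1L && any(v$cds_pos[-1L] <= ends[-nrow(v)])) {
    stop("overlapping variants on ", transcript_id, call. = FALSE)
  }
  obs <- substring(cds, v$cds_pos, ends)
  bad <- obs != v$ref
  if (any(bad)) {
    stop(sprintf("reference allele mismatch on %s at CDS position %d: expected '%s', CDS has '%s'",
                 transcript_id, v$cds_pos[which(bad)[1]],
                 v$ref[which(bad)[1]], obs[which(bad)[1]]), call. = FALSE)
  }
  out <- cds
  for (i in rev(seq_len(nrow(v)))) {
    out <- paste0(
      substr(out, 1L, v$cds_pos[i] - 1L),
      v$alt[i],
      substring(out, ends[i] + 1L)
    )
  }
  out
}

#' Translate a CDS with the standard genetic code
#'
#' Translation starts at position 1, stops at (and excludes) the first stop
#' codon, drops a trailing incomplete codon, and renders codons containing N
#' that cannot be resolved as `X`. Used for both reference and frameshifted
#' products, so no ATG is required.
#'
#' @param cds Nucleotide string.
#' @return Amino-acid string (possibly empty).
#' @export
translate_cds <- function(cds) {
  n <- 3L * (nchar(cds) %/% 3L)
  if (n == 0L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  aa <- unname(CODON_TABLE[substring(cds, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"   # codons containing N (or other ambiguity)
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1L)]
  paste(aa, collapse = "")
}

#' Translate every reference CDS in one vectorized call
#'
#' @param reference A `cds_reference` tibble.
#' @return Named character vector transcript_id -> reference protein.
#' @export
translate_reference <- function(reference) {
  if (nrow(reference) == 0L) return(stats::setNames(character(0), character(0)))
  stats::setNames(vapply(reference$cds, translate_cds, character(1), USE.NAMES = FALSE),
                  reference$transcript_id)
}

#' Build a per-individual in-silico proteome
#'
#' Maps a subject's quality-filtered non-synonymous variants onto the CDS
#' reference and translates the result. Phase is unknown, so two
#' pseudo-haplotypes are used per transcript: H1 carries only homozygous-alt
#' variants, H2 carries all non-missing carried variants (hom + het). This is
#' deterministic, requires no phasing, and guarantees that the
#' reference-allele product survives whenever a heterozygous site exists.
#' Per transcript the proteome stores the deduplicated set
#' \{translate(H1), translate(H2)\} (1 or 2 sequences); transcripts without
#' carried variants map to the reference protein.
#'
#' @param sample_id Subject identifier (must be present in `variants`).
#' @param reference A `cds_reference` tibble.
#' @param variants A `variant_calls` tibble, already quality-filtered and
#'   restricted to non-synonymous effects.
#' @param reference_proteins Optional precomputed [translate_reference()]
#'   result, reusable across subjects of a cohort.
#' @return An object of class `individual_proteome`: list with `sample_id`,
#'   `proteins` (named list transcript_id -> character vector) and `genes`
#'   (named character vector transcript_id -> gene_id).
#' @export
build_individual_proteome <- function(sample_id, reference, variants,
                                      reference_proteins = NULL) {
  assert_scalar_string(sample_id, "sample_id")
  ref_prot <- reference_proteins %||% translate_reference(reference)
  proteins <- as.list(unname(ref_prot[reference$transcript_id]))
  names(proteins) <- reference$transcript_id

  v <- variants[variants$sample_id == sample_id & !variants$missing & variants$dosage > 0L, , drop = FALSE]
  if (nrow(v)) {
    unknown_tx <- setdiff(unique(v$transcript_id), reference$transcript_id)
    if (length(unknown_tx)) {
      stop("variants refer to transcripts absent from the reference: ",
           paste(unknown_tx, collapse = ", "), call. = FALSE)
    }
    cds_by_tx <- stats::setNames(reference$cds, reference$transcript_id)
    for (tx in unique(v$transcript_id)) {
      vt <- v[v$transcript_id == tx, , drop = FALSE]
      h2 <- translate_cds(apply_variants_to_cds(cds_by_tx[[tx]], vt, tx))
      hom <- vt[vt$dosage == 2L, , drop = FALSE]
      h1 <- if (nrow(hom) == nrow(vt)) h2 else
        translate_cds(apply_variants_to_cds(cds_by_tx[[tx]], hom, tx))
      prods <- unique(c(h1, h2))
      prods <- prods[nzchar(prods)]
      proteins[[tx]] <- if (length(prods)) prods else character(0)
    }
  }
  structure(
    list(
      sample_id = sample_id,
      proteins = proteins,
      genes = stats::setNames(reference$gene_id, reference$transcript_id)
    ),
    class = "individual_proteome"
  )
}

#' @export
print.individual_proteome <- function(x, ...) {
  n_var <- sum(lengths(x$proteins) > 1L)
  cat("<individual_proteome> sample", x$sample_id, "-",
      length(x$proteins), "transcripts,", n_var, "with a variant product\n")
  invisible(x)
}

#' Export a proteome to FASTA (debugging aid)
#'
#' @param proteome An `individual_proteome`.
#' @param path Output path; headers are `sample|transcript|h<i>`.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  seqs <- unlist(proteome$proteins, use.names = FALSE)
  tx <- rep(names(proteome$proteins), lengths(proteome$proteins))
  idx <- unlist(lapply(lengths(proteome$proteins), seq_len), use.names = FALSE)
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- paste(proteome$sample_id, tx, paste0("h", idx), sep = "|")
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}
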