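#' Read and filter a coding-sequence FASTA reference
#'
#' Reads an Ensembl-CDS-style FASTA file and keeps only transcripts that start
#' with the canonical ATG codon and are at least `min_length` nucleotides long,
#' mirroring the usual pre-filtering applied before in-silico translation of
#' personal genomes. Headers are parsed as `<transcript_id> ... gene:<gene_id>`;
#' when no `gene:` token is present the transcript id doubles as the gene id.
#'
#' @param path Path to a FASTA file (gzipped accepted).
#' @param min_length Minimum CDS length in nucleotides (inclusive). Default 50.
#' @param require_atg Keep only records whose sequence starts with "ATG".
#' @return A tibble of class `cds_reference` with columns `transcript_id`,
#'   `gene_id` and `cds`. The number of rejected records is reported.
#' @export
read_cds_fasta <- function(path, min_length = 50L, require_atg = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  # read without alphabet coercion so invalid letters are rejected here
  # rather than silently dropped
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) {
    warning("FASTA file '", path, "' contains no records", call. = FALSE)
    return(new_cds_reference(tibble::tibble(
      transcript_id = character(), gene_id = character(), cds = character()
    )))
  }
  headers <- names(seqs)
  transcript_id <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  gene_id <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("gene:[^ ]+", h))
    if (length(m)) sub("^gene:", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  gene_id <- ifelse(is.na(gene_id), transcript_id, gene_id)
  if (anyDuplicated(transcript_id)) {
    dup <- unique(transcript_id[duplicated(transcript_id)])
    stop("duplicate transcript_id in reference: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  cds <- toupper(as.character(seqs))
  bad_alpha <- grepl("[^ACGTN]", cds)
  if (any(bad_alpha)) {
    stop("CDS records with characters outside A/C/G/T/N: ",
         paste(transcript_id[bad_alpha], collapse = ", "), call. = FALSE)
  }
  keep <- nchar(cds) >= min_length
  if (isTRUE(require_atg)) keep <- keep & startsWith(cds, "ATG")
  n_rejected <- sum(!keep)
  if (n_rejected > 0L) {
    message(n_rejected, " of ", length(cds), " CDS records rejected (ATG/length filter)")
  }
  new_cds_reference(tibble::tibble(
    transcript_id = transcript_id[keep],
    gene_id = gene_id[keep],
    cds = unname(cds[keep])
  ))
}

new_cds_reference <- function(tbl) {
  structure(tbl, class = c("cds_reference", class(tbl)))
}

#' Write a CDS reference back to FASTA
#'
#' Inverse of [read_cds_fasta()]; headers are written as
#' `<transcript_id> gene:<gene_id>` so a read/write cycle round-trips.
#'
#' @param reference A `cds_reference` tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(reference, path) {
  seqs <- Biostrings::DNAStringSet(reference$cds)
  names(seqs) <- paste0(reference$transcript_id, " gene:", reference$gene_id)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read coding-consequence variants from an annotated VCF
#'
#' Parses a VCF whose records live in transcript space (`CHROM` = transcript
#' id, `POS` = 1-based CDS position) and carry a pipe-delimited consequence
#' annotation `ANN=transcript_id|effect|cds_pos|cds_ref|cds_alt[,...]`. One
#' variant row per (record, transcript annotation, sample) is returned in long
#' format; annotations whose effect is not one of missense, insertion,
#' deletion, frameshift or stop_gained (e.g. synonymous or non-coding
#' consequences) are dropped. snpEff/VEP ANN/CSQ fields can be reduced to this
#' dialect by extracting the transcript id, consequence term and CDS-relative
#' alleles from their annotation subfields.
#'
#' @param path Path to a VCF 4.x file (gzipped accepted).
#' @param samples Character vector of sample ids to extract; all must be
#'   present in the VCF header.
#' @param effects Effect classes to retain. Defaults to the non-synonymous set.
#' @return A tibble of class `variant_calls` with columns `transcript_id`,
#'   `cds_pos`, `ref`, `alt`, `effect`, `sample_id`, `dosage`, `dp`, `gq`,
#'   `missing`.
#' @export
read_annotated_vcf <- function(path, samples, effects = VALID_EFFECTS) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(vcf@gt)[-1]
  missing_samples <- setdiff(samples, have)
  if (length(missing_samples)) {
    stop("sample(s) absent from VCF header: ", paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  n_rec <- nrow(vcf@fix)
  if (is.null(n_rec) || n_rec == 0L) return(empty_variant_calls())

  ann <- vcfR::extract.info(vcf, element = "ANN")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))

  no_ann <- is.na(ann) | !nzchar(ann)
  if (any(no_ann)) {
    warning(sum(no_ann), " VCF record(s) without ANN annotation skipped", call. = FALSE)
  }

  rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    if (no_ann[i]) next
    parts <- strsplit(strsplit(ann[i], ",", fixed = TRUE)[[1]], "|", fixed = TRUE)
    ok <- vapply(parts, length, integer(1)) == 5L
    if (!all(ok)) {
      warning("malformed ANN entry at record ", i, " skipped", call. = FALSE)
      parts <- parts[ok]
    }
    if (!length(parts)) next
    a <- do.call(rbind, parts)
    keep <- a[, 2] %in% effects
    if (!any(keep)) next
    a <- a[keep, , drop = FALSE]
    rows[[i]] <- tibble::tibble(
      transcript_id = a[, 1],
      cds_pos = as.integer(a[, 3]),
      ref = a[, 4],
      alt = a[, 5],
      effect = a[, 2],
      .record = i
    )
  }
  ann_tbl <- dplyr::bind_rows(rows)
  if (nrow(ann_tbl) == 0L) return(empty_variant_calls())

  geno <- lapply(samples, function(s) {
    g <- gt[ann_tbl$.record, s]
    dosage <- unname(gt_to_dosage(g))
    tibble::tibble(
      sample_id = s,
      dosage = dosage,
      dp = unname(as.numeric(dp[ann_tbl$.record, s])),
      gq = unname(as.numeric(gq[ann_tbl$.record, s])),
      missing = is.na(dosage)
    )
  })
  out <- dplyr::bind_cols(
    ann_tbl[rep(seq_len(nrow(ann_tbl)), times = length(samples)), , drop = FALSE],
    dplyr::bind_rows(geno)
  )
  out$.record <- NULL
  new_variant_calls(out)
}

gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0L || any(is.na(a)) || any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
}

new_variant_calls <- function(tbl) {
  structure(tbl, class = c("variant_calls", setdiff(class(tbl), "variant_calls")))
}

empty_variant_calls <- function() {
  new_variant_calls(tibble::tibble(
    transcript_id = character(), cds_pos = integer(), ref = character(),
    alt = character(), effect = character(), sample_id = character(),
    dosage = integer(), dp = numeric(), gq = numeric(), missing = logical()
  ))
}

#' Quality thresholds for genotype hard filtering
#'
#' @param dp_min Minimum read depth (DP); genotypes below are set missing.
#' @param gq_min Minimum genotype quality (GQ).
#' @return A list of class `quality_thresholds`.
#' @export
quality_thresholds <- function(dp_min = 15L, gq_min = 20L) {
  if (dp_min < 0 || gq_min < 0) stop("quality thresholds must be >= 0", call. = FALSE)
  structure(list(dp_min = dp_min, gq_min = gq_min), class = "quality_thresholds")
}

#' Hard-filter genotypes on read depth and genotype quality
#'
#' Genotypes with `DP < dp_min` or `GQ < gq_min` (or with DP/GQ unavailable)
#' are set to missing; variants whose genotypes are missing in every sample
#' are removed. The operation is idempotent.
#'
#' @param variants A `variant_calls` tibble.
#' @param thresholds A [quality_thresholds()] object.
#' @return Filtered `variant_calls`.
#' @export
genotype_quality_filter <- function(variants, thresholds = quality_thresholds()) {
  stopifnot(inherits(thresholds, "quality_thresholds"))
  if (nrow(variants) == 0L) return(variants)
  fail <- is.na(variants$dp) | is.na(variants$gq) |
    variants$dp < thresholds$dp_min | variants$gq < thresholds$gq_min
  variants$missing <- variants$missing | fail
  variants$dosage[variants$missing] <- NA_integer_
  keep_keys <- variants |>
    dplyr::summarise(
      any_ok = any(!.data$missing),
      .by = c("transcript_id", "cds_pos", "ref", "alt")
    ) |>
    dplyr::filter(.data$any_ok)
  out <- dplyr::semi_join(
    variants, keep_keys,
    by = c("transcript_id", "cds_pos", "ref", "alt")
  )
  new_variant_calls(out)
}

#' Keep only non-synonymous coding variants
#'
#' Explicit whitelist gate on the effect class: only missense, insertion,
#' deletion, frameshift and stop_gained survive. [read_annotated_vcf()]
#' already enforces this; the gate exists for adapters that ingest looser
#' annotation sources.
#'
#' @param variants A `variant_calls` tibble.
#' @return Filtered `variant_calls`; unknown effect strings are dropped with a
#'   warning.
#' @export
select_nonsynonymous <- function(variants) {
  if (nrow(variants) == 0L) return(variants)
  unknown <- setdiff(unique(variants$effect), VALID_EFFECTS)
  if (length(unknown)) {
    warning("dropping variants with effect class(es) outside the non-synonymous set: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  new_variant_calls(dplyr::filter(variants, .data$effect %in% VALID_EFFECTS))
}
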