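#' Read a tissue-expression reliability table
#'
#' HPA-schema TSV with columns `gene`, `transcript` (may be empty), `tissue`,
#' `reliability`.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_expression_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene", "tissue", "reliability")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    stop("expression table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"transcript" %in% names(tbl)) tbl$transcript <- NA_character_
  tbl
}

#' Filter mismatched peptides by tissue-expression reliability
#'
#' A peptide is kept if at least one of its source genes (or source
#' transcripts, when transcript-level records exist) has an expression record
#' with the required reliability in at least one of the GvHD target tissues.
#' Matching is gene-level, with transcript-level records acting as an
#' additional route when the table provides transcript ids.
#'
#' @param peptides A `mismatched_peptides` tibble (provenance required).
#' @param expression A table from [read_expression_table()].
#' @param tissues Target tissues (default skin, intestine, lung, liver,
#'   bone marrow); matched case-insensitively.
#' @param required_reliability Reliability class required (default
#'   "supportive"); matched case-insensitively.
#' @return Filtered `mismatched_peptides`.
#' @export
filter_by_expression <- function(peptides, expression,
                                 tissues = GVHD_TARGET_TISSUES,
                                 required_reliability = "supportive") {
  if (is.null(expression) || nrow(expression) == 0L) {
    stop("expression table is missing or empty; cannot apply the tissue-expression filter",
         call. = FALSE)
  }
  if (nrow(peptides) == 0L) return(peptides)
  pass <- tolower(expression$reliability) == tolower(required_reliability) &
    tolower(expression$tissue) %in% tolower(tissues)
  pass_genes <- unique(expression$gene[pass])
  pass_tx <- unique(expression$transcript[pass & !is.na(expression$transcript) &
                                            nzchar(expression$transcript)])
  keep <- vapply(seq_len(nrow(peptides)), function(i) {
    any(peptides$source_genes[[i]] %in% pass_genes) ||
      any(peptides$source_transcripts[[i]] %in% pass_tx)
  }, logical(1))
  new_mismatched_peptides(peptides[keep, , drop = FALSE])
}

#' Per-pair alloreactivity estimates M1-M4
#'
#' From one donor-recipient pair's recipient-unique peptide set `U` this
#' computes the four HLA-presentation-based estimators:
#' \describe{
#'   \item{m1}{peptides of `U` shared with experimental IEDB 9-mer ligands;}
#'   \item{m2}{peptides of the immunogenicity- and expression-filtered set
#'     `F` shared with the IEDB ligands;}
#'   \item{m3}{peptides of `U` shared with known 9-mer minor
#'     histocompatibility antigens;}
#'   \item{m4}{peptides of `F` predicted high-affinity (consensus percentile
#'     rank at or below the cutoff) for at least one recipient HLA-A/-B
#'     allele.}
#' }
#' By default ligand databases are pooled over the recipient's own class I
#' alleles before intersecting (allele-aware matching);
#' `restrict_to_recipient_hla = FALSE` pools the whole database instead.
#'
#' @param pair_id Pair identifier carried into the output.
#' @param peptides Recipient-unique peptides from
#'   [recipient_unique_peptides()].
#' @param recipient_typing The recipient's `hla_typing`.
#' @param iedb_db,mha_db `ligand_db` objects.
#' @param expression Expression table (see [filter_by_expression()]).
#' @param imm_model An [immunogenicity_model()].
#' @param predictor An affinity predictor.
#' @param affinity An [affinity_config()].
#' @param restrict_to_recipient_hla Pool ligand databases over the
#'   recipient's class I alleles only (default `TRUE`).
#' @param strict Raise errors from any estimator (default). With
#'   `strict = FALSE`, failing estimators yield `NA` counts and the error
#'   messages are attached as the `"estimate_errors"` attribute so unaffected
#'   estimators still report.
#' @return One-row tibble: `pair_id`, `m1`-`m4`, `total_mismatched`,
#'   `total_filtered`.
#' @export
compute_method_counts <- function(pair_id, peptides, recipient_typing,
                                  iedb_db, mha_db, expression,
                                  imm_model = immunogenicity_model(),
                                  predictor = toy_pssm_predictor(),
                                  affinity = affinity_config(),
                                  restrict_to_recipient_hla = TRUE,
                                  strict = TRUE) {
  if (is.null(recipient_typing)) stop("missing HLA typing for recipient of pair ", pair_id, call. = FALSE)
  u <- peptides$peptide
  class1 <- if (restrict_to_recipient_hla) {
    typing_alleles(recipient_typing, loci = HLA_CLASS1_LOCI, unique_only = TRUE)
  } else NULL

  errors <- character(0)
  grab <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      if (strict) stop(e)
      errors[[label]] <<- conditionMessage(e)
      NULL
    })
  }

  m1 <- grab("m1", length(intersect(u, pool_ligands(iedb_db, class1))))
  m3 <- grab("m3", length(intersect(u, pool_ligands(mha_db, class1))))

  filtered <- grab("filter", {
    filter_by_expression(filter_by_immunogenicity(peptides, imm_model), expression)
  })
  m2 <- m4 <- total_filtered <- NULL
  if (!is.null(filtered)) {
    total_filtered <- nrow(filtered)
    m2 <- grab("m2", length(intersect(filtered$peptide, pool_ligands(iedb_db, class1))))
    m4 <- grab("m4", {
      ab <- typing_alleles(recipient_typing, loci = affinity$loci, unique_only = TRUE)
      ranks <- suppressWarnings(
        predict_percentile_ranks(filtered$peptide, ab, predictor)
      )
      count_high_affinity(ranks, ab, affinity)
    })
  }

  out <- tibble::tibble(
    pair_id = pair_id,
    m1 = (m1 %||% NA_integer_) + 0L,
    m2 = (m2 %||% NA_integer_) + 0L,
    m3 = (m3 %||% NA_integer_) + 0L,
    m4 = (m4 %||% NA_integer_) + 0L,
    total_mismatched = length(u),
    total_filtered = (total_filtered %||% NA_integer_) + 0L
  )
  attr(out, "estimate_errors") <- errors
  out
}
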