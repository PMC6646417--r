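# T-cell immunogenicity scoring: a position-weighted sum of per-residue
# log-enrichment weights (residues over-represented in immunogenic vs.
# non-immunogenic HLA class I ligands score positive). Constants transcribed
# from the public Immunogenicity-1.1 source (Calis et al. 2013) and shipped as
# a versioned data file so any future revision is traceable.

# Per-position importance weights for 9-mers; anchor positions 1, 2 and the
# C-terminus carry no weight when run without HLA-type specification.
IMM_POSITION_WEIGHTS_9 <- c(0.00, 0.00, 0.10, 0.31, 0.30, 0.29, 0.26, 0.18, 0.00)

#' Immunogenicity scoring model
#'
#' Assembles the residue log-enrichment table and per-position importance
#' weights into a scoring model for k-mer peptides. The default masks
#' positions 1, 2 and the C-terminus (the HLA anchor positions), matching the
#' tool's behaviour when no HLA type is specified; allele-specific masks are
#' deliberately not implemented.
#'
#' @param k Peptide length (default 9; only 9 has published position weights).
#' @param threshold Selection threshold on the score; peptides are kept only
#'   if score is strictly greater (default 0.2).
#' @param masked_positions Positions whose weight is forced to 0.
#' @param position_weights Numeric vector of length `k`.
#' @param weights_file TSV with columns `residue`, `log_enrichment`.
#' @return A list of class `immunogenicity_model`.
#' @export
immunogenicity_model <- function(k = 9L,
                                 threshold = 0.2,
                                 masked_positions = c(1L, 2L, k),
                                 position_weights = NULL,
                                 weights_file = system.file(
                                   "extdata", "immunogenicity_residue_weights_v1.1.tsv",
                                   package = "allopep")) {
  if (is.null(position_weights)) {
    if (k != 9L) stop("default position weights are defined for k = 9 only", call. = FALSE)
    position_weights <- IMM_POSITION_WEIGHTS_9
  }
  if (length(position_weights) != k) {
    stop("position_weights must have length k = ", k, call. = FALSE)
  }
  w <- readr::read_tsv(weights_file, show_col_types = FALSE, progress = FALSE)
  if (!setequal(w$residue, AA_STANDARD)) {
    stop("residue weight table must cover exactly the 20 standard residues", call. = FALSE)
  }
  pw <- position_weights
  pw[masked_positions] <- 0
  structure(
    list(
      k = as.integer(k),
      threshold = threshold,
      residue_log_enrichment = stats::setNames(w$log_enrichment, w$residue),
      position_weights = pw,
      masked_positions = as.integer(masked_positions)
    ),
    class = "immunogenicity_model"
  )
}

#' Score peptides for predicted T-cell immunogenicity
#'
#' `score = sum_i position_weight[i] * log_enrichment[peptide[i]]`, with
#' masked (anchor) positions contributing 0.
#'
#' @param peptides Character vector of k-mers over the 20-letter alphabet.
#' @param model An [immunogenicity_model()].
#' @return Numeric vector of scores.
#' @export
immunogenicity_score <- function(peptides, model = immunogenicity_model()) {
  if (!length(peptides)) return(numeric(0))
  if (any(nchar(peptides) != model$k)) {
    stop("all peptides must have length k = ", model$k, call. = FALSE)
  }
  mat <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
                ncol = model$k, byrow = TRUE)
  if (!all(mat %in% names(model$residue_log_enrichment))) {
    bad <- unique(mat[!(mat %in% names(model$residue_log_enrichment))])
    stop("peptide residue(s) outside the standard alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  e <- matrix(model$residue_log_enrichment[mat], ncol = model$k)
  as.numeric(e %*% model$position_weights)
}

#' Filter mismatched peptides by predicted immunogenicity
#'
#' Retains peptides whose immunogenicity score is strictly greater than the
#' model threshold (a score exactly at the threshold is excluded).
#'
#' @param peptides A `mismatched_peptides` tibble.
#' @param model An [immunogenicity_model()].
#' @param threshold Override of the model threshold.
#' @return Filtered `mismatched_peptides`.
#' @export
filter_by_immunogenicity <- function(peptides, model = immunogenicity_model(),
                                     threshold = model$threshold) {
  if (nrow(peptides) == 0L) return(peptides)
  s <- immunogenicity_score(peptides$peptide, model)
  new_mismatched_peptides(peptides[s > threshold, , drop = FALSE])
}
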