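# Pluggable HLA-binding percentile-rank predictors. The multi-algorithm
# consensus engines used for real data sit behind this contract: a predictor
# declares which alleles it supports and returns a percentile rank in
# (0, 100] per (peptide, allele) pair, lower = stronger predicted binding.

#' Affinity configuration
#'
#' @param rank_cutoff Consensus percentile-rank cutoff defining a
#'   "high-affinity" peptide (default 4; 6 is the standard robustness
#'   alternative).
#' @param loci HLA loci used for prediction (default A and B).
#' @return A list of class `affinity_config`.
#' @export
affinity_config <- function(rank_cutoff = 4, loci = c("A", "B")) {
  if (rank_cutoff <= 0 || rank_cutoff > 100) {
    stop("rank_cutoff must be in (0, 100]", call. = FALSE)
  }
  structure(list(rank_cutoff = rank_cutoff, loci = loci), class = "affinity_config")
}

#' Alleles supported by an affinity predictor
#' @param predictor A predictor object.
#' @param alleles Candidate allele names (normalized).
#' @return Logical vector: which of `alleles` the predictor can score.
#' @export
supports_alleles <- function(predictor, alleles) UseMethod("supports_alleles")

#' Raw rank computation for a predictor (internal contract)
#' @param predictor A predictor object.
#' @param peptides Character vector of 9-mers.
#' @param alleles Normalized allele names, all supported.
#' @return Tibble with columns `peptide`, `allele`, `percentile_rank`.
#' @export
compute_ranks <- function(predictor, peptides, alleles) UseMethod("compute_ranks")

#' Predictor backed by a precomputed percentile-rank table
#'
#' @param x Either a path to a TSV with columns `peptide`, `allele`,
#'   `percentile_rank`, or a data frame with those columns.
#' @return A predictor of class `rank_table_predictor`.
#' @export
rank_table_predictor <- function(x) {
  tbl <- if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE, progress = FALSE) else tibble::as_tibble(x)
  need <- c("peptide", "allele", "percentile_rank")
  if (!all(need %in% names(tbl))) {
    stop("rank table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tbl$allele <- normalize_hla_allele(tbl$allele)
  if (any(tbl$percentile_rank <= 0 | tbl$percentile_rank > 100, na.rm = TRUE)) {
    stop("percentile ranks must lie in (0, 100]", call. = FALSE)
  }
  tbl <- dplyr::distinct(tbl[stats::complete.cases(tbl[need]), need])
  structure(list(table = tbl), class = c("rank_table_predictor", "affinity_predictor"))
}

#' @export
supports_alleles.rank_table_predictor <- function(predictor, alleles) {
  alleles %in% unique(predictor$table$allele)
}

#' @export
compute_ranks.rank_table_predictor <- function(predictor, peptides, alleles) {
  dplyr::filter(predictor$table,
                .data$peptide %in% !!peptides,
                .data$allele %in% !!alleles)
}

#' Deterministic toy position-specific-scoring-matrix predictor
#'
#' A self-contained stand-in predictor for tests and simulations: each class I
#' allele gets a reproducible 20 x 9 score matrix seeded from the allele name,
#' a peptide's score is the sum of its per-position entries, and the
#' percentile rank is the upper-tail probability of that score under the
#' normal approximation to random uniform peptides. Deterministic given
#' `seed`; not a real binding model.
#'
#' @param seed Integer seed mixed into every allele's matrix.
#' @return A predictor of class `toy_pssm_predictor`.
#' @export
toy_pssm_predictor <- function(seed = 1L) {
  structure(list(seed = as.integer(seed)),
            class = c("toy_pssm_predictor", "affinity_predictor"))
}

#' @export
supports_alleles.toy_pssm_predictor <- function(predictor, alleles) {
  hla_locus(alleles) %in% HLA_CLASS1_LOCI
}

toy_pssm_matrix <- function(allele, seed) {
  h <- sum(utf8ToInt(allele) * seq_along(utf8ToInt(allele)))
  s <- as.integer((as.numeric(seed) * 69621 + h * 104729) %% 2147483629L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(s)
  matrix(stats::rnorm(20L * 9L), nrow = 20L, dimnames = list(AA_STANDARD, NULL))
}

#' @export
compute_ranks.toy_pssm_predictor <- function(predictor, peptides, alleles) {
  res <- lapply(alleles, function(al) {
    pssm <- toy_pssm_matrix(al, predictor$seed)
    mu <- sum(colMeans(pssm))
    sigma <- sqrt(sum(apply(pssm, 2, function(col) mean(col^2) - mean(col)^2)))
    chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
                    ncol = 9L, byrow = TRUE)
    idx <- cbind(match(as.vector(chars), AA_STANDARD),
                 rep(seq_len(9L), each = length(peptides)))
    scores <- rowSums(matrix(pssm[idx], ncol = 9L))
    rank <- 100 * stats::pnorm(scores, mean = mu, sd = sigma, lower.tail = FALSE)
    tibble::tibble(peptide = peptides, allele = al,
                   percentile_rank = pmin(pmax(rank, 1e-6), 100))
  })
  dplyr::bind_rows(res)
}

#' Percentile ranks for peptide-allele pairs
#'
#' Dispatches to a predictor (precomputed table or built-in toy matrix model),
#' returning a complete rank map over the supported alleles. Unsupported
#' alleles are not silently skipped: they are recorded in the
#' `"unsupported_alleles"` attribute and reported as a warning.
#'
#' @param peptides Character vector of 9-mers.
#' @param alleles HLA allele names (any resolution; normalized to two-field).
#' @param predictor A predictor object (see [rank_table_predictor()],
#'   [toy_pssm_predictor()]).
#' @return Tibble `peptide`, `allele`, `percentile_rank` with ranks in
#'   (0, 100].
#' @export
predict_percentile_ranks <- function(peptides, alleles, predictor = toy_pssm_predictor()) {
  peptides <- unique(peptides)
  alleles <- unique(stats::na.omit(normalize_hla_allele(alleles)))
  if (!length(peptides) || !length(alleles)) {
    out <- tibble::tibble(peptide = character(), allele = character(),
                          percentile_rank = numeric())
    attr(out, "unsupported_alleles") <- character(0)
    return(out)
  }
  supported <- supports_alleles(predictor, alleles)
  unsupported <- alleles[!supported]
  if (length(unsupported)) {
    warning("allele(s) unsupported by the affinity predictor: ",
            paste(unsupported, collapse = ", "), call. = FALSE)
  }
  out <- if (any(supported)) {
    compute_ranks(predictor, peptides, alleles[supported])
  } else {
    tibble::tibble(peptide = character(), allele = character(), percentile_rank = numeric())
  }
  attr(out, "unsupported_alleles") <- unsupported
  out
}

#' Count distinct peptides predicted as high-affinity binders
#'
#' A peptide counts if its percentile rank is at or below the cutoff for at
#' least one of the recipient's alleles at the configured loci.
#'
#' @param rank_map Tibble from [predict_percentile_ranks()].
#' @param recipient_alleles Recipient allele names (will be normalized and
#'   restricted to `config$loci`).
#' @param config An [affinity_config()].
#' @return Integer count.
#' @export
count_high_affinity <- function(rank_map, recipient_alleles, config = affinity_config()) {
  alleles <- unique(stats::na.omit(normalize_hla_allele(recipient_alleles)))
  alleles <- alleles[hla_locus(alleles) %in% config$loci]
  hits <- rank_map$allele %in% alleles & rank_map$percentile_rank <= config$rank_cutoff
  length(unique(rank_map$peptide[hits]))
}
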