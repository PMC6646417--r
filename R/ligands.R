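#' Normalize an HLA allele name to two-field resolution
#'
#' Accepts names like `"HLA-A*01:01:01:02"`, `"A*01:01"` or `"B*07:02"` and
#' returns the locus plus the first two fields (`"A*01:01"`). Higher-resolution
#' fields are truncated; unparseable names give `NA` with a warning.
#'
#' @param allele Character vector of allele names.
#' @return Character vector of normalized names.
#' @export
normalize_hla_allele <- function(allele) {
  x <- toupper(trimws(as.character(allele)))
  x <- sub("^HLA-", "", x)
  m <- regexec("^([A-Z]+[0-9]*)\\*([0-9]+):([0-9]+)", x)
  out <- vapply(regmatches(x, m), function(g) {
    if (length(g) == 4L) paste0(g[2], "*", g[3], ":", g[4]) else NA_character_
  }, character(1))
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  if (any(bad)) {
    warning("unparseable HLA allele name(s): ",
            paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

hla_locus <- function(allele) sub("\\*.*$", "", allele)

new_ligand_db <- function(kind, ligands) {
  structure(list(kind = kind, ligands = ligands), class = "ligand_db")
}

#' @export
print.ligand_db <- function(x, ...) {
  cat("<ligand_db kind=", x$kind, "> ", length(x$ligands), " alleles, ",
      sum(lengths(x$ligands)), " 9-mer ligands\n", sep = "")
  invisible(x)
}

build_ligand_db <- function(kind, peptide, allele, ninemerize) {
  peptide <- toupper(trimws(peptide))
  allele <- normalize_hla_allele(allele)
  ok <- !is.na(allele) & nzchar(peptide) & !grepl("[^A-Z]", peptide)
  peptide <- peptide[ok]; allele <- allele[ok]
  if (ninemerize) {
    short <- nchar(peptide) < 9L
    if (any(short)) {
      warning(sum(short), " peptide(s) shorter than 9 residues dropped", call. = FALSE)
    }
    frames <- lapply(peptide[!short], nine_merize_peptide)
    allele <- rep(allele[!short], lengths(frames))
    peptide <- unlist(frames, use.names = FALSE)
  } else {
    keep <- nchar(peptide) == 9L
    peptide <- peptide[keep]; allele <- allele[keep]
  }
  if (!length(peptide)) return(new_ligand_db(kind, list()))
  ligands <- lapply(split(peptide, allele), function(p) sort(unique(p)))
  new_ligand_db(kind, ligands[order(names(ligands))])
}

#' Parse an IEDB-style ligand export into an allele-keyed 9-mer database
#'
#' Applies the three inclusion filters used when curating experimental HLA
#' class I ligand data: human host organism, qualitative measure "positive" or
#' "positive-high" (case-insensitive), and available HLA allele information.
#' Peptides are deduplicated per allele. By default only 9-mer entries are
#' retained; set `ninemerize = TRUE` to instead expand longer entries into all
#' their 9-mer frames.
#'
#' @param path Path to a TSV file (gzipped accepted).
#' @param col_map Named character vector mapping the logical columns
#'   `peptide`, `allele`, `qualitative_measure`, `host_organism` to the file's
#'   column names. Defaults to those literal names; real IEDB full-export
#'   headers (e.g. `Description`, `Allele Name`, `Qualitative Measure`,
#'   `Organism Name`) can be supplied here.
#' @param ninemerize Expand longer peptides into 9-mer frames instead of
#'   dropping them (default `FALSE`).
#' @return A `ligand_db` of kind `"iedb"`.
#' @export
parse_iedb_table <- function(path,
                             col_map = c(peptide = "peptide",
                                         allele = "allele",
                                         qualitative_measure = "qualitative_measure",
                                         host_organism = "host_organism"),
                             ninemerize = FALSE) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("peptide", "allele", "qualitative_measure", "host_organism")
  missing_cols <- setdiff(col_map[need], names(tbl))
  if (length(missing_cols)) {
    stop("required column(s) missing from ligand table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) == 0L) {
    warning("empty ligand table: ", path, call. = FALSE)
    return(new_ligand_db("iedb", list()))
  }
  host <- tolower(tbl[[col_map[["host_organism"]]]])
  qual <- tolower(trimws(tbl[[col_map[["qualitative_measure"]]]]))
  allele <- tbl[[col_map[["allele"]]]]
  keep <- grepl("homo sapiens", host, fixed = TRUE) &
    qual %in% c("positive", "positive-high") &
    !is.na(allele) & nzchar(trimws(allele))
  build_ligand_db("iedb",
                  peptide = tbl[[col_map[["peptide"]]]][keep],
                  allele = allele[keep],
                  ninemerize = ninemerize)
}

#' Expand a peptide into all 9-mer frames
#'
#' @param peptide Amino-acid string of length >= 9; shorter peptides are
#'   dropped with a warning.
#' @param k Frame length (default 9).
#' @return Character vector of unique k-mer frames.
#' @export
nine_merize_peptide <- function(peptide, k = 9L) {
  n <- nchar(peptide)
  if (n < k) {
    warning("peptide shorter than ", k, " residues dropped: ", peptide, call. = FALSE)
    return(character(0))
  }
  unique(stringi::stri_sub(peptide, seq_len(n - k + 1L), length = k))
}

#' Parse a published minor histocompatibility antigen table
#'
#' Reads a TSV with `peptide` and `allele` (restricting allele) columns,
#' expands peptides longer than 9 residues into all 9-mer frames, and removes
#' duplicates per allele.
#'
#' @param path Path to a TSV file.
#' @param col_map Named character vector mapping `peptide` and `allele` to the
#'   file's column names.
#' @return A `ligand_db` of kind `"mha"`.
#' @export
parse_mha_table <- function(path, col_map = c(peptide = "peptide", allele = "allele")) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(col_map[c("peptide", "allele")], names(tbl))
  if (length(missing_cols)) {
    stop("required column(s) missing from mHA table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) == 0L) {
    warning("empty mHA table: ", path, call. = FALSE)
    return(new_ligand_db("mha", list()))
  }
  build_ligand_db("mha",
                  peptide = tbl[[col_map[["peptide"]]]],
                  allele = tbl[[col_map[["allele"]]]],
                  ninemerize = TRUE)
}

#' Fraction of cohort HLA alleles represented in a ligand database
#'
#' @param cohort_alleles Character vector of allele names carried by the
#'   cohort (duplicates allowed; normalized to two-field resolution).
#' @param db A `ligand_db`.
#' @param by_locus If `TRUE`, return a tibble with one coverage row per locus.
#' @return Percentage in `[0, 100]`, or a tibble if `by_locus`.
#' @export
allele_coverage <- function(cohort_alleles, db, by_locus = FALSE) {
  alleles <- unique(stats::na.omit(normalize_hla_allele(cohort_alleles)))
  if (length(alleles) == 0L) stop("empty cohort allele set", call. = FALSE)
  covered <- alleles %in% names(db$ligands)[lengths(db$ligands) > 0L]
  if (!by_locus) return(100 * mean(covered))
  tibble::tibble(locus = hla_locus(alleles), covered = covered) |>
    dplyr::summarise(
      n_alleles = dplyr::n(),
      coverage_pct = 100 * mean(.data$covered),
      .by = "locus"
    ) |>
    dplyr::arrange(.data$locus)
}

#' Pool a ligand database over a set of HLA alleles
#'
#' @param db A `ligand_db`.
#' @param alleles Allele names to pool over; `NULL` pools the whole database.
#' @return Character vector of unique 9-mer ligands.
#' @export
pool_ligands <- function(db, alleles = NULL) {
  if (is.null(alleles)) return(unique(unlist(db$ligands, use.names = FALSE)))
  alleles <- unique(stats::na.omit(normalize_hla_allele(alleles)))
  unique(unlist(db$ligands[intersect(alleles, names(db$ligands))], use.names = FALSE))
}

#' Write a ligand database to TSV (peptide, allele)
#'
#' @param db A `ligand_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ligand_db <- function(db, path) {
  tbl <- tibble::tibble(
    peptide = unlist(db$ligands, use.names = FALSE),
    allele = rep(names(db$ligands), lengths(db$ligands))
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}
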