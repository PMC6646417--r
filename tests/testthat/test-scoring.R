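mk_peptides <- function(peptide, tx = "T1", gene = "G1") {
  structure(
    tibble::tibble(peptide = peptide,
                   source_transcripts = replicate(length(peptide), as.character(tx), simplify = FALSE),
                   source_genes = replicate(length(peptide), as.character(gene), simplify = FALSE)),
    class = c("mismatched_peptides", class(tibble::tibble()))
  )
}

test_that("tissue-expression filtering keeps any-source supportive records in target tissues", {
  expr <- tibble::tibble(
    gene = c("G1", "G2", "G3"),
    transcript = NA_character_,
    tissue = c("skin", "liver", "brain"),
    reliability = c("Supportive", "Uncertain", "Supportive")
  )
  peps <- dplyr::bind_rows(mk_peptides("AAAAAAAAA", gene = "G1"),
                           mk_peptides("CCCCCCCCC", gene = "G2"),
                           mk_peptides("DDDDDDDDD", gene = "G3"))
  peps <- structure(peps, class = c("mismatched_peptides", class(tibble::tibble())))
  out <- filter_by_expression(peps, expr)
  expect_equal(out$peptide, "AAAAAAAAA")   # G2 unreliable, G3 wrong tissue

  # any-source rule: one passing gene among two rescues the peptide
  multi <- structure(
    tibble::tibble(peptide = "EEEEEEEEE",
                   source_transcripts = list(c("T2", "T3")),
                   source_genes = list(c("G2", "G1"))),
    class = c("mismatched_peptides", class(tibble::tibble()))
  )
  expect_equal(nrow(filter_by_expression(multi, expr)), 1L)

  # transcript-level records provide an additional matching route
  expr_tx <- tibble::tibble(gene = "GX", transcript = "T9",
                            tissue = "lung", reliability = "Supportive")
  tx_pep <- structure(
    tibble::tibble(peptide = "FFFFFFFFF",
                   source_transcripts = list("T9"), source_genes = list("GOTHER")),
    class = c("mismatched_peptides", class(tibble::tibble()))
  )
  expect_equal(nrow(filter_by_expression(tx_pep, expr_tx)), 1L)

  expect_error(filter_by_expression(peps, expr[0, ]), "missing or empty")
  expect_error(filter_by_expression(peps, NULL), "missing or empty")
})

test_that("method counts intersect allele-pooled databases correctly", {
  u <- mk_peptides(c("AAAAAAAAA", "CCCCCCCCC"))
  typing <- full_typing("R")
  iedb <- make_ligand_db("iedb", list("A*01:01" = "CCCCCCCCC",
                                      "C*05:01" = "AAAAAAAAA"))  # C*05:01 not carried
  mha <- make_ligand_db("mha", list())
  expr <- tibble::tibble(gene = "G1", transcript = NA_character_,
                         tissue = "skin", reliability = "Supportive")
  est <- compute_method_counts("P1", u, typing, iedb, mha, expr,
                               imm_model = immunogenicity_model(threshold = -Inf),
                               predictor = toy_pssm_predictor())
  expect_equal(est$m1, 1L)       # only the ligand under a carried allele
  expect_equal(est$m3, 0L)       # empty mHA database
  expect_equal(est$total_mismatched, 2L)
  expect_equal(est$total_filtered, 2L)

  # unrestricted mode sees the C*05:01 ligand too
  est2 <- compute_method_counts("P1", u, typing, iedb, mha, expr,
                                imm_model = immunogenicity_model(threshold = -Inf),
                                restrict_to_recipient_hla = FALSE)
  expect_equal(est2$m1, 2L)

  # empty peptide set: every estimator is zero
  est0 <- compute_method_counts("P1", u[0, ], typing, iedb, mha, expr)
  expect_equal(unlist(est0[, c("m1", "m2", "m3", "m4")]), c(m1 = 0L, m2 = 0L, m3 = 0L, m4 = 0L))
})

test_that("non-strict mode reports NA for failing estimators and keeps the rest", {
  u <- mk_peptides("AAAAAAAAA")
  typing <- full_typing("R")
  iedb <- make_ligand_db("iedb", list("A*01:01" = "AAAAAAAAA"))
  mha <- make_ligand_db("mha", list())
  est <- compute_method_counts("P1", u, typing, iedb, mha, expression = NULL,
                               strict = FALSE)
  expect_equal(est$m1, 1L)
  expect_equal(est$m3, 0L)
  expect_true(is.na(est$m2) && is.na(est$m4) && is.na(est$total_filtered))
  expect_match(attr(est, "estimate_errors")[["filter"]], "expression")
  expect_error(compute_method_counts("P1", u, typing, iedb, mha, expression = NULL,
                                     strict = TRUE), "expression")
})

test_that("method counts match a brute-force set oracle on randomized micro-universes", {
  set.seed(41)
  weights_tbl <- readr::read_tsv(
    system.file("extdata", "immunogenicity_residue_weights_v1.1.tsv", package = "allopep"),
    show_col_types = FALSE
  )
  model <- immunogenicity_model()
  for (i in 1:30) {
    n_pep <- sample(5:50, 1L)
    universe <- unique(replicate(
      n_pep, paste(sample(allopep:::AA_STANDARD, 9, replace = TRUE), collapse = "")
    ))
    genes <- paste0("G", sample(1:6, length(universe), replace = TRUE))
    u <- structure(
      tibble::tibble(peptide = universe,
                     source_transcripts = as.list(paste0("T", seq_along(universe))),
                     source_genes = as.list(genes)),
      class = c("mismatched_peptides", class(tibble::tibble()))
    )
    alleles <- c("A*01:01", "A*02:01", "B*07:02")
    typing <- full_typing("R", A = alleles[1:2], B = c(alleles[3], alleles[3]))
    iedb <- make_ligand_db("iedb", lapply(
      stats::setNames(nm = alleles),
      function(a) unique(sample(universe, sample(0:length(universe), 1L), replace = FALSE))
    ))
    mha <- make_ligand_db("mha", list("B*07:02" = sample(universe, min(3, length(universe)))))
    expr <- tibble::tibble(gene = unique(genes)[seq_len(ceiling(length(unique(genes)) / 2))],
                           transcript = NA_character_,
                           tissue = "skin", reliability = "Supportive")
    ranks <- tidyr::expand_grid(peptide = universe, allele = alleles)
    ranks$percentile_rank <- stats::runif(nrow(ranks), 0.1, 100)
    est <- compute_method_counts("P", u, typing, iedb, mha, expr,
                                 imm_model = model,
                                 predictor = rank_table_predictor(ranks),
                                 affinity = affinity_config(rank_cutoff = 20))

    # oracle: explicit loops and set operations
    rec_class1 <- unique(c(alleles[1:2], alleles[3]))
    iedb_pool <- unique(unlist(iedb$ligands[rec_class1]))
    mha_pool <- unique(unlist(mha$ligands[rec_class1]))
    pass_imm <- universe[vapply(universe, function(p)
      oracle_imm_score(p, weights_tbl, model$position_weights) > 0.2, logical(1))]
    pass_expr <- universe[genes %in% expr$gene]
    f <- intersect(pass_imm, pass_expr)
    m4_oracle <- sum(vapply(f, function(p) {
      any(ranks$percentile_rank[ranks$peptide == p &
                                  ranks$allele %in% c("A*01:01", "A*02:01", "B*07:02")] <= 20)
    }, logical(1)))
    expect_equal(est$m1, length(intersect(universe, iedb_pool)))
    expect_equal(est$m2, length(intersect(f, iedb_pool)))
    expect_equal(est$m3, length(intersect(universe, mha_pool)))
    expect_equal(est$total_filtered, length(f))
    expect_equal(est$m4, m4_oracle)

    # subset structure
    expect_lte(est$m2, est$m1)
    expect_lte(est$m2, est$total_filtered)
    expect_lte(est$m4, est$total_filtered)
    expect_lte(est$total_filtered, est$total_mismatched)
  }
})
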