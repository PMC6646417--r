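test_that("reference generation is deterministic and passes the CDS filters by construction", {
  cfg <- simulation_config(n_transcripts = 15L, seed = 5L)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  p1 <- tempfile(fileext = ".fa"); p2 <- tempfile(fileext = ".fa")
  write_cds_fasta(r1, p1); write_cds_fasta(r2, p2)
  expect_identical(readLines(p1), readLines(p2))

  back <- read_cds_fasta(p1)   # no rejection message expected
  expect_equal(nrow(back), 15L)
  expect_true(all(startsWith(r1$cds, "ATG")))
  expect_true(all(nchar(r1$cds) %% 3 == 0))
  expect_true(all(nchar(r1$cds) >= cfg$cds_length_range[1]))
  # terminal stop, no internal in-frame stop
  prot <- translate_reference(r1)
  expect_true(all(nchar(prot) == nchar(r1$cds) / 3 - 1))

  r0 <- generate_reference(simulation_config(n_transcripts = 0L))
  expect_equal(nrow(r0), 0L)
})

test_that("pair variants are valid edits with Poisson-scale counts and working shared fraction", {
  cfg <- simulation_config(n_transcripts = 120L, per_transcript_variant_rate = 0.5,
                           shared_variant_fraction = 0.6, synonymous_rate = 0,
                           low_dp_fraction = 0, low_gq_fraction = 0, seed = 9L)
  ref <- generate_reference(cfg)
  ev <- generate_pair_variants(ref, "P001", cfg)
  expect_true(all(ev$effect %in% c(allopep:::VALID_EFFECTS, "synonymous_variant")))
  # every ref allele matches the CDS (apply succeeds on each haplotype)
  for (tx in unique(ev$transcript_id)) {
    vt <- ev[ev$transcript_id == tx & ev$sample_id == "P001_D" & ev$dosage > 0, ]
    cds <- ref$cds[ref$transcript_id == tx]
    expect_no_error(apply_variants_to_cds(cds, vt, tx))
  }
  # distributional check: per-subject carried-variant count ~ Poisson(n_tx * rate)
  lambda <- 120 * 0.5
  for (s in c("P001_D", "P001_R")) {
    n_s <- sum(ev$sample_id == s & ev$dosage > 0)
    expect_lt(abs(n_s - lambda), 3 * sqrt(lambda) + 3)
  }

  # zero rate: donor and recipient identical, no mismatched peptides
  cfg0 <- simulation_config(n_transcripts = 10L, per_transcript_variant_rate = 0,
                            synonymous_rate = 0, seed = 2L)
  ref0 <- generate_reference(cfg0)
  expect_equal(nrow(generate_pair_variants(ref0, "P001", cfg0)), 0L)

  # fully shared variants: zero mismatched peptides end to end
  cfg1 <- simulation_config(n_transcripts = 15L, shared_variant_fraction = 1,
                            synonymous_rate = 0, seed = 3L)
  ref1 <- generate_reference(cfg1)
  ev1 <- generate_pair_variants(ref1, "P001", cfg1)
  v1 <- allopep:::new_variant_calls(ev1[ev1$effect %in% allopep:::VALID_EFFECTS, ])
  d <- build_individual_proteome("P001_D", ref1, v1)
  r <- build_individual_proteome("P001_R", ref1, v1)
  expect_equal(nrow(recipient_unique_peptides(d, r)), 0L)
})

test_that("VCF writing round-trips through the annotated-VCF reader", {
  cfg <- simulation_config(n_transcripts = 25L, seed = 13L)
  ref <- generate_reference(cfg)
  ev <- generate_pair_variants(ref, "P001", cfg)
  p <- tempfile(fileext = ".vcf")
  write_pair_vcf(ev, p)
  back <- read_annotated_vcf(p, samples = c("P001_D", "P001_R"))
  want <- ev[ev$effect %in% allopep:::VALID_EFFECTS, ]
  key <- function(x) paste(x$transcript_id, x$cds_pos, x$ref, x$alt, x$sample_id, x$dosage)
  expect_setequal(key(back), key(want))
  expect_equal(nrow(back), nrow(want))
})

test_that("typing generation yields HLA-identical siblings except a configured mismatch fraction", {
  cfg <- simulation_config(n_pairs = 30L, hla_mismatch_fraction = 0, seed = 17L)
  typ <- generate_hla_typings(cfg)
  expect_equal(nrow(typ), 60L)
  matches <- vapply(sprintf("P%03d", 1:30), function(pid) {
    count_hla_matches(hla_typing_of(typ, paste0(pid, "_D")),
                      hla_typing_of(typ, paste0(pid, "_R")))
  }, numeric(1))
  expect_true(all(matches == 12))
  expect_identical(generate_hla_typings(cfg), typ)

  cfg2 <- simulation_config(n_pairs = 200L, hla_mismatch_fraction = 0.5, seed = 18L)
  typ2 <- generate_hla_typings(cfg2)
  matches2 <- vapply(sprintf("P%03d", 1:200), function(pid) {
    count_hla_matches(hla_typing_of(typ2, paste0(pid, "_D")),
                      hla_typing_of(typ2, paste0(pid, "_R")))
  }, numeric(1))
  frac <- mean(matches2 < 12)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 200) + 0.05)
  expect_true(all(matches2 >= 9))
})

test_that("resource planting controls the ligand overlap", {
  cfg <- simulation_config(n_pairs = 2L, seed = 19L)
  typ <- generate_hla_typings(cfg)
  u <- list(P001 = replicate(50, paste(sample(allopep:::AA_STANDARD, 9, TRUE), collapse = "")),
            P002 = replicate(50, paste(sample(allopep:::AA_STANDARD, 9, TRUE), collapse = "")))

  # no planting: ligand DB is disjoint decoys, so m1 = 0
  cfg0 <- simulation_config(n_pairs = 2L, planted_overlap = 0, mha_overlap = 0, seed = 19L)
  res0 <- generate_resources(u, typ, generate_reference(cfg0), cfg0)
  keep <- res0$iedb$host_organism == "Homo sapiens" &
    tolower(res0$iedb$qualitative_measure) %in% c("positive", "positive-high") &
    nzchar(res0$iedb$allele)
  expect_length(intersect(res0$iedb$peptide[keep], unlist(u)), 0L)

  # full planting: every recipient-unique peptide is in the DB under a carried allele
  cfg1 <- simulation_config(n_pairs = 2L, planted_overlap = 1, seed = 19L)
  res1 <- generate_resources(u, typ, generate_reference(cfg1), cfg1)
  iedb_db <- allopep:::build_ligand_db("iedb", res1$iedb$peptide, res1$iedb$allele, FALSE)
  for (pid in names(u)) {
    rec <- hla_typing_of(typ, paste0(pid, "_R"))
    pool <- pool_ligands(iedb_db, typing_alleles(rec, loci = c("A", "B", "C")))
    expect_true(all(u[[pid]] %in% pool))
  }

  # intermediate planting: pooled overlap close to its binomial expectation
  cfg5 <- simulation_config(n_pairs = 2L, planted_overlap = 0.4, seed = 23L)
  res5 <- generate_resources(u, typ, generate_reference(cfg5), cfg5)
  planted_n <- length(intersect(res5$iedb$peptide, unlist(u)))
  expect_lt(abs(planted_n - 0.4 * 100), 3 * sqrt(100 * 0.4 * 0.6) + 1)

  # rank table covers every peptide x its recipient's A/B alleles, in (0, 100]
  expect_true(all(res1$ranks$percentile_rank > 0 & res1$ranks$percentile_rank <= 100))
  ab1 <- typing_alleles(hla_typing_of(typ, "P001_R"), loci = c("A", "B"), unique_only = TRUE)
  covered <- res1$ranks[res1$ranks$peptide %in% u$P001 & res1$ranks$allele %in% ab1, ]
  expect_equal(nrow(covered), length(u$P001) * length(ab1))  # complete grid
})

test_that("outcome generation follows the logistic model and degenerates sensibly", {
  set.seed(1)
  est <- tibble::tibble(pair_id = sprintf("P%03d", 1:400),
                        m1 = rpois(400, 300), m2 = rpois(400, 20), m3 = rpois(400, 3),
                        m4 = rpois(400, 40), total_mismatched = rpois(400, 5000),
                        total_filtered = rpois(400, 1500))
  cov <- tibble::tibble(pair_id = est$pair_id,
                        hla_freq_sum = rnorm(400, 6), n_unique_hla = sample(7:12, 400, TRUE),
                        donor_age = rnorm(400, 45, 8), tr_year = sample(2001:2015, 400, TRUE),
                        f_to_m = runif(400) < 0.2, hla_match_count = 12L)
  cfg <- simulation_config(n_pairs = 400L, effect_beta = 2, limited_fraction = 0.1,
                           covariate_betas = c(hla_freq_sum = 0, n_unique_hla = 0,
                                               donor_age = 0, tr_year = 0, f_to_m = 0,
                                               hla_match_count = 0, mismatch = 0),
                           intercept = 0, seed = 29L)
  out <- generate_outcomes(est, cov, cfg)
  expect_setequal(setdiff(unique(out$cgvhd_grade), "limited"), c("no", "extensive"))
  lim_frac <- mean(out$cgvhd_grade == "limited")
  expect_lt(abs(lim_frac - 0.1), 3 * sqrt(0.1 * 0.9 / 400) + 0.01)
  # strong positive effect: extensive cases have higher m1
  non_lim <- out$cgvhd_grade != "limited"
  expect_gt(mean(est$m1[non_lim & out$cgvhd_grade == "extensive"]),
            mean(est$m1[non_lim & out$cgvhd_grade == "no"]))

  # impossible severity: single-class outcome raises downstream
  cfg_none <- cfg; cfg_none$intercept <- -Inf; cfg_none$effect_beta <- 0
  out_none <- generate_outcomes(est, cov, cfg_none)
  expect_false(any(out_none$cgvhd_grade == "extensive"))
  d <- dplyr::inner_join(dplyr::inner_join(est, cov, "pair_id"), out_none, "pair_id")
  expect_error(suppressWarnings(run_association_suite(d)), "single class|both 'no' and 'extensive'")
})

test_that("full-bundle simulation is deterministic on disk", {
  cfg <- simulation_config(n_pairs = 3L, n_transcripts = 12L, seed = 31L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  s1 <- simulate_cohort(cfg, d1)
  s2 <- simulate_cohort(cfg, d2)
  expect_equal(s1$estimates, s2$estimates)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)), label = f)
  }
})
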