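# Synthetic-cohort generator. Produces a complete sibling-transplant study --
# CDS reference, paired annotated VCFs, HLA typings, ligand / mHA /
# expression / affinity-rank tables and outcomes drawn from a known logistic
# model -- in exactly the formats the pipeline consumes, so every stage is
# testable without patient data. Every generator is a pure function of
# (config, seed); random streams are split per stage.

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

NON_STOP_CODONS <- setdiff(all_codons(), STOP_CODONS)

#' Built-in HLA allele pool with population frequencies
#'
#' A compact per-locus pool of common European-ancestry alleles used for
#' sampling synthetic typings; frequencies are normalized per locus at
#' sampling time. Not a faithful population spectrum.
#'
#' @return Tibble with columns `locus`, `allele`, `freq`.
#' @export
default_allele_pool <- function() {
  tibble::tribble(
    ~locus, ~allele, ~freq,
    "A", "A*01:01", 0.17, "A", "A*02:01", 0.27, "A", "A*03:01", 0.14,
    "A", "A*11:01", 0.06, "A", "A*24:02", 0.10, "A", "A*26:01", 0.05,
    "B", "B*07:02", 0.14, "B", "B*08:01", 0.12, "B", "B*15:01", 0.08,
    "B", "B*18:01", 0.05, "B", "B*35:01", 0.07, "B", "B*40:01", 0.08,
    "B", "B*44:02", 0.07, "B", "B*27:05", 0.04,
    "C", "C*03:04", 0.10, "C", "C*04:01", 0.12, "C", "C*05:01", 0.08,
    "C", "C*06:02", 0.09, "C", "C*07:01", 0.15, "C", "C*07:02", 0.16,
    "DRB1", "DRB1*01:01", 0.10, "DRB1", "DRB1*03:01", 0.12,
    "DRB1", "DRB1*04:01", 0.10, "DRB1", "DRB1*07:01", 0.11,
    "DRB1", "DRB1*13:01", 0.09, "DRB1", "DRB1*15:01", 0.16,
    "DQB1", "DQB1*02:01", 0.14, "DQB1", "DQB1*03:01", 0.18,
    "DQB1", "DQB1*03:02", 0.10, "DQB1", "DQB1*05:01", 0.13,
    "DQB1", "DQB1*06:02", 0.16,
    "DPB1", "DPB1*01:01", 0.10, "DPB1", "DPB1*02:01", 0.22,
    "DPB1", "DPB1*03:01", 0.11, "DPB1", "DPB1*04:01", 0.36,
    "DPB1", "DPB1*04:02", 0.12
  )
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions where stated (157 sibling pairs;
#' HLA-identical siblings with a small mismatched minority; chronic GvHD
#' grades no/limited/extensive with "limited" around 15%; a positive
#' ligand-count effect on severe chronic GvHD) and desk-scale choices
#' elsewhere (reference size, variant rates, database sizes), documented in
#' the methods vignette.
#'
#' @param n_pairs Number of donor-recipient pairs.
#' @param n_transcripts Reference transcripts.
#' @param cds_length_range CDS length range in nucleotides (rounded to
#'   codons).
#' @param per_transcript_variant_rate Expected non-synonymous variants per
#'   transcript per subject.
#' @param shared_variant_fraction Probability a donor variant is shared with
#'   the recipient (identical genotype).
#' @param synonymous_rate Expected synonymous decoy annotations per
#'   transcript (exercise the consequence filter).
#' @param effect_weights Sampling weights over missense, insertion, deletion,
#'   frameshift, stop_gained.
#' @param het_fraction Probability a carried variant is heterozygous.
#' @param dp_mean Mean simulated read depth.
#' @param low_dp_fraction,low_gq_fraction Fractions of genotypes emitted
#'   below the default DP/GQ cutoffs.
#' @param dp_min,gq_min Genotype hard-filter thresholds applied by the
#'   pipeline.
#' @param allele_pool Allele frequency pool, see [default_allele_pool()].
#' @param hla_mismatch_fraction Fraction of pairs with 1-3 mismatched
#'   alleles (rest are 12/12 HLA-identical siblings).
#' @param ligand_db_size Decoy 9-mers per class I allele in the synthetic
#'   ligand database.
#' @param planted_overlap Probability a recipient-unique peptide is planted
#'   into the ligand database under one of that recipient's class I alleles.
#' @param mha_overlap As `planted_overlap`, for the mHA table.
#' @param mha_decoys Decoy mHA entries (9-12-mers).
#' @param expr_supportive_fraction Fraction of genes with a "Supportive"
#'   record in a GvHD target tissue.
#' @param rank_high_fraction Fraction of (peptide, allele) affinity ranks
#'   drawn below the high-affinity cutoff.
#' @param limited_fraction Probability a pair is graded "limited"
#'   (independently of the severity model; these pairs are excluded from
#'   association).
#' @param effect_beta Log-odds of extensive chronic GvHD per SD of the
#'   ligand count.
#' @param effect_method Which estimator carries the planted effect.
#' @param covariate_betas Named log-odds for hla_freq_sum, n_unique_hla,
#'   donor_age, tr_year, f_to_m, hla_match_count, mismatch (scaled scales;
#'   f_to_m per unit).
#' @param intercept Model intercept (log-odds).
#' @param seed Master seed; per-stage streams are derived from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 157L,
                              n_transcripts = 60L,
                              cds_length_range = c(300L, 900L),
                              per_transcript_variant_rate = 0.8,
                              shared_variant_fraction = 0.85,
                              synonymous_rate = 0.2,
                              effect_weights = c(missense = 0.70, insertion = 0.08,
                                                 deletion = 0.08, frameshift = 0.10,
                                                 stop_gained = 0.04),
                              het_fraction = 0.67,
                              dp_mean = 35,
                              low_dp_fraction = 0.02,
                              low_gq_fraction = 0.02,
                              dp_min = 15L, gq_min = 20L,
                              allele_pool = default_allele_pool(),
                              hla_mismatch_fraction = 10 / 157,
                              ligand_db_size = 200L,
                              planted_overlap = 0.05,
                              mha_overlap = 0.01,
                              mha_decoys = 40L,
                              expr_supportive_fraction = 0.5,
                              rank_high_fraction = 0.05,
                              limited_fraction = 23 / 151,
                              effect_beta = 0.6,
                              effect_method = "m1",
                              covariate_betas = c(hla_freq_sum = -0.4, n_unique_hla = 0.15,
                                                  donor_age = 0.3, tr_year = 0.1,
                                                  f_to_m = -0.8, hla_match_count = 0.25,
                                                  mismatch = 0),
                              intercept = -0.6,
                              seed = 1L) {
  stopifnot(n_pairs >= 0, n_transcripts >= 0,
            per_transcript_variant_rate >= 0,
            shared_variant_fraction >= 0, shared_variant_fraction <= 1,
            planted_overlap >= 0, planted_overlap <= 1,
            limited_fraction >= 0, limited_fraction < 1)
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

pair_ids_of <- function(config) sprintf("P%03d", seq_len(config$n_pairs))

#' Generate a synthetic CDS reference
#'
#' Each transcript starts with ATG, ends with an in-frame stop codon, has no
#' internal in-frame stop (codons are sampled uniformly from the 61 non-stop
#' codons), and has a codon-rounded length inside `cds_length_range` -- so
#' every record passes the [read_cds_fasta()] filters by construction.
#'
#' @param config A [simulation_config()].
#' @return A `cds_reference` tibble.
#' @export
generate_reference <- function(config = simulation_config()) {
  with_stage_seed(config$seed, "reference", {
    n <- config$n_transcripts
    if (n == 0L) {
      return(new_cds_reference(tibble::tibble(
        transcript_id = character(), gene_id = character(), cds = character()
      )))
    }
    lo <- max(2L, config$cds_length_range[1] %/% 3L)
    hi <- max(lo, config$cds_length_range[2] %/% 3L)
    n_codons <- sample(lo:hi, n, replace = TRUE)
    cds <- vapply(n_codons, function(nc) {
      paste0("ATG",
             paste(sample(NON_STOP_CODONS, nc - 2L, replace = TRUE), collapse = ""),
             sample(STOP_CODONS, 1L))
    }, character(1))
    new_cds_reference(tibble::tibble(
      transcript_id = sprintf("TXS%04d", seq_len(n)),
      gene_id = sprintf("GENES%04d", seq_len(n)),
      cds = cds
    ))
  })
}

codon_at <- function(cds, codon_idx) substr(cds, 3L * (codon_idx - 1L) + 1L, 3L * codon_idx)

translate_codon <- function(codon) unname(CODON_TABLE[codon])

# Construct a VCF-style left-anchored edit of the requested effect class at
# the given codon. Assumes the codon is internal (index >= 3) and non-stop.
make_edit <- function(cds, codon_idx, class) {
  start <- 3L * (codon_idx - 1L) + 1L
  anchor_pos <- start - 1L
  anchor <- substr(cds, anchor_pos, anchor_pos)
  switch(class,
    missense = {
      ref_codon <- codon_at(cds, codon_idx)
      ref_aa <- translate_codon(ref_codon)
      for (off in sample(0:2)) {
        pos <- start + off
        ref <- substr(cds, pos, pos)
        for (alt in sample(setdiff(c("A", "C", "G", "T"), ref))) {
          new_codon <- ref_codon
          substr(new_codon, off + 1L, off + 1L) <- alt
          aa <- translate_codon(new_codon)
          if (aa != "*" && aa != ref_aa) {
            return(list(cds_pos = pos, ref = ref, alt = alt, effect = "missense"))
          }
        }
      }
      NULL
    },
    stop_gained = {
      ref_codon <- codon_at(cds, codon_idx)
      list(cds_pos = start, ref = ref_codon, alt = sample(STOP_CODONS, 1L),
           effect = "stop_gained")
    },
    insertion = list(cds_pos = anchor_pos, ref = anchor,
                     alt = paste0(anchor, sample(NON_STOP_CODONS, 1L)),
                     effect = "insertion"),
    deletion = list(cds_pos = anchor_pos,
                    ref = paste0(anchor, codon_at(cds, codon_idx)),
                    alt = anchor, effect = "deletion"),
    frameshift = {
      len <- sample(1:2, 1L)
      if (stats::runif(1) < 0.5) {
        list(cds_pos = anchor_pos, ref = anchor,
             alt = paste0(anchor, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                        collapse = "")),
             effect = "frameshift")
      } else {
        list(cds_pos = anchor_pos,
             ref = substr(cds, anchor_pos, anchor_pos + len),
             alt = anchor, effect = "frameshift")
      }
    },
    synonymous_variant = {
      # label-only decoy; the substitution is real but reported as synonymous
      pos <- start
      ref <- substr(cds, pos, pos)
      list(cds_pos = pos, ref = ref,
           alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1L),
           effect = "synonymous_variant")
    }
  )
}

sim_genotype_fields <- function(n, config) {
  dp <- stats::rpois(n, config$dp_mean)
  low_dp <- stats::runif(n) < config$low_dp_fraction
  dp[low_dp] <- sample(0:(config$dp_min - 1L), sum(low_dp), replace = TRUE)
  gq <- rep(99, n)
  low_gq <- stats::runif(n) < config$low_gq_fraction
  gq[low_gq] <- sample(0:(config$gq_min - 1L), sum(low_gq), replace = TRUE)
  list(dp = dp, gq = gq)
}

#' Generate one pair's annotated variants
#'
#' Per transcript, the donor draws Poisson(`rate`) non-synonymous variants, a
#' `shared_variant_fraction` of which are shared with the recipient at
#' identical genotype; the recipient additionally draws
#' Poisson(`rate * (1 - shared_variant_fraction)`) private variants, so both
#' subjects' marginal counts are Poisson(`rate`). Synonymous decoy
#' annotations and a small fraction of low-DP/GQ genotypes are included to
#' exercise the consequence and quality filters. Variant positions are
#' spaced at least two codons apart, so edits never overlap.
#'
#' @param reference A `cds_reference`.
#' @param pair_id Pair identifier; samples are named `<pair_id>_D` and
#'   `<pair_id>_R`.
#' @param config A [simulation_config()].
#' @return A `variant_calls` tibble (long format, both samples) including any
#'   synonymous decoy rows.
#' @export
generate_pair_variants <- function(reference, pair_id, config = simulation_config()) {
  with_stage_seed(config$seed, paste0("variants_", pair_id), {
    samples <- paste0(pair_id, c("_D", "_R"))
    rows <- list()
    for (i in seq_len(nrow(reference))) {
      cds <- reference$cds[i]
      n_codons <- nchar(cds) %/% 3L
      if (n_codons < 6L) next
      n_d <- stats::rpois(1L, config$per_transcript_variant_rate)
      shared <- stats::runif(n_d) < config$shared_variant_fraction
      n_r <- stats::rpois(1L, config$per_transcript_variant_rate *
                            (1 - config$shared_variant_fraction))
      n_syn <- stats::rpois(1L, config$synonymous_rate)
      m <- n_d + n_r + n_syn
      if (m == 0L) next
      cand <- seq(3L, n_codons - 2L, by = 2L)
      if (m > length(cand)) m <- length(cand)
      codons <- sample(cand, m)
      carrier <- c(rep("D", min(n_d, m)),
                   rep("R", max(0L, min(n_r, m - n_d))),
                   rep("syn", max(0L, m - n_d - n_r)))
      shared <- c(shared, rep(FALSE, m))[seq_len(m)]
      classes <- ifelse(
        carrier == "syn", "synonymous_variant",
        sample(names(config$effect_weights), m, replace = TRUE,
               prob = config$effect_weights)
      )
      for (j in seq_len(m)) {
        ed <- make_edit(cds, codons[j], classes[j])
        if (is.null(ed)) next
        dosage_carrier <- if (stats::runif(1) < config$het_fraction) 1L else 2L
        in_d <- carrier[j] == "D" || carrier[j] == "syn"
        in_r <- carrier[j] == "R" || shared[j] || carrier[j] == "syn"
        q <- sim_genotype_fields(2L, config)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          transcript_id = reference$transcript_id[i],
          cds_pos = ed$cds_pos, ref = ed$ref, alt = ed$alt, effect = ed$effect,
          sample_id = samples,
          dosage = c(if (in_d) dosage_carrier else 0L,
                     if (in_r) dosage_carrier else 0L),
          dp = q$dp, gq = q$gq, missing = FALSE
        )
      }
    }
    if (!length(rows)) return(empty_variant_calls())
    new_variant_calls(dplyr::bind_rows(rows))
  })
}

#' Write a pair's variants as an annotated VCF
#'
#' Transcript-space VCF 4.2: `CHROM` = transcript id, `POS` = CDS position,
#' `INFO/ANN` = `transcript|effect|pos|ref|alt`, `FORMAT` = `GT:DP:GQ`.
#'
#' @param variants Long-format `variant_calls` for exactly two samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_vcf <- function(variants, path) {
  samples <- unique(variants$sample_id)
  wide <- variants |>
    tidyr::pivot_wider(
      id_cols = c("transcript_id", "cds_pos", "ref", "alt", "effect"),
      names_from = "sample_id",
      values_from = c("dosage", "dp", "gq")
    ) |>
    dplyr::arrange(.data$transcript_id, .data$cds_pos)
  gt_of <- function(d) c("0/0", "0/1", "1/1")[d + 1L]
  body <- vapply(seq_len(nrow(wide)), function(i) {
    ann <- paste(wide$transcript_id[i], wide$effect[i], wide$cds_pos[i],
                 wide$ref[i], wide$alt[i], sep = "|")
    geno <- vapply(samples, function(s) {
      paste(gt_of(wide[[paste0("dosage_", s)]][i]),
            wide[[paste0("dp_", s)]][i],
            wide[[paste0("gq_", s)]][i], sep = ":")
    }, character(1))
    paste(c(wide$transcript_id[i], wide$cds_pos[i], ".", wide$ref[i],
            wide$alt[i], ".", "PASS", paste0("ANN=", ann), "GT:DP:GQ", geno),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Consequence annotation: transcript|effect|cds_pos|cds_ref|cds_alt\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Approximate read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate HLA typings for all subjects of a cohort
#'
#' Recipients are sampled from the allele pool by frequency; donors are
#' HLA-identical siblings by default, with `hla_mismatch_fraction` of pairs
#' receiving 1-3 replaced donor alleles to emulate the minority of
#' incompletely matched pairs.
#'
#' @param config A [simulation_config()].
#' @return An `hla_typings` tibble covering `<pair>_D` and `<pair>_R`.
#' @export
generate_hla_typings <- function(config = simulation_config()) {
  with_stage_seed(config$seed, "typings", {
    pool <- split(config$allele_pool, config$allele_pool$locus)
    draw <- function(locus, n) {
      p <- pool[[locus]]
      sample(p$allele, n, replace = TRUE, prob = p$freq)
    }
    pairs <- pair_ids_of(config)
    rows <- lapply(pairs, function(pid) {
      rec <- stats::setNames(
        lapply(HLA_LOCI, draw, n = 2L),
        HLA_LOCI
      )
      don <- rec
      if (stats::runif(1) < config$hla_mismatch_fraction) {
        k <- sample(1:3, 1L)
        for (slot in sample(1:12, k)) {
          locus <- HLA_LOCI[(slot + 1L) %/% 2L]
          which_allele <- 2L - (slot %% 2L)
          current <- don[[locus]][which_allele]
          alt_pool <- setdiff(pool[[locus]]$allele, current)
          don[[locus]][which_allele] <- sample(alt_pool, 1L)
        }
      }
      mk <- function(sid, typ) {
        vals <- c(list(sample_id = sid),
                  stats::setNames(unlist(typ, use.names = FALSE),
                                  paste0(rep(HLA_LOCI, each = 2L), "_", 1:2)))
        tibble::as_tibble(vals)
      }
      dplyr::bind_rows(mk(paste0(pid, "_D"), don), mk(paste0(pid, "_R"), rec))
    })
    structure(dplyr::bind_rows(rows), class = c("hla_typings", class(tibble::tibble())))
  })
}

random_peptides <- function(n, len = 9L) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(AA_STANDARD, len[i], replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate the external-resource tables for a simulated cohort
#'
#' Builds the IEDB-style ligand table (planted recipient-unique peptides
#' under alleles their recipients actually carry, plus per-allele random
#' decoys and a few rows violating each inclusion filter), the mHA table
#' (planted 9-mers plus longer decoys that exercise 9-merization), the
#' tissue-expression table and the affinity percentile-rank table covering
#' every recipient-unique peptide against its recipient's HLA-A/-B alleles.
#'
#' @param pair_peptides Named list pair_id -> character vector of
#'   recipient-unique 9-mers.
#' @param typings The cohort `hla_typings`.
#' @param reference The `cds_reference` (for the expression table's genes).
#' @param config A [simulation_config()].
#' @return List of tibbles: `iedb`, `mha`, `expression`, `ranks`.
#' @export
generate_resources <- function(pair_peptides, typings, reference,
                               config = simulation_config()) {
  with_stage_seed(config$seed, "resources", {
    pairs <- names(pair_peptides)
    rec_class1 <- lapply(pairs, function(pid) {
      typing_alleles(hla_typing_of(typings, paste0(pid, "_R")),
                     loci = HLA_CLASS1_LOCI, unique_only = TRUE)
    })
    names(rec_class1) <- pairs

    planted <- lapply(pairs, function(pid) {
      u <- pair_peptides[[pid]]
      take <- stats::runif(length(u)) < config$planted_overlap
      if (!any(take)) return(NULL)
      tibble::tibble(
        peptide = u[take],
        allele = sample(rec_class1[[pid]], sum(take), replace = TRUE)
      )
    })
    class1_pool <- config$allele_pool$allele[config$allele_pool$locus %in% HLA_CLASS1_LOCI]
    decoys <- tibble::tibble(
      peptide = random_peptides(config$ligand_db_size * length(class1_pool)),
      allele = rep(class1_pool, each = config$ligand_db_size)
    )
    iedb_core <- dplyr::bind_rows(c(planted, list(decoys)))
    iedb <- tibble::tibble(
      peptide = c(iedb_core$peptide, random_peptides(3L)),
      allele = c(iedb_core$allele, "A*02:01", "A*02:01", ""),
      qualitative_measure = c(sample(c("Positive", "Positive-High"),
                                     nrow(iedb_core), replace = TRUE),
                              "Positive", "Negative", "Positive"),
      host_organism = c(rep("Homo sapiens", nrow(iedb_core)),
                        "Mus musculus", "Homo sapiens", "Homo sapiens")
    )

    mha_planted <- lapply(pairs, function(pid) {
      u <- pair_peptides[[pid]]
      take <- stats::runif(length(u)) < config$mha_overlap
      if (!any(take)) return(NULL)
      tibble::tibble(
        peptide = u[take],
        allele = sample(rec_class1[[pid]], sum(take), replace = TRUE)
      )
    })
    mha_decoys <- tibble::tibble(
      peptide = random_peptides(config$mha_decoys,
                                len = sample(9:12, config$mha_decoys, replace = TRUE)),
      allele = sample(class1_pool, config$mha_decoys, replace = TRUE)
    )
    mha <- dplyr::bind_rows(c(mha_planted, list(mha_decoys)))
    mha$gene <- sprintf("MHAGENE%03d", seq_len(nrow(mha)))

    supportive <- stats::runif(nrow(reference)) < config$expr_supportive_fraction
    expression <- tibble::tibble(
      gene = reference$gene_id,
      transcript = NA_character_,
      tissue = ifelse(supportive,
                      sample(GVHD_TARGET_TISSUES, nrow(reference), replace = TRUE),
                      sample(c("brain", "kidney", "testis"), nrow(reference), replace = TRUE)),
      reliability = ifelse(supportive, "Supportive",
                           sample(c("Uncertain", "Approved"), nrow(reference), replace = TRUE))
    )

    ranks <- lapply(pairs, function(pid) {
      u <- pair_peptides[[pid]]
      ab <- rec_class1[[pid]]
      ab <- ab[hla_locus(ab) %in% c("A", "B")]
      if (!length(u) || !length(ab)) return(NULL)
      grid <- tidyr::expand_grid(peptide = u, allele = ab)
      high <- stats::runif(nrow(grid)) < config$rank_high_fraction
      grid$percentile_rank <- ifelse(high,
                                     stats::runif(nrow(grid), 0.05, 4),
                                     stats::runif(nrow(grid), 4, 100))
      grid
    })
    ranks <- dplyr::bind_rows(ranks)
    if (nrow(ranks) == 0L) {
      ranks <- tibble::tibble(peptide = character(), allele = character(),
                              percentile_rank = numeric())
    } else {
      ranks <- dplyr::distinct(ranks, .data$peptide, .data$allele, .keep_all = TRUE)
    }
    list(iedb = iedb, mha = mha, expression = expression, ranks = ranks)
  })
}

sim_pair_metadata <- function(config) {
  with_stage_seed(config$seed, "metadata", {
    n <- config$n_pairs
    tibble::tibble(
      pair_id = pair_ids_of(config),
      donor_age = pmin(pmax(round(stats::rnorm(n, 45, 10)), 18), 70),
      tr_year = sample(2001:2015, n, replace = TRUE),
      f_to_m = stats::runif(n) < 0.2
    )
  })
}

safe_scale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Generate outcomes from a known logistic model
#'
#' `P(extensive) = plogis(intercept + effect_beta * scaled ligand count +
#' sum(covariate_betas * scaled covariates))`; independently of severity, a
#' `limited_fraction` of pairs is graded "limited" to exercise the exclusion
#' rule. Acute GvHD grade and relapse are carried but unused downstream.
#' Covariates with zero spread (degenerate cohorts) contribute 0.
#'
#' @param estimates Per-pair estimate tibble (`pair_id`, `m1`-`m4`,
#'   `total_mismatched`, `total_filtered`).
#' @param covariates Per-pair covariates (`pair_id`, `hla_freq_sum`,
#'   `n_unique_hla`, `donor_age`, `tr_year`, `f_to_m`, `hla_match_count`).
#' @param config A [simulation_config()].
#' @return Outcome tibble: `pair_id`, `cgvhd_grade`, `agvhd_grade`,
#'   `relapse`.
#' @export
generate_outcomes <- function(estimates, covariates, config = simulation_config()) {
  with_stage_seed(config$seed, "outcomes", {
    dat <- dplyr::inner_join(estimates, covariates, by = "pair_id")
    b <- config$covariate_betas
    mismatch_col <- mismatch_covariate_for(config$effect_method)
    lp <- config$intercept +
      config$effect_beta * safe_scale(dat[[config$effect_method]]) +
      b[["hla_freq_sum"]] * safe_scale(dat$hla_freq_sum) +
      b[["n_unique_hla"]] * safe_scale(dat$n_unique_hla) +
      b[["donor_age"]] * safe_scale(dat$donor_age) +
      b[["tr_year"]] * safe_scale(dat$tr_year) +
      b[["f_to_m"]] * as.numeric(dat$f_to_m) +
      b[["hla_match_count"]] * safe_scale(dat$hla_match_count) +
      b[["mismatch"]] * safe_scale(dat[[mismatch_col]])
    extensive <- stats::runif(nrow(dat)) < stats::plogis(lp)
    limited <- stats::runif(nrow(dat)) < config$limited_fraction
    tibble::tibble(
      pair_id = dat$pair_id,
      cgvhd_grade = ifelse(limited, "limited", ifelse(extensive, "extensive", "no")),
      agvhd_grade = sample(0:4, nrow(dat), replace = TRUE,
                           prob = c(0.60, 0.18, 0.12, 0.06, 0.04)),
      relapse = stats::runif(nrow(dat)) < 0.3
    )
  })
}

#' Simulate a complete study bundle on disk
#'
#' Runs every generator, executes the peptide pipeline internally to obtain
#' the per-pair recipient-unique sets the resource generator plants ligands
#' into, computes the M1-M4 estimates, draws outcomes from the configured
#' logistic model, and writes the full input bundle (`reference.fa`,
#' `vcf/<pair>.vcf`, `hla_typings.tsv`, `iedb_ligands.tsv`,
#' `mha_ligands.tsv`, `expression.tsv`, `affinity_ranks.tsv`,
#' `outcomes.tsv`, `config.yaml`) into `out_dir`. Deterministic given the
#' config seed. The bundle is consumed unchanged by [run_pipeline()].
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory cohort objects: `reference`,
#'   `typings`, `peptides`, `resources`, `estimates`, `covariates`,
#'   `outcomes`, `out_dir`.
#' @export
simulate_cohort <- function(config = simulation_config(), out_dir = tempfile("cohort_")) {
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  pairs <- pair_ids_of(config)

  reference <- generate_reference(config)
  write_cds_fasta(reference, file.path(out_dir, "reference.fa"))
  ref_prot <- translate_reference(reference)

  typings <- generate_hla_typings(config)
  readr::write_tsv(typings, file.path(out_dir, "hla_typings.tsv"))

  thresholds <- quality_thresholds(config$dp_min, config$gq_min)
  pair_peptide_tbls <- vector("list", length(pairs))
  names(pair_peptide_tbls) <- pairs
  for (pid in pairs) {
    events <- generate_pair_variants(reference, pid, config)
    if (nrow(events)) write_pair_vcf(events, file.path(out_dir, "vcf", paste0(pid, ".vcf")))
    v <- events[events$effect %in% VALID_EFFECTS, , drop = FALSE]
    v <- genotype_quality_filter(new_variant_calls(v), thresholds)
    don <- build_individual_proteome(paste0(pid, "_D"), reference, v, ref_prot)
    rec <- build_individual_proteome(paste0(pid, "_R"), reference, v, ref_prot)
    pair_peptide_tbls[[pid]] <- recipient_unique_peptides(don, rec)
  }
  pair_peptides <- lapply(pair_peptide_tbls, function(p) p$peptide)

  resources <- generate_resources(pair_peptides, typings, reference, config)
  readr::write_tsv(resources$iedb, file.path(out_dir, "iedb_ligands.tsv"))
  readr::write_tsv(resources$mha, file.path(out_dir, "mha_ligands.tsv"))
  readr::write_tsv(resources$expression, file.path(out_dir, "expression.tsv"))
  readr::write_tsv(resources$ranks, file.path(out_dir, "affinity_ranks.tsv"))

  iedb_db <- build_ligand_db("iedb", resources$iedb$peptide[
    resources$iedb$host_organism == "Homo sapiens" &
      tolower(resources$iedb$qualitative_measure) %in% c("positive", "positive-high") &
      nzchar(resources$iedb$allele)],
    resources$iedb$allele[
      resources$iedb$host_organism == "Homo sapiens" &
        tolower(resources$iedb$qualitative_measure) %in% c("positive", "positive-high") &
        nzchar(resources$iedb$allele)],
    ninemerize = FALSE)
  mha_db <- build_ligand_db("mha", resources$mha$peptide, resources$mha$allele,
                            ninemerize = TRUE)
  predictor <- if (nrow(resources$ranks)) rank_table_predictor(resources$ranks) else toy_pssm_predictor()
  imm_model <- immunogenicity_model()

  estimates <- dplyr::bind_rows(lapply(pairs, function(pid) {
    compute_method_counts(
      pair_id = pid,
      peptides = pair_peptide_tbls[[pid]],
      recipient_typing = hla_typing_of(typings, paste0(pid, "_R")),
      iedb_db = iedb_db, mha_db = mha_db,
      expression = resources$expression,
      imm_model = imm_model, predictor = predictor
    )
  }))

  rec_typings <- typings[endsWith(typings$sample_id, "_R"), , drop = FALSE]
  meta <- sim_pair_metadata(config)
  covariates <- dplyr::bind_rows(lapply(pairs, function(pid) {
    don <- hla_typing_of(typings, paste0(pid, "_D"))
    rec <- hla_typing_of(typings, paste0(pid, "_R"))
    hc <- compute_hla_covariates(rec_typings, rec)
    tibble::tibble(pair_id = pid, hla_freq_sum = hc$hla_freq_sum,
                   n_unique_hla = hc$n_unique_hla,
                   hla_match_count = count_hla_matches(don, rec))
  }))
  covariates <- dplyr::inner_join(covariates, meta, by = "pair_id")

  outcomes <- generate_outcomes(estimates, covariates, config)
  readr::write_tsv(
    dplyr::inner_join(outcomes, meta, by = "pair_id"),
    file.path(out_dir, "outcomes.tsv")
  )

  cfg <- unclass(config)
  cfg$allele_pool <- as.list(config$allele_pool)
  cfg$effect_weights <- as.list(config$effect_weights)
  cfg$covariate_betas <- as.list(config$covariate_betas)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))

  invisible(list(
    out_dir = out_dir, reference = reference, typings = typings,
    peptides = pair_peptide_tbls, resources = resources,
    estimates = estimates, covariates = covariates, outcomes = outcomes
  ))
}

#' Fast association-stage cohort simulator
#'
#' Draws per-pair estimates, covariates and outcomes directly from
#' distributions calibrated to the cohort scale (shared latent mismatch
#' burden driving correlated M1-M4 counts), bypassing the sequence-level
#' pipeline. This is the workhorse for parameter-recovery and null
#' calibration studies where hundreds of replicate cohorts are fitted.
#'
#' @param n_pairs Cohort size.
#' @param effect_beta Planted ligand-count log-odds per SD.
#' @param effect_method Estimator carrying the effect.
#' @param intercept,covariate_betas,limited_fraction As in
#'   [simulation_config()].
#' @param seed Seed.
#' @return A tibble ready for [run_association_suite()].
#' @export
simulate_association_cohort <- function(n_pairs = 157L,
                                        effect_beta = 0.6,
                                        effect_method = "m1",
                                        intercept = -0.6,
                                        covariate_betas = c(hla_freq_sum = -0.4,
                                                            n_unique_hla = 0.15,
                                                            donor_age = 0.3, tr_year = 0.1,
                                                            f_to_m = -0.8,
                                                            hla_match_count = 0.25,
                                                            mismatch = 0),
                                        limited_fraction = 23 / 151,
                                        seed = 1L) {
  cfg <- simulation_config(
    n_pairs = n_pairs, effect_beta = effect_beta, effect_method = effect_method,
    intercept = intercept, covariate_betas = covariate_betas,
    limited_fraction = limited_fraction, seed = seed
  )
  with_stage_seed(seed, "assoc_cohort", {
    # Three-level count model: a shared mismatch burden drives everything
    # (totals are tight around it, CV ~ 0.2); a shared HLA-presentation
    # factor drives the four estimator counts jointly but not the totals;
    # method-private dispersion decorrelates the estimators from each other.
    # Gamma shapes are calibrated to the cohort's printed per-statistic
    # spread (m1 CV ~ 0.45 up to m4 CV > 1).
    burden <- stats::rgamma(n_pairs, shape = 25, rate = 25)
    presented <- stats::rgamma(n_pairs, shape = 15, rate = 15)
    private <- function(shape) stats::rgamma(n_pairs, shape = shape, rate = shape)
    estimates <- tibble::tibble(
      pair_id = pair_ids_of(cfg),
      m1 = stats::rpois(n_pairs, burden * presented * private(10) * 393),
      m2 = stats::rpois(n_pairs, burden * presented * private(5) * 21.6),
      m3 = stats::rpois(n_pairs, burden * presented * private(2) * 2.6),
      m4 = stats::rpois(n_pairs, burden * presented * private(0.8) * 39.5),
      total_mismatched = stats::rpois(n_pairs, burden * private(100) * 8729),
      total_filtered = stats::rpois(n_pairs, burden * private(100) * 2815)
    )
    covariates <- tibble::tibble(
      pair_id = estimates$pair_id,
      hla_freq_sum = stats::rnorm(n_pairs, 6, 1.2),
      n_unique_hla = sample(7:12, n_pairs, replace = TRUE),
      donor_age = pmin(pmax(round(stats::rnorm(n_pairs, 45, 10)), 18), 70),
      tr_year = sample(2001:2015, n_pairs, replace = TRUE),
      f_to_m = stats::runif(n_pairs) < 0.2,
      hla_match_count = sample(c(12L, 11L, 10L, 9L), n_pairs, replace = TRUE,
                               prob = c(147, 3, 2, 5))
    )
    # effect_method = "presented" plants the effect on the shared
    # HLA-presentation factor, the analogue of all four estimators deriving
    # from one presented-peptide pool: every fitted ligand coefficient then
    # sees a positive signal beyond the total-mismatch covariate.
    # "burden" plants it on the overall mismatch burden instead.
    est_for_outcomes <- estimates
    if (identical(effect_method, "burden")) est_for_outcomes$burden <- burden
    if (identical(effect_method, "presented")) est_for_outcomes$presented <- presented
    outcomes <- generate_outcomes(est_for_outcomes, covariates, cfg)
    dplyr::inner_join(dplyr::inner_join(estimates, covariates, by = "pair_id"),
                      outcomes, by = "pair_id")
  })
}
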