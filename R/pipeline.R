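# End-to-end orchestration over a run directory produced by
# simulate_cohort() (or assembled by hand in the same layout). Stages follow
# the pipeline topology: reference/variant ingestion -> per-pair proteomes ->
# recipient-unique peptides -> immunogenicity/expression filters and ligand /
# affinity intersections (M1-M4) -> covariate-adjusted logistic association.

#' Run the full mismatch-estimation and association pipeline
#'
#' Consumes a run directory containing `reference.fa`, `vcf/<pair>.vcf`,
#' `hla_typings.tsv`, `iedb_ligands.tsv`, `mha_ligands.tsv`,
#' `expression.tsv`, optionally `affinity_ranks.tsv`, and `outcomes.tsv`.
#' Per-pair failures (including a missing expression table, which disables
#' only the filtered estimators M2/M4) are collected rather than aborting
#' the cohort; the association stage runs on whatever estimators completed.
#' Outputs (`estimates.tsv`, `association.tsv`, `cohort_summary.tsv`,
#' `summary.json`, `manifest.json`) are written under `out_dir`.
#'
#' @param run_dir Input bundle directory.
#' @param out_dir Output directory (default `<run_dir>/output`).
#' @param thresholds Genotype [quality_thresholds()].
#' @param imm_model An [immunogenicity_model()].
#' @param affinity An [affinity_config()].
#' @param assoc An [association_config()].
#' @param predictor Affinity predictor; default uses
#'   `affinity_ranks.tsv` when present, else the built-in toy matrix model.
#' @param restrict_to_recipient_hla Allele-aware ligand matching (default
#'   `TRUE`).
#' @return Invisibly, a list: `estimates`, `association`, `summary`,
#'   `errors`, `out_dir`.
#' @export
run_pipeline <- function(run_dir,
                         out_dir = file.path(run_dir, "output"),
                         thresholds = quality_thresholds(),
                         imm_model = immunogenicity_model(),
                         affinity = affinity_config(),
                         assoc = association_config(),
                         predictor = NULL,
                         restrict_to_recipient_hla = TRUE) {
  paths <- list(
    reference = file.path(run_dir, "reference.fa"),
    typings = file.path(run_dir, "hla_typings.tsv"),
    iedb = file.path(run_dir, "iedb_ligands.tsv"),
    mha = file.path(run_dir, "mha_ligands.tsv"),
    expression = file.path(run_dir, "expression.tsv"),
    ranks = file.path(run_dir, "affinity_ranks.tsv"),
    outcomes = file.path(run_dir, "outcomes.tsv")
  )
  required <- c("reference", "typings", "iedb", "mha", "outcomes")
  missing_in <- !vapply(paths[required], file.exists, logical(1))
  if (any(missing_in)) {
    stop("missing required input file(s): ",
         paste(unlist(paths[required])[missing_in], collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  reference <- read_cds_fasta(paths$reference)
  ref_prot <- translate_reference(reference)
  typings <- read_hla_typings(paths$typings)
  iedb_db <- parse_iedb_table(paths$iedb)
  mha_db <- suppressWarnings(parse_mha_table(paths$mha))
  expression <- if (file.exists(paths$expression)) read_expression_table(paths$expression) else NULL
  if (is.null(predictor)) {
    predictor <- if (file.exists(paths$ranks)) rank_table_predictor(paths$ranks) else toy_pssm_predictor()
  }

  vcf_files <- sort(list.files(file.path(run_dir, "vcf"), pattern = "\\.vcf(\\.gz)?$",
                               full.names = TRUE))
  pair_ids <- sub("\\.vcf(\\.gz)?$", "", basename(vcf_files))
  errors <- list()
  est_rows <- vector("list", length(pair_ids))
  for (i in seq_along(pair_ids)) {
    pid <- pair_ids[i]
    est_rows[[i]] <- tryCatch({
      samples <- paste0(pid, c("_D", "_R"))
      variants <- suppressWarnings(read_annotated_vcf(vcf_files[i], samples))
      variants <- genotype_quality_filter(variants, thresholds)
      don <- build_individual_proteome(samples[1], reference, variants, ref_prot)
      rec <- build_individual_proteome(samples[2], reference, variants, ref_prot)
      peptides <- recipient_unique_peptides(don, rec)
      est <- compute_method_counts(
        pair_id = pid, peptides = peptides,
        recipient_typing = hla_typing_of(typings, samples[2]),
        iedb_db = iedb_db, mha_db = mha_db, expression = expression,
        imm_model = imm_model, predictor = predictor, affinity = affinity,
        restrict_to_recipient_hla = restrict_to_recipient_hla,
        strict = FALSE
      )
      ee <- attr(est, "estimate_errors")
      if (length(ee)) errors[[pid]] <- ee
      est
    }, error = function(e) {
      errors[[pid]] <<- conditionMessage(e)
      NULL
    })
  }
  estimates <- dplyr::bind_rows(est_rows)
  if (nrow(estimates) == 0L) stop("no pair produced estimates", call. = FALSE)
  readr::write_tsv(estimates, file.path(out_dir, "estimates.tsv"))

  outcomes <- readr::read_tsv(paths$outcomes, show_col_types = FALSE, progress = FALSE)
  rec_typings <- typings[endsWith(typings$sample_id, "_R"), , drop = FALSE]
  covariates <- dplyr::bind_rows(lapply(estimates$pair_id, function(pid) {
    don <- hla_typing_of(typings, paste0(pid, "_D"))
    rec <- hla_typing_of(typings, paste0(pid, "_R"))
    hc <- compute_hla_covariates(rec_typings, rec, mode = assoc$hla_freq_mode)
    tibble::tibble(pair_id = pid, hla_freq_sum = hc$hla_freq_sum,
                   n_unique_hla = hc$n_unique_hla,
                   hla_match_count = count_hla_matches(don, rec))
  }))
  assoc_data <- estimates |>
    dplyr::inner_join(covariates, by = "pair_id") |>
    dplyr::inner_join(outcomes, by = "pair_id")

  methods_ok <- assoc$methods[vapply(assoc$methods, function(m) !anyNA(assoc_data[[m]]), logical(1))]
  association <- NULL
  if (length(methods_ok)) {
    cfg <- assoc
    cfg$methods <- methods_ok
    association <- tryCatch(run_association_suite(assoc_data, cfg),
                            error = function(e) {
                              errors[["association"]] <<- conditionMessage(e)
                              NULL
                            })
  } else {
    errors[["association"]] <- "no estimator column is complete; association skipped"
  }
  if (!is.null(association)) {
    readr::write_tsv(association, file.path(out_dir, "association.tsv"))
  }

  summary <- write_reports(estimates, association, outcomes, out_dir)

  manifest <- list(
    inputs = lapply(paths[file.exists(unlist(paths))], function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    n_pairs = nrow(estimates),
    settings = list(
      dp_min = thresholds$dp_min, gq_min = thresholds$gq_min,
      immunogenicity_threshold = imm_model$threshold,
      rank_cutoff = affinity$rank_cutoff,
      affinity_loci = affinity$loci,
      restrict_to_recipient_hla = restrict_to_recipient_hla,
      fdr_threshold = assoc$fdr_threshold
    ),
    errors = errors
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(estimates = estimates, association = association,
                 summary = summary, errors = errors, out_dir = out_dir))
}

#' Write cohort-summary and association reports
#'
#' Emits a cohort characteristics table in the style of a transplant-study
#' Table 1 -- for each count statistic its mean and empirical 2.5-97.5
#' percentile interval (the printed intervals of such tables are asymmetric
#' around the mean, consistent with percentile ranges rather than
#' normal-theory intervals), plus categorical outcome rows -- and a JSON run
#' summary.
#'
#' @param estimates Per-pair estimate tibble.
#' @param association An `association_result` (or `NULL`).
#' @param outcomes Outcome tibble with `cgvhd_grade`.
#' @param out_dir Output directory.
#' @return The summary list, invisibly.
#' @export
write_reports <- function(estimates, association, outcomes, out_dir) {
  stats_cols <- c("total_mismatched", "total_filtered", "m1", "m2", "m3", "m4")
  count_rows <- dplyr::bind_rows(lapply(stats_cols, function(col) {
    x <- estimates[[col]]
    x <- x[!is.na(x)]
    tibble::tibble(
      statistic = col,
      mean = if (length(x)) mean(x) else NA_real_,
      p2.5 = if (length(x)) unname(stats::quantile(x, 0.025)) else NA_real_,
      p97.5 = if (length(x)) unname(stats::quantile(x, 0.975)) else NA_real_
    )
  }))
  grade_rows <- outcomes |>
    dplyr::count(.data$cgvhd_grade, name = "n") |>
    dplyr::mutate(statistic = paste0("cgvhd_", .data$cgvhd_grade),
                  percentage = 100 * .data$n / sum(.data$n)) |>
    dplyr::select("statistic", "n", "percentage")
  readr::write_tsv(dplyr::bind_rows(
    count_rows,
    tibble::tibble(statistic = grade_rows$statistic, mean = grade_rows$n,
                   p2.5 = NA_real_, p97.5 = grade_rows$percentage)
  ), file.path(out_dir, "cohort_summary.tsv"))

  summary <- list(
    n_pairs = nrow(estimates),
    counts = stats::setNames(
      lapply(seq_len(nrow(count_rows)), function(i) {
        list(mean = count_rows$mean[i],
             percentile_interval = c(count_rows$p2.5[i], count_rows$p97.5[i]))
      }),
      count_rows$statistic
    ),
    cgvhd_grades = stats::setNames(as.list(grade_rows$n), grade_rows$statistic),
    association = if (!is.null(association)) {
      lig <- association[association$term == "ligand_count", , drop = FALSE]
      stats::setNames(
        lapply(seq_len(nrow(lig)), function(i) {
          list(estimate = lig$estimate[i], std_error = lig$std_error[i],
               z = lig$z[i], p_value = lig$p_value[i],
               p_adjusted = lig$p_adjusted[i])
        }),
        lig$method
      )
    } else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
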