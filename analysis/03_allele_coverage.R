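#!/usr/bin/env Rscript
# Step 3: ligand-database HLA allele coverage of the cohort.
#
# Rare HLA alleles are under-represented in experimental ligand databases,
# which motivates the HLA-frequency covariates in the association models.
# This step quantifies, per class I locus, the fraction of cohort alleles
# with at least one ligand in the curated IEDB-style and mHA databases.

library(allopep)

typ <- read_hla_typings("results/run/hla_typings.tsv")
rec <- typ[endsWith(typ$sample_id, "_R"), ]
iedb <- parse_iedb_table("results/run/iedb_ligands.tsv")
mha <- suppressWarnings(parse_mha_table("results/run/mha_ligands.tsv"))

cohort_class1 <- unlist(rec[paste0(rep(c("A", "B", "C"), each = 2), "_", 1:2)])
cov_iedb <- allele_coverage(cohort_class1, iedb, by_locus = TRUE)
cov_mha <- allele_coverage(cohort_class1, mha, by_locus = TRUE)

message("cohort class I allele coverage (%):")
for (l in cov_iedb$locus) {
  m <- cov_mha$coverage_pct[cov_mha$locus == l]
  message(sprintf("  HLA-%s  IEDB %5.1f  mHA %5.1f", l,
                  cov_iedb$coverage_pct[cov_iedb$locus == l],
                  if (length(m)) m else 0))
}
dir.create("results", showWarnings = FALSE)
readr::write_tsv(
  dplyr::bind_rows(dplyr::mutate(cov_iedb, db = "iedb"),
                   dplyr::mutate(cov_mha, db = "mha")),
  "results/allele_coverage.tsv"
)
message("written to results/allele_coverage.tsv")
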