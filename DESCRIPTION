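Package: allopep
Title: Donor-Recipient Exome Mismatch Estimation for HLA-Presented Alloreactivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-individual in-silico proteomes from paired donor and
    recipient coding-region variant calls, extracts recipient-unique 9-mer
    peptides, estimates HLA-presented alloreactivity with four
    ligandome-intersection and affinity-prediction based counts (M1-M4), and
    tests their covariate-adjusted logistic association with chronic
    graft-versus-host disease under Benjamini-Hochberg false discovery rate
    control. Includes a deterministic synthetic-cohort generator emulating
    every required input format (reference CDS FASTA, annotated VCFs, HLA
    typings, experimental ligand tables, tissue-expression and affinity-rank
    tables, outcomes) so the full pipeline and the association analysis are
    reproducible without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    dplyr,
    tidyr,
    tibble,
    readr,
    stringi,
    rlang,
    jsonlite,
    yaml,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
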