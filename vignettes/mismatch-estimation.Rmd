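---
title: "Estimating HLA-presented donor-recipient mismatch: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating HLA-presented donor-recipient mismatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopep)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the parameters that matter, what
the synthetic cohort does and does not emulate, and the choices made where
the design was genuinely open.

## From variant calls to personal proteomes

The pipeline works entirely in *transcript space*: a variant is a
left-anchored VCF-style edit at a 1-based position of a coding sequence
(`CHROM` = transcript id, `POS` = CDS position). This removes the need for
a genome-to-CDS projection engine; callers working from genome-space
snpEff/VEP annotations can populate the supported pipe-delimited dialect
(`transcript|effect|cds_pos|cds_ref|cds_alt`) from the annotation
subfields. Only missense, insertion, deletion, frameshift and stop-gained
consequences enter the analysis; synonymous and non-coding annotations are
dropped at parse time, with `select_nonsynonymous()` as an explicit gate
for looser adapters.

Genotypes are hard-filtered on approximate read depth and genotype quality
(defaults `dp_min = 15`, `gq_min = 20`, both overridable). The thresholds
are deliberately configuration, not science: typical exome practice puts
DP cutoffs at 10–20x and GQ at 20, and the filter's behaviour — failing
genotypes become missing, variants missing in all samples disappear, the
operation is idempotent and monotone in the thresholds — matters more than
the exact values.

**Phasing.** Short-read exomes do not phase variants, so per transcript the
builder forms two *pseudo-haplotypes*: H1 carries only homozygous-alt
variants, H2 carries every non-missing carried variant (hom + het). This
rule is deterministic, needs no phase information, and guarantees the
reference-allele protein survives whenever any heterozygous site exists.
It brackets the truth: the real pair of haplotypes always lies between
"all hets together" (H2) and "no hets" (H1). Whether the original analysis
kept both products of a heterozygous site is unstated in the source
material; keeping both is the conservative choice for a *recipient-unique*
set, because anything the donor might also produce is subtracted anyway.

Translation starts at position 1 (the reference filter enforces ATG
starts), stops at and excludes the first stop codon, drops a trailing
partial codon, and renders any codon containing N as `X`; 9-mer windows
containing `X` are discarded downstream. Variants are applied in
descending coordinate order so indels never invalidate the coordinates of
earlier edits; overlapping variants and reference-allele mismatches are
hard errors rather than silent repairs.

## Recipient-unique 9-mers

Transcripts whose protein *sets* differ (set semantics — order and
duplicates ignored) are split into all overlapping 9-mers; the recipient
union minus the donor union over those same transcripts is the candidate
alloantigen set *U*. Two open points were decided as follows:

* *Scope of the donor subtraction.* The donor 9-mer union is built from
  the differing transcripts only, mirroring the stated order of operations
  (exclude identical proteins, then split, then subtract). A strict mode
  (`strict_donor_union = TRUE`) subtracts the donor's whole-proteome
  union; it is off by default and only removes peptides that recur
  identically elsewhere in the donor proteome.
* *Deduplication.* Peptides are counted once per unique sequence, with
  provenance (source transcripts and genes) merged, since a peptide's
  identity — not its genomic multiplicity — determines HLA presentation.

"Split into 9-mers from all frames" is read as sliding windows over the
protein (the split applies to amino-acid sequences, where nucleotide
reading frames no longer exist). Peptide lengths other than 9 are out of
scope by design: class I ligands are predominantly 9-mers and the
experimental resources used are 9-merized.

## The four estimators

With *F* = *U* after the immunogenicity and expression filters:

* **M1** = |U ∩ IEDB| and **M3** = |U ∩ mHA| — intersections with
  experimental ligand sets;
* **M2** = |F ∩ IEDB| — the filtered variant of M1 (hence M2 ≤ M1 and
  M2 ≤ |F| structurally);
* **M4** = high-affinity count over *F*: peptides with consensus
  percentile rank ≤ 4 (alternative 6) for at least one recipient HLA-A or
  -B allele.

**Allele restriction.** Ligand databases are pooled over the *recipient's
own* class I alleles before intersecting (two-field resolution). The
source material does not state this explicitly, but its HLA-frequency
covariates and allele-coverage analysis only make sense under allele-aware
matching; `restrict_to_recipient_hla = FALSE` gives the unrestricted
reading for comparison.

**IEDB 9-merization.** Entries longer than 9 residues are dropped, not
9-merized: the estimator definitions speak of experimental *9-mer* class I
ligands, while frame expansion is described only for the mHA set (which
`parse_mha_table()` does apply). `parse_iedb_table(ninemerize = TRUE)`
implements the other reading.

**Immunogenicity.** The score is a position-weighted sum of per-residue
log-enrichment weights (residues over-represented among immunogenic
ligands score positive), with HLA anchor positions 1, 2 and the C-terminus
masked — the behaviour of the public Immunogenicity-1.1 tool when run
without HLA specification. The constants ship as a versioned data file
(`inst/extdata/immunogenicity_residue_weights_v1.1.tsv`) so any future
re-transcription is traceable. Allele-specific position masking is
intentionally absent. Selection is strictly greater than 0.2; a peptide at
exactly the threshold is excluded.

**Expression.** A peptide passes if at least one source gene (or source
transcript, when the table carries transcript ids) has a record with the
required reliability (default "supportive", case-insensitive) in at least
one of skin, intestine, lung, liver or bone marrow — the tissues relevant
for epithelial GvHD plus the hematopoietic compartment. An empty or
missing expression table is an error, not an empty result, so "no data"
can never masquerade as "nothing expressed".

**Affinity prediction** sits behind a contract, not an implementation: a
predictor declares which alleles it supports and returns percentile ranks
in (0, 100] (lower = stronger). Shipped implementations are a
precomputed-rank table reader (the production path; multi-algorithm
consensus engines run outside R) and a deterministic toy
position-specific-scoring-matrix model for tests and simulations. The toy
model is a stand-in for exercising the contract, not a binding predictor.
Unsupported alleles are surfaced in the run report rather than silently
skipped.

## The association stage

Outcome: chronic GvHD "no" (0) vs "extensive" (1); "limited" pairs are
excluded entirely rather than merged into either class. Each estimator is
tested in its own logistic model with: the method-specific mismatch total
(raw *|U|* for M1/M3, filtered *|F|* for M2/M4), the sum of cohort
frequencies of the recipient's distinct HLA alleles, the number of
distinct alleles, transplantation year, donor age, female-to-male
direction, and the 0–12 HLA allele matching count. Numeric predictors are
centered and scaled (sample SD), so coefficients are per-SD log-odds and
comparable across estimators; the binary direction indicator enters as
0/1. Wald z-tests use the standard normal; the four ligand-count p-values
are jointly Benjamini–Hochberg adjusted (via `stats::p.adjust`), covariate
rows stay nominal.

Design choices worth recording:

* *HLA frequency definition.* "Cohort frequency of an allele" is
  ambiguous; the default is carrier frequency (fraction of cohort
  recipients carrying the allele), with allele-copy frequency available
  via `hla_freq_mode = "allele_count"`.
* *HLA matching* enters as a scaled numeric count (multiset intersection
  per locus, summed over six loci), not as a factor.
* *Degenerate covariates.* An adjustment covariate that is constant in
  the analyzed subset (e.g. a fully 12/12-matched cohort) is dropped with
  a warning; the tested ligand count itself must have spread.
* *Separation.* The fitter converges to `glm`'s ML solution (tolerance
  1e-10, up to 100 iterations) and flags (quasi-)complete separation by
  its Wald signature — a diverging coefficient with an exploding standard
  error on the scaled design. `fit_logistic_wald()` raises it as an
  error; the suite additionally recognizes the common benign case of a
  sparse adjustment-covariate cell (e.g. all five 9/12-matched pairs
  sharing one outcome), drops that covariate with a warning, and refits.
  A diverging ligand count is always an error. No penalized (Firth-type)
  fallback is attempted; that is a documented non-goal.

The BH worked example deserves a note: adjusting the four reported nominal
p-values (0.00976, 0.0234, 0.0366, 0.36) exactly gives 0.03904, 0.0468,
0.04880, 0.36, while the source reports 0.04, 0.046, 0.0493, 0.36 — the
small discrepancies are consistent with the nominal values having been
rounded before adjustment. The package computes exact BH and does not
"correct" toward the printed values; tests compare the smallest adjusted
value at two decimals and the largest exactly.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` generates the complete input bundle from a seed, with
per-stage random streams (reference / variants / typings / resources /
metadata / outcomes) so changing one knob perturbs only its stage.
Study-condition defaults: 157 sibling pairs; cGvHD "limited" fraction
23/151; a small minority (~6%) of pairs with 1–3 mismatched HLA alleles
(the rest 12/12-identical siblings); a planted ligand-count effect of 0.6
log-odds per SD on M1 with covariate effects of plausible sign and size
(negative female-to-male-avoidance, positive donor age, negative HLA
frequency sum). Desk-scale defaults chosen once and documented here rather
than tuned: 60 transcripts of 300–900 nt (real exomes have ~20,000 —
counts scale linearly and the statistical machinery is size-agnostic),
~0.8 non-synonymous variants per transcript per subject with 85% donor–
recipient sharing, 200 decoy ligands per class I allele, 5% planted
ligand overlap, 50% of genes "supportive" in a target tissue.

Synthetic CDS sequences sample codons uniformly from the 61 non-stop
codons, so internal in-frame stops cannot occur by construction and
frameshift tests control their own stop codons; shifted reading frames
still hit stops by chance, as in real sequence. Genotype DP/GQ values
include a 2% low-quality fraction to exercise the hard filter —
note that this dropout is *per genotype*, so a shared variant can lose one
side's genotype and legitimately create a mismatch; conservation checks
(zero variant rate, or 100% sharing implying zero mismatched peptides)
therefore disable the dropout, which is part of specifying the degenerate
condition.

`simulate_association_cohort()` is the fast path for replicate studies: it
draws the per-pair estimate/covariate/outcome table directly from a
three-level count model — a shared mismatch burden (tight, CV ≈ 0.2, as
the reported totals), a shared HLA-presentation factor common to M1–M4
but not the totals, and method-private overdispersion calibrated to the
reported per-statistic spread (M1 CV ≈ 0.45 up to M4 CV > 1). Planting
the outcome effect on the presentation factor (`effect_method =
"presented"`) reproduces the direction-consistency phenomenon: all four
estimators inherit a positive coefficient beyond what the total-mismatch
covariate absorbs.

What the generator does **not** emulate: real human allele-frequency
spectra or linkage between loci; realistic variant clustering, multi-
allelic sites or genome-space coordinates; proteasomal cleavage and TAP
transport (out of scope for the scoring too); sequencing read-level error.
Passing tests therefore demonstrate the correctness and calibration of the
*computational machinery* under controlled truth, not the biological
validity of the estimators on real cohorts.

## Numerical and procedural details

* Counts and set operations are exact; no tolerance is involved anywhere
  before the regression stage.
* `glm` convergence: epsilon 1e-10, maxit 100; Wald p-values from the
  standard normal; `z = estimate / SE` holds to 1e-10 by construction.
* Percentile ranks live in (0, 100]; rank tables are validated on read.
* Allele names are normalized to two-field resolution before any keying
  or comparison; unparseable names warn and drop rather than abort.
* Ties/duplicates: duplicate ligand rows collapse per allele; duplicate
  peptides across transcripts merge provenance.
* Problem sizes in the test-suite and acceptance runs: micro-instances of
  ≤ 5 transcripts × ≤ 4 variants for brute-force oracle equivalence (200
  instances); 10–80-pair sequence-level cohorts for pipeline properties;
  150-pair association cohorts × 300 replicates for effect recovery and ×
  200 for null calibration; one 157-pair study-scale cohort for the
  end-to-end run. These sizes were chosen so the whole suite documents
  the statistical properties at interactive cost; all scale knobs are
  config fields.

## Known limitations

* Exclusively 9-mer, HLA class I; class II ligands and other lengths are
  out of scope.
* The two-pseudo-haplotype rule can merge variants that lie on opposite
  real haplotypes into one protein; with phased input one would apply
  variants per true haplotype instead.
* The expression filter is binary reliability-based; quantitative
  expression levels are not modeled.
* Cohort-scale results on synthetic data are not comparable in magnitude
  to a real exome cohort (the desk-scale reference is ~300× smaller than
  a real transcriptome); only structure, calibration and invariants
  transfer.
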