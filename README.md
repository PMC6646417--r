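# allopep

Estimating HLA-presented donor–recipient mismatch and its association with
chronic graft-versus-host disease (cGvHD) in HLA-matched sibling stem-cell
transplantation.

## The problem

After an HLA-matched allogeneic hematopoietic stem-cell transplantation,
donor T cells can still attack recipient tissues: polymorphic peptides that
differ between donor and recipient and are presented by the recipient's HLA
class I receptors act as minor histocompatibility antigens (mHAs). Only a
few dozen mHAs are experimentally validated, so cohort studies need
computational estimates of each pair's alloreactivity potential. `allopep`
implements such a pipeline end to end:

1. **Personal proteomes** — paired donor/recipient coding variants (VCF in
   transcript space, annotated `transcript|effect|cds_pos|ref|alt`) are
   hard-filtered on read depth and genotype quality, applied to an
   ATG-initiated, length-filtered CDS reference, and translated into
   per-subject protein sets (two pseudo-haplotypes per transcript).
2. **Recipient-unique 9-mers** — transcripts whose protein sets differ are
   split into all overlapping 9-mer peptides; peptides present in the
   recipient but absent from the donor form the candidate alloantigen set
   *U*, with transcript/gene provenance.
3. **Four alloreactivity estimators** (per pair, with *F* = *U* filtered by
   a position-weighted T-cell immunogenicity score > 0.2 and by supportive
   protein expression in skin, intestine, lung, liver or bone marrow):

   | method | definition |
   |--------|------------|
   | M1 | \|U ∩ IEDB ligands\| for the recipient's class I alleles |
   | M2 | \|F ∩ IEDB ligands\| |
   | M3 | \|U ∩ known 9-mer mHAs\| |
   | M4 | \|{p ∈ F : percentile rank ≤ 4 for ≥ 1 recipient HLA-A/-B allele}\| |

4. **Association** — per estimator, a logistic regression of cGvHD
   "no" (0) vs "extensive" (1) (pairs graded "limited" excluded):

   logit P(extensive) = β₀ + β₁·ligand count + β₂·mismatch total +
   β₃·Σ HLA freq + β₄·tr. direction + β₅·donor age + β₆·n unique HLA +
   β₇·tr. year + β₈·HLA match count,

   all numeric predictors centered and scaled, Wald tests, and
   Benjamini–Hochberg adjustment across the four ligand-count p-values.

Because the underlying patient data are not public, the package ships a
deterministic synthetic-cohort generator (`simulate_cohort()`,
`simulate_association_cohort()`) that emulates every input format —
reference FASTA, per-pair annotated VCFs, HLA typing table, IEDB-style and
mHA ligand tables, HPA-style expression table, affinity percentile ranks,
and outcomes drawn from a configurable logistic model — so the full
pipeline is reproducible and statistically testable from a seed.

## Worked example

The `analysis/` scripts run the whole study on a simulated cohort:

```sh
Rscript analysis/01_simulate.R 1        # 157-pair synthetic bundle -> results/run
Rscript analysis/02_pipeline.R          # estimates + association tables
Rscript analysis/03_allele_coverage.R   # ligand-database allele coverage
Rscript analysis/04_calibration.R 1     # effect recovery + null calibration
```

With seed 1 the pipeline step prints:

```
estimates for 157 pairs:
  total_mismatched   mean   160.73  [ 51.0,  437.4] (2.5-97.5 pct)
  total_filtered     mean    13.26  [  0.0,   46.2] (2.5-97.5 pct)
  m1                 mean    10.70  [  2.0,   32.7] (2.5-97.5 pct)
  m2                 mean     0.71  [  0.0,    3.0] (2.5-97.5 pct)
  m3                 mean     2.29  [  0.0,    9.1] (2.5-97.5 pct)
  m4                 mean     2.04  [  0.0,    8.0] (2.5-97.5 pct)
ligand-count associations (135 pairs analyzed):
  M1  coef  0.898 (SE 0.547)  p 0.1009  BH-adjusted 0.2018
  ...
```

i.e. per-pair counts of recipient-unique peptides and their
HLA-presentation-based subsets (mean and empirical 2.5–97.5 percentile
interval), then each estimator's standardized log-odds coefficient for
extensive cGvHD with nominal and FDR-adjusted p-values. The calibration
step prints

```
effect recovery over 300 cohorts: mean coef 0.637 (truth 0.6), 95% Wald coverage 95.0%
null calibration over 800 method tests: BH-adjusted rejection rate 0.016 at FDR 0.05
```

showing that the association stage recovers a planted ligand-count effect
essentially unbiased with nominal confidence-interval coverage, and stays
within the FDR level under the null.

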