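---
title: "Genome-wide predictive studies: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide predictive studies: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwps)
```

## The problem

A genome-wide association study asks, SNP by SNP, whether genotype
frequencies differ between cases and controls. A genome-wide *predictive*
study asks a harder question: given the full genotype profile of a previously
unseen subject, can we predict their phenotype? With hundreds of thousands of
SNPs and a few hundred subjects, the central methodological danger is not the
learner but the *evaluation*: any step that looks at all subjects — feature
selection above all — before cross-validation splits the data will leak
information about the held-out subjects and inflate apparent accuracy, on
pure noise, from ~50% to well above 90%. This package implements the
pipeline and both evaluation protocols (honest and deliberately leaky) so
the contrast itself is reproducible.

## Data model

Genotypes are coded 1 (wild-type homozygote), 2 (heterozygote),
3 (variant homozygote); a missing call is `NA` in the integer matrix and
`"."` in the on-disk TSV. We use `NA` rather than a numeric sentinel because
it propagates through every arithmetic path automatically — a missing call
can never silently enter a mean or a distance. Labels are a factor with
levels `control`, `case`; `case` is the positive class in all derived
metrics.

On VCF import, code 3 means the ALT homozygote whatever the allele
frequencies, because that convention is reproducible without estimating
frequencies; the simulator, by contrast, orients code 3 to the minor
(variant) allele it draws from, which removes strand ambiguity in
synthetic truth.

## Quality control

Three SNP-level filters, applied in one pass over the original matrix:

* **Missingness** — any missing call removes the SNP. This is absolute:
  the other statistics are still reported (computed on available calls) for
  diagnostics, but cannot rescue the SNP.
* **Hardy-Weinberg equilibrium in controls** — Pearson chi-square with 1
  degree of freedom against expected proportions
  \(((1-q)^2,\,2q(1-q),\,q^2)\) at the allele frequency estimated from the
  same controls; removal at nominal \(p < 0.001\). We use the chi-square
  rather than the exact test: it is the conventional default, has a closed
  form that an independent oracle can reproduce, and at the sample sizes
  where this pipeline is sensible (hundreds of controls, MAF ≥ 5%) the
  asymptotics are comfortably valid. Monomorphic SNPs fit trivially
  (\(\chi^2 = 0, p = 1\)). The test is restricted to controls because a true
  risk locus deviates from HWE in cases even when genotyping is perfect.
* **Minor allele frequency** — computed over *all* subjects (common GWAS
  practice; controls-only would also be defensible, and the threshold is a
  plain argument); removal if MAF < 0.05, with the boundary itself
  surviving ("less than 5%" read strictly).

Filters are evaluated independently, so a report row can list several
failures; survivors are SNPs with none.

## Feature selection and the classifier

`MeanDiff` is the absolute difference of per-class genotype-code means — a
univariate filter that is fast enough to re-run inside every
cross-validation fold, which is precisely what honest evaluation requires.
The top m SNPs are kept; ties at the boundary break by ascending column
index so selection is deterministic across platforms (scores are rationals
from small-integer arithmetic, so exact float equality detects true ties).
The default m = 500 reflects the regime the pipeline was designed for;
`m_sweep()` re-estimates accuracy over a grid (500–1500 by default) to check
robustness to that choice.

The classifier is plain KNN under squared Euclidean distance on the codes,
majority vote, no distance weighting. Two totality choices the distance
contract needs: equal distances at the k-th position are resolved by
ascending training-subject index (exactly k voters, deterministically), and
a tied vote — impossible for binary labels with odd k, but the contract must
cover even k — falls back to the training majority class.

**BestKNN** chooses k ∈ {1, 3, 5, 7} by internal r = 10-fold
cross-validation in which each fold's top-m SNPs are re-selected on that
fold's training complement alone; each k is scored by its mean fold
accuracy, ties go to the smallest k (simplest model), and the final
classifier is refit on all data with the winning k. Folds are stratified by
class with a seeded shuffle — stratification is not strictly required but
protects small internal folds from class imbalance, and the seed is recorded
so a fit is exactly reproducible. The chosen k is data-dependent; no
particular value is asserted anywhere.

## Evaluation

`nested_loocv` re-runs the *whole* procedure — selection and k-tuning — on
every leave-one-out training set; `biased_loocv` selects once on the full
data and is otherwise identical (per-fold k-selection is retained on the
fixed panel, so feature-selection leakage is the *only* difference between
the two estimates). When m equals the SNP count the selection step is
vacuous and the two procedures coincide exactly — a useful structural test.

`permutation_test` builds the empirical null by permuting labels (class
counts preserved) and repeating nested LOOCV B times. The p-value uses the
add-one estimator \((x+1)/(B+1)\), which is never zero and counts ties as
exceedances (conservative); with zero exceedances at B = 100 it yields
1/101 < 0.01.

Reported percentages are rounded half-up to two decimals; raw proportions
are always kept alongside. Metrics with zero denominators are `NA`, never 0.

## The synthetic-data generator

The simulator is the package's substitute for cohort data: unlinked
biallelic SNPs, genotypes drawn per subject from HWE proportions at a MAF
uniform on `maf_range`, identically in cases and controls for null SNPs.
Planted structure:

* **effect SNPs** shift the case allele frequency by `effect_delta`
  (capped at 0.999), each group in HWE within itself. This additive
  allele-scale effect was chosen over genotype odds-ratio models because
  its expected MeanDiff has the closed form \(2\,\Delta q\)
  (`expected_meandiff`), giving parameter-recovery tests an exact target.
* **HWE-violating SNPs** use inbreeding-distorted proportions
  \(((1-q)^2 + Fq(1-q),\, 2q(1-q)(1-F),\, q^2 + Fq(1-q))\) in all subjects.
* **low-MAF SNPs** fix q below the 5% cutoff; **missing-call SNPs** blank
  each genotype with probability `missing_rate` (at least one forced).

Defaults emulate a single-cohort study of 302 cases and 321 controls at
desk scale: 10,000 SNPs stands in for a ~900k-SNP array (the pipeline is
O(subjects × SNPs) per fold, so conclusions about *relative* behaviour
transfer; absolute runtimes do not), MAF in (0.05, 0.5], inbreeding F = 0.8
(a blatant violation, appropriate for testing a filter rather than
estimating its power curve), low-MAF q = 0.01, missing rate 5%.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, population structure and admixture, genotyping batch effects,
covariates, and any relationship between effect SNPs and real biology. A
green test suite therefore shows the *algorithms* are correct and the
evaluation honest — not that any particular accuracy is attainable on real
cohorts.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the pipeline at sizes chosen to
make the statistical assertions decisive while staying desk-scale: the
selection-bias contrast on pure-null data at n = 100, p = 10,000, m = 500
(nested lands near 50%, non-nested near 100%, gap ≥ 0.15 asserted); nested
LOOCV power at n = 120 with 30 planted effect SNPs at Δq = 0.45 among 1,000
nulls (≥ 80% asserted, with the null counterpart within 4 binomial standard
errors of 50%); QC calibration at n = 2,000 with null MAF bounded away from
the threshold so the rare-variant filter's removals are exactly the planted
set and the HWE filter's false-removal rate can be compared to its nominal
0.001; and permutation calibration at B = 19 (the smallest B certifying
p = 0.05) with 10 null repeats. Oracle checks (exhaustive distance-sort KNN,
independent score-sort selection) sweep instances up to 30 subjects × 5
SNPs, where brute force is instant.

## Known limitations

* MeanDiff is univariate: it cannot find purely epistatic signal, and
  correlated SNPs are selected redundantly.
* KNN on 1/2/3 codes weights a homozygote difference 4× a heterozygote
  difference (squared distance); that is the method's definition, not a
  tunable.
* The LOOCV estimate, while unbiased for the procedure, has high variance
  at small n, and leave-one-out training sets are slightly class-imbalanced
  against the held-out subject — visible as null accuracies marginally
  below 50%.
* The permutation test re-runs nested LOOCV B times; at array scale this is
  expensive by construction (it was the original method's dominant cost,
  too). Scale B and n to the question.
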