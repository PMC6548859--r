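---
title: "Dosage-based genomic selection in autotetraploids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-based genomic selection in autotetraploids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spudgs)
```

spudgs implements the computational path from tetraploid sequencing read
counts to genomic-selection prediction accuracies: five-class allele-dosage
calling, variant filtering, LD k-nearest-neighbour imputation, BayesA/BayesB
whole-genome regression by Gibbs sampling, cross-validated accuracy and bias
evaluation, and genetic-diversity summaries (Nei distance, neighbour
joining). This vignette explains the models, the choices that were genuinely
open, and what the synthetic cohort does and does not demonstrate about real
data.

## Dosage coding

An autotetraploid genotype at a biallelic locus is one of five classes,
AAAA, AAAB, AABB, ABBB, BBBB, coded throughout as the **reference-allele
frequency** of the individual: 1, 0.75, 0.5, 0.25, 0 (so AABB = 0.5). The
expected alternate-read fraction of a cell is therefore `1 - code`,
perturbed by symmetric base error. This one convention is fixed once and
used by every module: the caller, the imputer (which may emit fractional
codes), the genomic-selection design matrix Z, and the per-individual
"allele frequencies" entering Nei's distance.

## Dosage calling and filtering

`call_dosages()` assigns the class nearest to the observed reference
fraction, with bin edges at 0.125, 0.375, 0.625, 0.875 — the
maximum-likelihood rule under symmetric binomial read error, since no class
boundaries are standard. Cells with total depth below 5 are missing; a cell
with some but fewer than 2 alternate reads cannot be called heterozygous and
falls back to homozygous reference. Both thresholds are configurable.

Accuracy of the nearest-class rule is depth-limited by binomial allele
sampling alone: at depth 30 the simplex class (AAAB) is misclassified 8.8%
of the time and the duplex class (AABB) 20% of the time even with zero
sequencing error (exact binomial tail mass outside the class bins). Recovery
of 99% of cells needs on the order of 100 reads; the test suite verifies
≥ 99% recovery at mean depth 150. At the default mean depth of 15, calling
error is a substantial — and realistic — noise source for everything
downstream.

`filter_variants()` applies three rules, in a fixed order that makes the
per-reason failure counts exclusive: (a) alternate support — at least one
sample with ≥ 5 alternate reads at an alternate fraction ≥ 0.4 ("more than
four reads" read as a strict inequality); (b) missingness — loci with 50%
or more missing genotypes are removed (strict); (c) MAF — loci at 5% or
less are removed (strict), with MAF computed on the mean dosage code, i.e.
on allele frequency, matching the coding used downstream. Whether the 0.4
alternate-fraction rule was applied per sample or per variant upstream of
extraction is not decidable from the description we follow; it is
implemented as "at least one sample satisfies it".

## LD k-nearest-neighbour imputation

For each locus with missing cells, all other loci are ranked by squared
Pearson correlation with it over jointly observed samples ("closest loci"
is read as highest-LD, not physically nearest, consistent with the method's
name); the top 17 are kept. A missing sample's Euclidean distance to every
observed sample is computed over those loci, normalised by the number of
jointly observed loci so residual missingness does not penalise a sample,
and the mean code of the 11 nearest observed samples is imputed. Ties in r²
break by genomic coordinate and ties in distance by sample order, so the
procedure is deterministic. Fewer observed samples than k falls back to all
of them. Imputed values stay continuous in [0, 1]: genomic selection
consumes allele frequencies, so there is nothing to gain by re-binning.

Imputation quality tracks LD, as it must: with two founder haplotypes per
chromosome the masked-cell correlation with truth exceeds 0.98, while on the
default 2,000-locus genome-wide panel (weak LD between most locus pairs) it
only modestly beats column-mean imputation. The real transcriptome panel it
emulates is ~90× denser, with correspondingly stronger local LD.

## BayesA / BayesB whole-genome regression

The model is `y = mu 1 + Z v + e` with Z the samples × markers matrix of
dosage codes. BayesA places a per-marker scaled-inverse-chi-squared variance
on each effect (marginally a scaled-t prior); BayesB adds a spike at zero:
each marker is in the model with prior probability `prob_in` — the
probability of a **non-zero** effect, fixed rather than estimated. A
single-site Gibbs sampler (Rcpp) updates mu, each effect (for BayesB the
inclusion indicator is drawn from its marginal odds with the effect
integrated out), each marker variance, and the residual variance per sweep;
posterior summaries are means over post-burn-in iterations with no thinning.
Defaults: 12,000 iterations, 1,000 burn-in, df 5 for both variance priors.

Prior scales derive from a trait heritability supplied by the user: the
marker-variance scale is `h2 * var(y) * (df + 2) / MSx`, MSx the summed
column variances of Z — so the prior mode of a marker variance is its
per-marker share of the genetic variance — divided by `prob_in` for BayesB
so sparsity preserves expected genetic variance; the residual scale is
`(1 - h2) * var(y) * (df + 2)`. These are total scales of the
inverse-chi-squared draws (`(S + v²)/chisq(df + 1)`), the convention of the
reference whole-genome-regression samplers this follows.

Columns of Z are centred before sampling (better mixing; the model is
shift-invariant), and the intercept is mapped back so `mu + Z %*% effects`
predicts on raw codes. Monomorphic columns get effect 0 with a warning.
Three exact properties anchor the implementation: with both variances
pinned, the posterior mean equals the closed-form ridge solution; BayesB
with `prob_in = 1` reproduces the BayesA chain draw for draw; and scaling y
by c scales mu and effects by c exactly under a shared seed.

## Evaluation

`kfold_cv()` partitions samples into k random folds (sizes within 1; 169
samples in 5 folds gives 34, 34, 34, 34, 33), trains on the complement,
and scores each fold by the Pearson correlation of held-out GEBVs with
phenotypes. The summary is the fold mean with SE = sd/sqrt(k) (the
"standard error across fold accuracies" left unformalised in the source
description). The bias slope — OLS of observed on predicted — is computed on
the pooled out-of-fold GEBVs ("all predicted GEBVs"), not per fold. No
stratification is applied. `max_potential_accuracy(h2) = sqrt(h2)` gives the
ceiling used for context.

Two calibration facts the tests exercise deserve emphasis. First, a
correctly specified Bayesian posterior mean is approximately unbiased: with
the prior heritability matching the simulated one, pooled slopes sit near
(slightly below) 1. Underprediction — slopes well above 1, as reported for
real dry matter (1.39) — emerges when the prior understates the genetic
signal and the GEBVs are over-shrunk; the suite demonstrates slopes > 1
with a prior h² of 0.1 against a true 0.8. Second, expected accuracy scales
like `sqrt(h2 * n / (n + m_e))` with m_e the effective number of
independent loci: at n = 300, m = 200 a dense h² = 0.8 trait is predicted
at ~0.78, inside the 0.6–0.89 band below the sqrt(0.8) = 0.89 ceiling,
while the default 181-cultivar, 2,000-locus dense cohort predicts at ~0.1 —
an honest property of that regime, not a defect.

## Diversity

Nei's standard distance treats each individual as a population of four
allele draws: with p the dosage code and q = 1 - p,
`D = -ln(Jxy / sqrt(Jx Jy))` with the J's averaged over loci (so panels of
different sizes are comparable). Identical individuals get D = 0; fully
opposed homozygotes have undefined (infinite) distance, reported as a capped
sentinel of 10 with a warning. The neighbour-joining dendrogram uses the
classic Saitou–Nei agglomeration (via ape); negative branch lengths, an
artefact of non-additive distances, are clamped to zero with the deficit
moved to the sister branch so cherry path lengths are preserved. Nei 1972 is
assumed where the upstream tooling offers several variants.

## The synthetic cohort: what it emulates, what it does not

`simulate_cohort()` generates 181 cultivars by default on the 12 potato
chromosome lengths, with loci placed inside gene intervals (density biased
toward chromosome ends, echoing the telomeric enrichment of transcript
SNPs; cosmetic and switchable). LD comes from a founder-haplotype model:
within each `ld_block_bp` window (default 1 Mb) a pool of 4 founder
haplotypes is drawn and every sample receives 4 independent copies from the
pool; two founders give near-perfect within-block LD, and loci in different
blocks are independent. Per-locus alternate-allele frequencies are uniform
on (0.05, 0.5), realised in the pool by stochastic rounding. Read counts
are Poisson(15) per cell with binomial allele sampling and error rate 0.01
(high-quality bases); phenotypes are `mu + Zv + e` with i.i.d. normal
effects (all loci, or `n_qtl` of them for sparse traits) and environmental
variance set so realised `var(Zv)/var(y)` targets h² (default 0.8);
missingness is masked completely at random at rate 0.2. Depth, error and
missingness defaults are stated assumptions — the emulated study does not
characterise them — chosen at magnitudes typical of transcriptome-based
genotyping (about 3M reads spread over a ~180k-SNP panel gives mean depth
in the teens).

Not modelled: coalescent or pedigree structure, allele-specific expression,
library preparation or splice artefacts, selection, population structure
beyond the founder pools. Passing tests on this cohort demonstrate the
correctness and calibration of the algorithms under known truth; they do
not certify accuracy figures for any real panel, whose LD, depth profile
and trait architectures differ.

## Problem sizes and numerics

The test suite and acceptance script run at deliberately modest sizes —
cohorts of 150–500 samples, 100–200 markers, chains of 1,500–6,000
iterations (4,000 for the cross-validation studies) — chosen so the full
suite completes in minutes while leaving Monte-Carlo error well inside the
asserted tolerances; the analysis scripts use the full defaults (181 × 2,000,
12,000 iterations). Degenerate inputs are errors, not guesses: constant
phenotypes, monomorphic LD targets, loci with no observed genotype, folds
with constant phenotype, heritability outside (0, 1]. Variance draws are
floored at 1e-12 to keep the chain numerically positive, and negative
rounding artefacts in distances are clamped to 0.
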