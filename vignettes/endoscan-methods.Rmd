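---
title: "Categorical ANCOVA scans for disease endophenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorical ANCOVA scans for disease endophenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoscan)
```

## The problem

Genome-wide association studies of heterogeneous diseases usually collapse
all cases into one group, or compare one disease subtype against everything
else. When the phenotype is a set of K ordinal *endophenotypes* — for
example five severity/atopy categories of childhood asthma derived from a
clinical principal-component axis — both designs lose information: the
single-case design assumes a shared architecture, and the one-vs-rest (OVR)
design multiplies the number of tests and splits the sample.

`endoscan` implements the alternative: treat the K endophenotypes as the
levels of a single categorical factor and test them simultaneously,
per variant, in one model.

## The core model

For each variant, the *reverse-regression* ANCOVA takes the genotype dosage
\(y_i \in [0,2]\) as the response:

\[
y_i = \mu + \beta_{g(i)} + \gamma_1\,\mathrm{age}_i +
  \gamma_2\,\mathrm{sex}_i + \sum_{j=1}^{10}\delta_j\,\mathrm{PC}_{ji} +
  \varepsilon_i ,
\]

where \(g(i)\in\{1,\dots,K\}\) is the sample's endophenotype and the PCs
are ancestry principal components. The factor is tested with the partial
(model-comparison) F statistic

\[
F \;=\; \frac{(\mathrm{SSE}_\text{reduced} - \mathrm{SSE}_\text{full})/(K-1)}
             {\mathrm{SSE}_\text{full}/df_2},
\qquad df_2 = n - K - p_{\text{cov}},
\]

with the reduced model dropping the factor. With a single factor this
partial test coincides with Type-II and Type-III tests, so the distinction
among ANOVA "types" is moot here. Dosage is a perfectly ordinary linear-model
response at these sample sizes: it is bounded and discrete, but the F test
only needs approximate normality of group means, and the package's
calibration suite confirms nominal behavior (below).

Modeling genotype as the response rather than the predictor keeps one model
per variant (rather than K logistic fits), lets the single F test absorb
any pattern of group differences, and makes the group means directly
interpretable as covariate-adjusted allele dosages.

### Which groups drive a hit: Tukey contrasts

For significant variants, all \(K(K-1)/2\) pairwise contrasts of the
covariate-adjusted (least-squares) group means are tested against the
studentized range distribution with \((K, df_2)\). Adjusted means are used
rather than raw means because the contrasts are asked to explain the ANCOVA
F test, which is itself covariate-adjusted; a raw-mean mode is available by
calling `tukey_hsd()` directly on raw group means.

Two numerical points deserve record:

* **Contrast standard errors.** The textbook Tukey–Kramer standard error
  \(\sqrt{\mathrm{MSE}\,(1/n_a+1/n_b)/2}\) is exact only when covariates
  are absent or balanced across groups. Endophenotype designs are exactly
  the case where they are *not* balanced — age rises monotonically across
  severity groups by construction. Using the plain Kramer formula there
  understates the variance of adjusted mean differences; on null synthetic
  cohorts with the default age gradient we measured a familywise error of
  0.083 instead of 0.05. The package therefore uses the exact model-based
  contrast variance \(\mathrm{MSE}\cdot c'(X'X)^{-1}c\) inside the ANCOVA
  (restoring familywise 0.047 in the same experiment), and reduces
  *exactly* to Tukey–Kramer when no covariates are present — verified
  against `TukeyHSD()` to 5e-12.
* **The studentized range tail.** `studentized_range_sf()` integrates the
  classical double-integral representation with Gauss–Legendre panels
  (96 outer nodes over the scaled error SD, 192 inner nodes over the
  normal-range CDF; the Gaussian density truncates the inner integral at
  |z| = 9). Accuracy is better than 1e-6; against the exact k = 2
  reduction to the Student t it agrees to ~1e-12, which is tighter than
  base R's `ptukey` at very small df. Whole-scan contrast batches sharing
  one \((k, df)\) are evaluated on a dense exact grid and monotone-spline
  interpolated (agreement with direct evaluation < 1e-8).

### The severity-trend test

To ask whether a categorical hit follows the underlying continuous
severity axis, `severity_trend()` fits the linear reverse regression
`dosage ~ score + covariates`, where the score is a per-sample severity
value (defaulting to the ordinal group index). The "ordinal regression"
phrasing common in this area is ambiguous — proportional-odds models treat
the category as the response, which is the opposite orientation from the
scan. We deliberately keep the reverse-regression orientation for
coherence with the ANCOVA; a proportional-odds variant is out of scope.

### The one-vs-rest comparison arm

`fit_ovr()` fits `I(group = k) ~ dosage + covariates` by IRLS (tolerance
1e-8, 100 iterations) and reports the Wald test, matching the convention
of reporting one OR and one p per contrast. Separation or non-convergence
is flagged (`converged = FALSE`) rather than corrected: no Firth penalty
is applied, so unstable fits are visible instead of silently shrunk.
`multiplicity()` does the Bonferroni bookkeeping with the exact
\(\alpha/m\) threshold; printed thresholds like "0.0016" for
\(0.05/30\) are treated as display rounding.

## Quality control

`apply_qc()` applies the conventional gates in a fixed order: samples with
genotype missingness > 5% first, then variants with call rate < 95%,
folded MAF < 5%, or Hardy–Weinberg exact p < 1e-6, computed on the
samples that survived. The order matters (a removed sample can change a
variant's fate) and is therefore part of the contract, exercised in tests.
The HWE exact test enumerates heterozygote configurations conditional on
the allele counts; on imputed dosages, hard calls are formed by rounding,
and calls further than 0.1 from an integer are excluded from the HWE
counts only — soft calls carry no reliable genotype, but should not kill
the variant. Downstream analyses use per-variant complete cases rather
than mean imputation, keeping the per-test n explicit.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the scan assumes,
not real genomes:

* **Group sizes** default to the discovery cohort of the motivating
  five-group pediatric asthma design (171/154/168/163/177; the replication
  configuration uses 207/205/204/207/207). The discovery table's sizes are
  used as printed even though the accompanying text reports a slightly
  smaller analyzed count; the table is the per-group source.
* **Ages** are drawn per group around the published monotone means
  (6.96–10.88 years for discovery, 8.25–9.95 for replication) with a
  common SD of 1.8 years — a value chosen once as typical for pediatric
  cohorts spanning roughly ages 5–14; the tables print only means. This
  makes age a genuine confounder of severity in synthetic data.
* **Sex** is Bernoulli(0.40 female), matching the reported 34–47% range.
* **Ancestry PCs** are standard normal. Setting `pc_confounding` adds a
  per-PC slope to the latent allele frequency, so population structure
  genuinely inflates an unadjusted scan and PC adjustment demonstrably
  repairs it — the reason the PCs are covariates at all. Frequencies are
  clamped to (0.001, 0.999), with a loud warning if more than 1% of draws
  clamp.
* **Null variants** share one frequency across groups, drawn
  Uniform(0.05, 0.5) — the post-QC common-variant range. **Planted
  variants** carry explicit per-group frequencies; the default effect
  sizes in benchmarks use between-group differences of 0.10–0.12, the
  delta-MAF range the motivating study prints for its replicated loci.
* Genotypes are hard Binomial(2, f) draws, so within-group Hardy–Weinberg
  equilibrium holds by construction; `dosage_noise_sd` optionally adds
  truncated Gaussian noise to mimic imputation uncertainty.
* `simulate_ld_blocks()` generates AR(1)-thresholded correlated dosages
  purely to exercise LD clumping; it is not a model of human LD. Null
  variants elsewhere are mutually independent, so passing tests say
  nothing about the scan's behavior under real LD, fine-scale structure,
  or relatedness — those require real data.

What the generator does *not* emulate: realistic LD and recombination,
related individuals, genotyping batch effects, non-random missingness,
and the clinical PCA that defines the endophenotype labels (labels are
consumed as given).

## LD clumping

`clump()` is the standard greedy reduction: repeatedly take the smallest-p
remaining variant as an index and absorb every variant on the same
chromosome that shares a sliding window (width 250 variants, step 50, the
published parameters; windows are variant-count based, not kb) and has
dosage \(r^2 \ge 0.5\) with it. Ties on p break deterministically by
(chromosome, position, id). Variants whose \(r^2\) is undefined are
retained conservatively with a warning. Cross-chromosome \(r^2\) is never
computed.

## The benchmark

`run_bench()` quantifies the design argument: each replicate simulates one
variant plus covariates and hands the *same* data to (a) the ANCOVA F test,
(b) K one-vs-rest logistic fits with within-variant Bonferroni
(reject if any \(p \le \alpha/K\)), and (c) the severity-trend test.
Rejection indicators are stored per replicate so method comparisons are
paired (McNemar-style), not independent. Power comparisons default to
\(\alpha = 10^{-4}\): at desk-scale replicate counts (1000) a genome-wide
\(5\times10^{-8}\) threshold would reject essentially never for any
method and resolve nothing; the genome-wide threshold is exercised in the
calibration suite instead. The within-variant family \(\alpha/K\) matches
how a published six-loci-by-five-endophenotypes table counts its "30
possible one-vs-rest tests".

Under a diffuse alternative — two of five groups shifted upward by 0.10
in allele frequency at the discovery group sizes — the joint F-test's
power advantage over Bonferroni OVR is large (roughly 0.20 vs 0.04 at
\(\alpha=10^{-4}\) in the shipped acceptance run); under a single-group
alternative the gap narrows, which the benchmark records without
asserting.

## Prediction and the leakage demonstration

`fit_ovr_enet()` trains K one-vs-rest elastic-net logistic models
(glmnet; mixing and penalty tuned by inner cross-validation) on screened
features and reports held-out per-class AUC by the rank-statistic
definition. The scientifically important switch is `nested`:

* `nested = TRUE` re-runs the feature screen (ANCOVA p filter + LD
  clumping) inside every outer training fold — held-out samples never
  inform selection;
* `nested = FALSE` screens once on the full data, the protocol that makes
  within-cohort cross-validated AUC look good and external validation
  collapse to chance.

`screening_optimism()` runs both on identical data and reports the AUC
difference. On null cohorts the optimism is positive in essentially every
run — an operational demonstration of why in-sample feature selection
inflates apparent performance. The screening threshold used in the
demonstration (p ≤ 0.01 over 1200 synthetic markers) is chosen so that
in-sample selection admits a double-digit feature count, the same regime a
\(10^{-5}\) threshold produces on a multimillion-marker array; the
`screen_params()` default remains 1e-5 for real-scale use.

## Numerical choices and degenerate inputs

* Monomorphic variants return F = NA with reason `"monomorphic"`; scans
  never abort on per-variant failures, they emit NA rows with reasons.
* Rank-deficient designs error, naming the collinear columns; groups
  emptied by missingness error, naming the group.
* The HWE exact test's p-values are discrete and conservative by
  construction (a property of exact conditional tests, not a bug); the
  generator's HWE-consistency is therefore tested via rejection-rate
  validity at several thresholds plus uniformity of the randomized exact
  p-value, which is the correct continuous analogue.
* Every stochastic routine takes an explicit integer seed and is
  bit-reproducible from it.

## Problem sizes used in the shipped checks

The calibration suite uses 10,000 null variants at the full discovery
group sizes (n = 833); the power benchmark uses 1000 paired replicates;
parameter recovery uses 10,000 planted replicates; the leakage
demonstration uses 20 independent null cohorts of 400 samples by 1200
markers. These sizes give Monte-Carlo standard errors small enough for
every bound asserted in the tests (e.g. ±0.0065 on a 0.05 type-I rate).

## Known limitations

* No mixed models or kinship correction; cohorts are assumed unrelated.
* Additive dosage coding only; no dominance/recessive modes, no
  X-chromosome handling.
* Multi-allelic records are skipped, not split.
* The trend test is linear-in-score; proportional-odds ordinal regression
  is out of scope.
* The published AUC levels of the motivating study are not reproduction
  targets: they depend on restricted individual-level data. The package's
  prediction claim is about the *difference* between nested and naive
  screening, which is reproducible synthetically.
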