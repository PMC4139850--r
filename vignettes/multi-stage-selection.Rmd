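---
title: "Multi-stage elastic-net selection with bootstrap stability for a quantitative activity trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage elastic-net selection with bootstrap stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-marker genome scans test each SNP separately and are poorly suited to
predicting a polygenic quantitative trait: they ignore joint effects and are
confounded by linkage disequilibrium (LD) among markers. Ordinary multiple
regression is not an alternative at genome scale, because the number of
markers far exceeds the sample size and LD makes the design collinear.
`stabselgwas` implements a multi-stage remedy for a physical-activity (PA)
phenotype measured in MET·min/day:

1. **Screen**: run the covariate-adjusted single-SNP scan and keep the top-K
   SNPs by p-value at several depths K (default 1000, 2000, 3000, 4000).
2. **Joint identification**: fit an elastic net (EN) at each depth —
   penalized least squares with mixing `alpha` between the lasso and ridge
   penalties — keeping the covariates sex, age, area and BMI unpenalized.
   SNPs with nonzero coefficients are "jointly identified".
3. **Stability**: refit the EN on `B` bootstrap resamples at the tuned
   penalty; each SNP's bootstrap selection stability (BSS) is the fraction
   of resamples in which it keeps a nonzero coefficient.
4. **Intersection and thresholding**: keep SNPs jointly identified at
   *every* depth (the "common set") whose BSS reaches a threshold (default
   0.95, by default at every depth). Per-SNP p-values for the final panel
   come from one joint multiple regression with covariates.

The final panel is compared with an equally sized single-marker (p-ranked)
panel by adjusted R², and its mapped genes are tested for pathway
over-representation with Fisher and EASE-adjusted exact statistics.

## The phenotype

The PA phenotype is built from an activity questionnaire with five intensity
categories (stable, sitting, low, medium, high), each recorded in minutes
per day. Each category carries an average MET intensity — a multiple of
resting metabolic rate — and

\[ \mathrm{PA}_i = \sum_c \mathrm{MET}_c \times \mathrm{minutes}_{ic}. \]

The category intensities are survey-instrument constants, not estimates; the
defaults (1.0, 1.5, 3.0, 5.0, 7.0) follow compendium convention and are a
mandatory configuration input of `met_assignment()`. Totals above 1440
min/day are flagged, never silently dropped: whether such records should be
truncated is a study decision, not a package one.

## Tuning the penalty: why "retention" is the default

For a single predictive EN fit, the standard tuning is k-fold
cross-validation (`lambda_choice = "min"` or the sparser `"1se"`), and both
are available. For the *multi-stage* procedure the package defaults to a
different rule, `lambda_choice = "retention"`: the largest penalty at which
at least `retention_frac` (default 0.6) of the screened SNPs keep nonzero
coefficients.

The reason is the division of labour in the multi-stage design. Its pruning
power comes from the bootstrap stability score and the cross-depth
intersection, not from the penalty itself; the joint-identification stage is
meant to be liberal, passing every plausible candidate forward. In the
cohort analyses this design descends from, the EN stage retained roughly
56–64% of the screened SNPs at every depth — an operating point far more
liberal than prediction-optimal cross-validation chooses under a sparse
architecture, where CV concentrates on the few strongest signals and leaves
moderate true effects hovering at the selection boundary. A SNP at the
boundary is selected in perhaps 85–95% of bootstrap resamples and so fails a
0.95 stability threshold not because its signal is unstable but because the
selection rule is operating at the wrong scale. With the retention rule,
true signals sit far inside the selected set (per-resample selection
probability near 1), while null SNPs — selected in roughly
`retention_frac` of resamples — have essentially no chance of reaching a
0.95 BSS, and the intersection across four screen depths removes most of
what remains.

λ is tuned once on the full screened data and held fixed across the
bootstrap refits, so stability is measured for one fixed selection rule;
`retune_lambda = TRUE` re-tunes inside every resample at substantial cost.

Two further defaults follow the same logic. `alpha = 0.5` keeps a
substantial ridge component so LD partners share weight instead of being
arbitrarily dropped (the grouping effect); and `bss_rule = "all"` requires
the BSS threshold at every screen depth, matching the strict reading of the
final-selection rule (a `"deepest"` single-depth alternative is a flag).
`B = 100` bootstraps give BSS a granularity of 0.01; the unpenalized limit
(`lambda = 0`) is computed by exact least squares because coordinate descent
converges too slowly at zero penalty for tight tolerances.

## The synthetic cohort generator

No cohort data ship with the package; every stage is exercised on synthetic
cohorts with known causal architecture (`sim_config()`,
`simulate_genotypes()`, `simulate_covariates_and_phenotype()`,
`simulate_questionnaire()`).

**Genotypes.** A latent-Gaussian threshold model: each of a sample's two
haplotypes carries, per LD block, a shared standard-normal block factor
mixed with an independent residual (exchangeable correlation
`within_block_rho`, default 0.3, blocks of 10 SNPs), thresholded at the
per-SNP MAF quantile. Because haplotypes are independent, genotype
frequencies are Hardy-Weinberg consistent by construction — the test suite
verifies that exact-test p-values are uniform (after the standard
randomization correction for the discreteness of exact conditional tests).
MAFs are drawn log-uniformly from `maf_range` (default 0.05–0.5): an
array-like decreasing frequency spectrum for which mean per-sample
heterozygosity (≈0.28) and mean unrelated-pair identity-by-state (≈0.75)
fall below the default QC thresholds (0.30 and 0.80), as they do on real
genotyping panels. A uniform spectrum would push mean heterozygosity to
≈0.36 and make the default heterozygosity filter nonsensical.

**Phenotype.** `pa = intercept + effects·(sex, age, area, bmi) + Σ βⱼ gⱼ +
noise`. Covariates: sex ~ Bernoulli(0.5), age ~ Uniform(40, 69), area ~
Bernoulli(0.5), BMI ~ Normal(24, 3). Default effects give men a ≈67
MET·min/day advantage and the rural area a ≈640 MET·min/day advantage, with
`intercept = 978.5` and `noise_sd = 786` chosen so the marginal phenotype
has mean ≈1332 and SD ≈871 MET·min/day once covariate and genetic shares
are included. Causal SNPs are drawn one per LD block (so their variance
contributions are additive) and each β is scaled to contribute
`h2_per_causal` of the total variance; signs are random. Gaussian noise is
the default; because a Gaussian phenotype can go negative in noisy
configurations, a `family = "lognormal"` switch provides the positive,
right-skewed alternative (multiplicative noise with matched conditional SD)
and is the pipeline default, since the questionnaire inversion requires
nonnegative totals. The distribution family of real PA phenotypes is
right-skewed; neither choice is asserted as the true data-generating law.

**Questionnaire.** Rather than forward-simulating durations and deriving
the phenotype, the generator inverts the phenotype: a Dirichlet(1,…,1) draw
splits each sample's PA into five MET·min shares, converted to minutes by
the category intensities. The round trip through `compute_total_pa()` is
then exact by construction, which is what the round-trip tests rely on;
`round_minutes = TRUE` trades that exactness for integer minutes.

**What the generator does not emulate**: population structure and
admixture, X-chromosome markers, genotyping-intensity artefacts, haplotype
-copying LD (the exchangeable-block model has no decay with distance), and
questionnaire reporting error. Passing tests therefore show the procedure's
behaviour under a clean, well-specified architecture — not robustness to
the full messiness of cohort data.

## Quality control

`sample_qc()` applies filters in a fixed order — missingness (>4%),
heterozygosity (>30%), reported/inferred sex mismatch, disease-exclusion
flag, relatedness (pairwise IBS > 0.80) — each sample counted at the first
stage it fails, so stage counts are sequential and disjoint. Autosomal data
cannot infer sex, so the sex check consumes a caller-supplied inferred-sex
column and is skipped with a warning when absent. From each related pair
the member with higher missingness is dropped (ties: lexicographically
later id). `marker_qc()` then removes markers by call rate (>5% missing),
MAF (<0.01) and the Hardy-Weinberg exact test (p < 1e-6), computed on all
post-sample-QC individuals. The HWE p-value is the exact conditional
two-sided test (summing probabilities of heterozygote configurations no
more probable than the observed one), verified against full enumeration for
every genotype triple with total ≤ 50. Missing calls are then imputed by
the per-SNP modal genotype (ties toward the lower code): downstream joint
modelling needs complete additive dosages, and at the few-percent
missingness the generator emulates, mode imputation perturbs them
negligibly.

## Numerical choices and degenerate inputs

Screening ties are broken by |t| descending then SNP id, making screens
deterministic and nested. Monomorphic SNPs are flagged with `beta = 0, p =
1` rather than dropped. The scan residualises phenotype and genotypes on
the covariates once (Frisch–Waugh–Lovell), which reproduces the full
per-SNP multiple regression exactly and is validated coefficient-by-
coefficient against a normal-equations oracle at 1e-8. Bootstrap refits
approach the fixed λ along a short decreasing path for solver stability; a
resample whose fit fails is redrawn once, then counted as selecting
nothing, with a warning. Rank-deficient designs in `adjusted_r2()` drop
collinear columns (with a warning) and adjust the predictor count.

## Problem sizes used in the test suite

The acceptance-grade simulations run at deliberately moderate scale: the
headline parameter-recovery experiment uses n = 2000 samples, p = 5000 SNPs
in LD blocks, 10 causal SNPs each explaining 1% of variance, screen depths
{500, 1000, 2000, 4000} and B = 50 bootstraps across 10 generator seeds;
oracle-equivalence checks use exhaustive grids (HWE totals ≤ 50,
hypergeometric universes ≤ 60); calibration checks use 2000 null SNPs at
n = 500. These sizes keep the full suite reproducible on a single CPU while
leaving every stage's statistical behaviour visible.

Recovering ≥ 8 of 10 causal SNPs with few false positives at these settings
is intrinsically borderline, and not every seed achieves it: with B = 50
resamples, even a SNP selected with probability 0.97 per resample fails a
0.95 BSS threshold in ≈19% of runs at a single depth (and more under the
all-depth rule), and a 1%-variance SNP's realised association can fall
below the strongest null signals among 5000 markers. The package reports
what the procedure achieves; it does not tune the generator to flatter it.

## Limitations

In-sample adjusted R² (the default in `build_r2_curves()`, mirroring the
descriptive comparison this pipeline descends from) overstates honest
predictive accuracy. Relatedly, the advantage of a stability-ranked panel
over a single-marker p-ranked panel depends on the data's correlation
structure: when causal variants are near-independent and effects additive
— as in the generator's recovery conditions, which place causal SNPs in
distinct LD blocks — the marginal p-value ordering is already close to
optimal and a bootstrap-stability score of finite B is a noisier surrogate
for it, so the stability-ranked curve need not dominate. The ranking's
value lies in collinear regions, where marginal statistics spread credit
across LD partners. Raw
enrichment p-values are reported without multiple-testing correction, with
significance called at EASE p < 0.1 — appropriate for hypothesis
generation, not confirmation. The enrichment universe defaults to all genes
mappable from the panel and is configurable; conclusions can be sensitive
to that choice.
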