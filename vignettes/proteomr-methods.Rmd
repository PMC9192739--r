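---
title: "Methods: serum proteogenomics and Mendelian randomization with correlated cis instruments"
author: "proteoMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum proteogenomics and Mendelian randomization with correlated cis instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

proteoMR implements an end-to-end serum proteogenomic analysis for a staged
binary disease (the motivating application is age-related macular
degeneration, AMD, in an elderly population cohort): protein preprocessing,
protein–disease association, pQTL scanning, stability selection of protein
predictors, and a two-sample Mendelian randomization (MR) engine for
correlated cis instruments. Because individual-level cohort data of this
kind are access-controlled, the package ships a synthetic-cohort generator
with a fully known ground truth; every analysis stage has a
parameter-recovery or oracle test against it.

# The synthetic two-sample cohort

**Genotypes.** Each LD block is generated from a latent multivariate
Gaussian: per haplotype, a correlated Gaussian vector is thresholded at the
MAF-determined quantile, and the two haplotype indicators are summed into a
dosage in {0, 1, 2}. This preserves Hardy–Weinberg proportions exactly at
the drawn MAF. The latent pairwise correlation is calibrated by
root-finding on the bivariate-normal orthant probability so that the
*genotype* correlation (not the latent one) matches the configured signed
target r; infeasible targets (beyond the Fréchet-type bound implied by the
two MAFs) are rejected with a diagnostic. The calibrated matrix is repaired
to the nearest correlation matrix (eigenvalue clipping) when needed.

**Proteins.** Each analyte is a sum of per-allele genetic effects (cis
and/or trans), a module latent factor with loading sqrt(module r), an
optional shared standard-normal confounder, and independent Gaussian noise
chosen so the total variance is 1. Configured effects are therefore on the
SD scale and a marginal per-allele regression recovers them when effect
variants are unlinked. Genes of cis-regulated proteins are placed at their
cis variants; all other genes are placed on chromosome 22, so trans effects
are distal by construction.

**Disease.** A logistic model: logit P(case) = intercept + sum of
protein effects (the causal path) + direct variant effects (the pleiotropy
knob, violating the exclusion assumption) + confounder (violating
instrument independence) + age and sex terms. The intercept is solved
numerically so the expected prevalence matches the target. Severity stages
among cases follow multinomial proportions defaulting to the cohort-scale
ratios early:late = 1755:272, with a stricter early definition nested in
the broader one (1054 of 1755) and late subtypes (pure geographic atrophy,
neovascular, mixed). The defaults emulate ~5,000 subjects aged 67+ (mean
76.6, SD 5.6), 57.3% female, overall prevalence 0.37.

**Two samples.** The exposure and outcome cohorts share one variant map
(drawn deterministically from the configuration seed) but no individuals;
outcome summary statistics are per-variant logistic log-odds ratios so the
MR stage combines SD-scale exposure effects with log-OR outcome effects,
as a consortium GWAS would supply.

What the generator does *not* emulate: recombination-map LD decay,
imputation uncertainty, assay batch effects, longitudinal protein change,
population structure and relatedness. Passing tests therefore demonstrate
correctness of the statistical machinery under a clean generative model,
not robustness to those real-data features.

# Protein preprocessing

Per analyte, a Box–Cox transform parameter lambda is chosen by profile
maximum likelihood on the fixed grid [-2, 2] step 0.01 (lambda = 0 meaning
log); nonpositive analytes are shifted by -min + 1e-6·SD first (recorded).
Transformed values are centred and scaled to mean 0, SD 1. Constant
analytes have no defined lambda and are flagged and passed through centred.

Extreme outliers are excluded with a two-level rule on the scaled data:
each analyte's 99th percentile is computed, the 99.5th percentile of the
distribution of those cutoffs becomes one global threshold, and values
above it are set to missing per value (a sample losing one analyte keeps
the others). Downstream regressions drop missing values case-wise per
model. Two fixed conventions: quantiles use linear interpolation between
order statistics (type 7) everywhere in the package, and the global
threshold is computed once and stored in the preprocessing report, so
repeating the exclusion with the same report is a no-op (idempotence). The
order of operations — transform, scale, per-analyte 99th percentile,
global 99.5th percentile, exclusion — pins "after scaling" down
explicitly.

# Association stage

The study-wide screen fits one age- and sex-adjusted logistic regression
per analyte. The multiple-testing unit is the number of *unique gene
symbols*, not analytes, because several aptamer-style analytes can target
one protein: with 4137 genes the threshold is 0.05/4137 = 1.21e-5, and the
adjusted P is the Bonferroni value min(1, P × genes). Fits with
non-convergence or exploding SEs (separation) are flagged rather than
reported as significant.

Quantile profiles bin an analyte into quintiles (or quartiles) by rank,
ties broken by stable sample order so bins are deterministic and differ in
size by at most one. Two logistic models are fitted: bins as a factor (per-
bin predicted log odds at mean covariate values, delta-method CIs) and
bins as a numeric 1..q score (log OR per bin). The top-vs-bottom contrast
is the q-th bin coefficient against the reference bin, which is exactly the
expected marginal difference at fixed covariates in a logit model.

Module enrichment is a two-sided Fisher exact test on the 2×2 table of
hits × module membership over the tested universe, reported with the
sample odds ratio ad/bc. Eigenproteins are principal-component scores of a
module's standardized sub-matrix: loadings have unit norm and each
component's sign is fixed to correlate positively with the module mean
profile; samples missing more than half the module's values get missing
scores, remaining missing values are mean-imputed for the decomposition.

# pQTL scan

Additive-model linear regression of every analyte on every variant dosage
(dosages used as-is, no hard-calling), adjusted for age and sex, computed
by residualizing both sides on the covariate design (Frisch–Waugh), which
is algebraically identical to the full fit including its degrees of
freedom. Monomorphic variants are skipped with a message. A record is cis
when the variant lies within the closed interval gene body ± 500 kb on the
gene's chromosome (1-based inclusive coordinates, the same window used for
MR instrument selection), trans otherwise. Records below P = 1e-6 are
flagged reportable; any analyte's records can be exported as exposure
summary statistics in the standard layout
`variant chrom pos ea oa beta se p n`.

# Stability selection and model comparison

Bootstrap-LASSO: B resamples of subjects with replacement; per resample an
L1-penalized logistic model over all analytes with age and sex included but
unpenalized (penalty factor 0); penalty chosen per replicate by 10-fold
cross-validated deviance. The default penalty rule is the one-standard-error
rule. The minimum-loss rule is also available, but it optimizes prediction,
not support recovery: at realistic sizes it admits tens of noise analytes
per replicate, so individual null analytes accumulate selection fractions
around 0.4–0.5 and stability fractions stop separating signal from noise;
the parsimonious 1-SE rule keeps null medians near 0.1 while strong
predictors remain selected in essentially every replicate. Per analyte we report the fraction of non-zero
coefficients, the mean coefficient, and 2.5%/97.5% quantiles; analytes at
or above the threshold fraction (default 0.8, with B = 500 in a full
analysis) are selected. Replicates with a single outcome class are redrawn
and logged. One master seed derives per-replicate seeds, so results are
reproducible and invariant to analyte column order.

AUC is the tie-corrected Mann–Whitney statistic with a DeLong CI. Nested
model comparison fits both logistic models and tests the paired AUC
difference by a stratified bootstrap of the two correlated ROC curves
(2,000 resamples by default): a named F-type test for equality of ROC
curves is not standardly defined, so the bootstrap is the implemented
contract.

# The MR engine

**Instrument selection.** For each protein: restrict exposure statistics
to the cis window (gene body ± 500 kb); compute the window-wide
significance level P_b = 0.05/N from the window's variant count; clump
greedily by ascending P (PLINK-style: the index variant is retained,
variants within 1 Mb at LD r² ≥ 0.2 with a retained index are removed —
the index rule is not dictated by the application, greedy-by-P is the
field's default); then prune remaining variants with P ≥ P_b
(clump-then-threshold). Signed LD among survivors comes from the
exposure-sample dosages. An empty survivor set marks the analyte
untestable rather than raising an error.

**Harmonization.** Outcome effects are aligned to the exposure effect
allele (sign flip on allele swap; strand flips reconciled where
unambiguous). Palindromic A/T and C/G variants with minor allele frequency
above 0.42 are dropped as strand-unresolvable. Instruments missing from
the outcome set are replaced by the best in-window proxy with r² > 0.8
when one exists; the exposure effect is re-estimated at the proxy (its own
summary-statistics record) rather than transferred, so both samples refer
to the same physical variant; outcome alignment at the proxy uses its own
alleles. The LD matrix is rebuilt for the final set.

**GWLS.** With M instruments, beta_X and beta_Y the exposure and outcome
effect vectors and Sigma the matrix with entries rho_ij·sigma_Yi·sigma_Yj
(rho the signed LD correlation),

theta-hat = (beta_X' Sigma^-1 beta_X)^-1 beta_X' Sigma^-1 beta_Y,

SE(theta-hat) = alpha · sqrt((beta_X' Sigma^-1 beta_X)^-1), with
alpha = max(1, sqrt(MSE)) and MSE the Sigma^-1-weighted residual quadratic
form (beta_Y − beta_X·theta-hat)' Sigma^-1 (…)/(M−1) — the generalized
least-squares residual variance, the only vectorization under which the
estimate and its dispersion are mutually consistent. The SE is inflated
under residual heterogeneity but never deflated (alpha ≥ 1). Exposure SEs
are carried but unused by the estimators (the first-order
no-measurement-error convention). At rho = I the estimate is the classical
IVW formula; at M = 1 it collapses exactly to the Wald ratio
beta_Y/beta_X with SE sigma_Y/|beta_X|. Sigma is regularized by adding
1e-6 to the diagonal of rho when its smallest eigenvalue falls below 1e-8;
a matrix singular beyond that is rejected with its condition number.

**Null distribution.** The causal P is configurable: t with M−1 degrees of
freedom (M−2 for the Egger slope, normal at M = 1) or normal. The default
for data analyses is t — a deliberately conservative convention
acknowledging that the weights are only relatively known; calibration
experiments (below) use the normal null so that rejection rates and CI
coverage target their nominal levels, and the choice is recorded in every
estimate.

**Sensitivity estimators.** The weighted median interpolates the
weighted median of per-instrument ratio estimates with first-order
inverse-variance weights beta_X²/sigma_Y²; its SE is a parametric
bootstrap (1,000 seeded resamples) drawing beta_Y from MVN(beta_Y, Sigma)
— so LD among instruments is propagated — and beta_X from N(beta_X,
sigma_X). MR-Egger regresses beta_Y on beta_X with an intercept by
generalized least squares using the full Sigma; instruments are oriented
so all beta_X ≥ 0; coefficient SEs use the residual variance floored at 1;
with rho = I this reduces exactly to the textbook 1/sigma_Y²-weighted
Egger regression. The Sigma-weighted form is used because with correlated
cis instruments a diagonal-weight Egger regression is anticonservative —
its intercept test would not hold its level in the package's own
calibration experiments.

**The gate.** Estimates are BH-adjusted across analytes. A BH-significant
protein must then (1) have a weighted-median estimate agreeing in
direction with the GWLS estimate and significant at P < 0.05, and (2) an
Egger slope agreeing in direction with an intercept P above 0.05; survivors
are causal candidates. Proteins with fewer than three harmonized
instruments cannot run the gate and remain "not_tested" (single-instrument
proteins are estimated by the Wald ratio).

# Calibration and recovery experiments

`recoveryStudy()` runs the full two-sample pipeline per replicate:
simulate the exposure cohort, compute age/sex-adjusted linear exposure
statistics; simulate an independent outcome cohort sharing the variant
map, compute age/sex-adjusted logistic outcome statistics; assemble all
block variants as correlated instruments with empirical signed LD; fit
GWLS and MR-Egger.

The frozen study conditions: one 10-variant block at target genotype
correlation 0.5, MAFs uniform on (0.25, 0.40); one protein with cis
per-allele effects (0.15, 0.11, 0.08) SD on three variants — cis
heritability ≈ 3%, typical for serum-protein cis pQTLs; disease prevalence
272/5457 ≈ 5% (the late-stage fraction at cohort scale — the causal
question targets advanced disease); n = 5,000 per sample; θ ∈ {0, 0.25,
0.5} log-odds per SD; 200 replicates per θ. The pleiotropy scenario plants
a direct log-odds effect of 0.3 on each of the three block variants with
no protein effect, violating the exclusion assumption while leaving the
three cis effects intact.

Two known, deliberate approximations bound the recovery bias and are why
the conditions above were chosen on realism grounds rather than for
maximal instrument strength: (i) logistic non-collapsibility — marginal
SNP log-ORs are attenuated by the protein residual variance, a bias of
order 0.17·θ²·(1−h²) as a fraction of θ; (ii) first-order weighting —
sampling error in beta_X enters the quadratic form and dilutes the
estimate by roughly M·var(beta_X-hat)/(b'ρb). At the frozen conditions
both are small relative to the Monte-Carlo error of 200 replicates; at
much higher prevalence or with much stronger instruments they would not
be, which is a property of the estimand and estimator, not of the
implementation.

Problem sizes used by the shipped experiments (tests and the acceptance
script) are stated inline in their code: 200 replicates per scenario at
n = 5,000; the stability-selection experiment plants three predictors
(log ORs 1.0/0.8/0.6 per SD, all above the 0.4 floor) among 100 nulls at
n = 1,000 with B = 100 and a baseline case fraction of 0.3.

# Numerical conventions and edge cases

- Quantiles: type 7 (linear interpolation), everywhere.
- Quantile-bin ties: stable sample order after ranking (deterministic).
- Box-Cox grid: [-2, 2] step 0.01; shift -min + 1e-6·SD for nonpositive
  values; constant analytes flagged, centred at 0.
- LD repair: eigenvalue clipping at 1e-6 then renormalization to unit
  diagonal; Sigma ridge 1e-6 triggered below eigenvalue 1e-8.
- Monomorphic variants: flagged in summary statistics, skipped with a
  message in the scan.
- Separation in logistic fits: flagged non-converged.
- Bootstrap replicates with one outcome class: redrawn, logged, abort
  after 100 failures.
- Seeds: one master seed per experiment; per-replicate seeds derived
  deterministically and kept below 2^31.

# Known limitations

- The disease-liability model linking proteins to disease is a stand-in;
  the application domain does not pin one down. Consequences of the
  logistic choice (non-collapsibility) are documented above.
- The weighted median assumes first-order ratio variances; its bootstrap
  SE is simulation-based and so carries seed-level variability.
- No colocalization, multivariable MR, Steiger filtering or trans-
  instrument MR; no survival or mixed models; no genotype imputation.
- The generator's LD is block-constant by design; analyses relying on
  fine-scale LD decay are out of scope.
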