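---
title: "Methods: DNAm biological age, differential methylation and mortality"
author: "methylSurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNAm biological age, differential methylation and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylSurv)
```

# Scope

methylSurv implements the computational analysis of DNA-methylation
(DNAm) derived biological age and mortality in a matched
type-2-diabetes case-control cohort assayed on an EPIC-like array:
quality control and probe filtering of beta matrices, a generic
coefficient-file engine for epigenetic clocks, EpiScores, protein
surrogates and principal-component (PC) clocks, reference-based blood
cell deconvolution, a two-stage residual-outcome regression test for
estimator batteries, propensity-score matching, Cox
proportional-hazards association, DMP/DVP/DMR calling and gene-set
over-representation. A seeded synthetic-data generator provides
datasets with the full statistical structure the pipeline assumes, so
every stage is testable without any external download. Upstream raw
intensity processing (idat parsing, background correction, dye-bias
normalization) is out of scope: the pipeline ingests beta, intensity
and detection-p matrices produced by standard array preprocessing.

# Quality control

A beta value is the methylated over total intensity ratio
$\beta = M/(M+U+\alpha)$; the stabilizing offset defaults to
$\alpha = 100$, the conventional choice, and is configurable. Samples
are kept when their mean detection p-value is below 0.05. Probes are
dropped when their detection p exceeds 0.01 in at least one sample,
when they lie on a sex chromosome, or when they carry any exclusion
flag (SNP-mapping, cross-reactive, non-specific, variant-containing,
masked); blacklists are supplied as flag columns or plain probe-id
lists because the published exclusion catalogues are not bundled. The
three rules are independent predicates, so their application order
cannot change the retained set; the `FilterReport` partitions removals
so that counts always reconcile exactly with the input dimensions.

**Multimodality screen.** Probes whose beta distribution is bi- or
trimodal in any sex stratum of the survived group are removed. No
standard test is mandated for this screen, so methylSurv uses a 1-D
Gaussian-mixture comparison: `mclust` fits 1, 2 and 3 components
(equal- and free-variance models) and a probe is called multimodal
when the best multi-component BIC beats the single component by more
than 6, the conventional "strong evidence" margin on the BIC scale.
The margin matters at the stratum sizes involved (10-15 samples): with
margin 0 roughly one in ten genuinely unimodal probes is flagged,
while planted two-mode probes (modes 0.2/0.8) exceed the margin by an
order of magnitude, so 6 buys specificity at no practical cost in
sensitivity. Constant probes are treated as unimodal; strata smaller
than 5 samples are skipped with a warning. Method, margin and strata
are recorded in the report.

# The estimator engine

Every linear DNAm estimator — first- and second-generation age clocks,
telomere-length surrogates, pace-of-aging measures, EpiScores, protein
surrogates, inflammation scores — is a coefficient file: an intercept,
a probe-to-weight map, a transform identifier and a missing-probe
policy. The estimate is

$$\hat y_j = f\Big(b_0 + \sum_i w_i \,\beta_{ij}\Big),$$

with $f$ either the identity or the piecewise age transform
$f(x) = (1+a)e^x - 1$ for $x<0$ and $(1+a)x + a$ for $x \ge 0$
(anchor $a = 20$ years), continuous at 0. EpiScore-style models may
request per-probe z-scaling of betas before weighting (a per-model
flag, since published sources differ). Missing model probes are
imputed from shipped reference means when available, otherwise from
cohort means, with a logged count; a strict `error` policy is
available. Composite estimators whose inputs include other estimates
(e.g. mortality composites "based on predicted age" versus "based on
real age") are expressed as model variants differing in the age
covariate supplied. No third-party coefficient sets are shipped: the
engine loads any file in the documented CSV schema, and the test
fixtures are toy models.

PC clocks store a per-probe center, a probes-by-components loading
matrix and component weights:
$\hat y_j = b_0 + \sum_k w_k\,[R^\top(\beta_j - c)]_k$. With an
identity rotation this reduces exactly to the linear engine, which is
one of the package's invariant tests.

Age acceleration is the residual of the least-squares regression of an
estimate on chronological age; the intrinsic variant additionally
adjusts for estimated cell-count columns. Residuals sum to zero by
construction.

# Cell deconvolution

Blood cell fractions are estimated per sample by constrained least
squares against a probes-by-cell-types reference of purified-cell
betas: non-negative least squares, optionally with fractions summing
to one. The sum constraint is imposed by augmenting the system with a
heavily weighted sum row (weight $10^4$) followed by exact
renormalization — the standard constrained-projection practice for
reference-based deconvolution. Noiseless mixtures of a full-column-rank
reference are recovered exactly; at beta noise $\sigma = 0.02$ over
200 probes and six cell types the mean absolute error per fraction is
well below 0.05. The bundled reference is synthetic; assembling a real
purified-cell panel is out of scope, and the pipeline reports
fractions (a user-supplied scale column can convert to counts).

# Two-stage residual-outcome regression

For each estimator in the battery, the residual-outcome procedure runs four
steps in order:

1. **Outlier removal.** Values outside $[Q_1 - 1.5\,\mathrm{IQR},\;
   Q_3 + 1.5\,\mathrm{IQR}]$ are removed, with quartiles computed once
   on the pooled cohort — fences are defined per estimator, not per
   group — by linear interpolation (type-7 quantiles);
   the convention is recorded. Group medians and IQRs are reported
   after removal.
2. **Reference model.** OLS of the estimate on chronological age, sex
   and presence of complications, fitted on survivors only. Sex and
   complications are coded 0/1 and the coding is recorded.
3. **Residualization.** The whole cohort is residualized against the
   survivor model; the survivor mean residual is exactly zero.
4. **Comparison.** Two-sample Student's (equal-variance) t-test of the
   residuals between deceased and survived; Welch is available behind
   a flag. Across the battery, nominal p-values are BH-adjusted and
   significance is flagged at both q = 0.05 and q = 0.10 — both
   thresholds are surfaced, neither hard-coded.

**Calibration.** Deceased residuals are out-of-sample predictions, so
their variance is inflated by roughly $\sigma^2 k/n_s$ (here
$k = 4$ coefficients, $n_s = 27$ survivors) while survivor residuals
are deflated by the same order; with near-equal group sizes the two
effects largely cancel inside the pooled t statistic. One term does
not cancel: when the groups' covariate means differ, the deceased
group mean residual acquires extra variance and the Student test
becomes mildly anticonservative (empirically ~0.066 at nominal 0.05
with independently drawn covariates at n = 27/23). In the design this
pipeline targets, the groups are propensity-matched and
covariate-balanced, and under that design the empirical type-I error
is 0.05 within Monte-Carlo error (2000 null replicates at n = 27/23,
estimator generated from the survivor model). The power check plants
a +0.5 total-SD shift on one of five battery estimators and requires
BH q = 0.10 detection in at least 80% of 500 replicates; with
covariates explaining a realistic share of estimator variance
(age slope 1/yr over age SD 5, residual SD 2.5), observed power is
~0.92 — residualization is exactly what buys this power.

# Propensity matching and survival association

Matching fits a logistic regression of group on the baseline
covariates and pairs each deceased subject 1:1 with the nearest
unmatched survivor by propensity score, greedily in descending treated
score order, without replacement; a caliper is off by default.
Standardized mean differences
$(\bar x_t - \bar x_c)/\sqrt{(s_t^2+s_c^2)/2}$ are reported before and
after. With ~28 pairs the post-match SMD of any single draw carries
sampling noise of ±0.15-0.25 even under perfect matching, which is why
the acceptance summary averages over replicates.

Survival association uses the Cox proportional-hazards partial
likelihood (Efron tie handling, via the survival package), reporting
the hazard ratio per unit of the estimator with a Wald 95% CI,
adjusted for the configured covariate list. A warning is raised when
events are scarcer than coefficients. Spearman correlation (midrank
ties) covers the auxiliary correlation analyses.

# Differential methylation, variability and regions

**DMP.** Per probe, beta is regressed on group plus covariates
(chronological age, sex, complications, estimated cell counts, batch —
whichever are supplied) by OLS, or by Huber M-estimation
(tuning constant 1.345, MAD scale, at most 50 IRLS iterations;
standard errors from the final weighted least-squares step). Variances
are moderated by closed-form moment matching of a scaled-inverse-
chi-squared prior on the log-variance scale
($\hat d_0$ from the trigamma-inverse of the excess log-variance
spread, $\hat s_0^2$ from its mean), giving the posterior
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and $d_0 + d$ degrees of
freedom; when the prior cannot be estimated the raw variances are used
and the event logged. A probe is a DMP when the BH-adjusted p is below
0.05 **and** the raw group-mean beta difference exceeds 0.05 in
absolute value. The dual rule uses the raw difference because the
calling criterion is phrased on the beta scale; the covariate-adjusted
coefficient is also emitted, since which of the two the original
filter used is not stated.

**DVP.** Absolute deviations from the group center (mean by default,
median behind a flag) are compared between groups by an
equal-variance t-test (the Levene/Brown-Forsythe regression form); the
group variance ratio (deceased over survived) is reported in log base
2, so the calling rule — $|\log_2 \mathrm{VR}| > 2$, strictly, with
nominal p < 0.001 — means a more-than-4-fold variance change. The base
is configurable and logged. Zero within-group variance flags the probe
and excludes it from calls.

**DMR.** Regions are called by spatially-correlated p-value
combination: (i) the autocorrelation of $z = \Phi^{-1}(1-p)$ is
estimated in genomic-distance bins (50 bp bins up to 500 bp; bins with
under 20 pairs, or negative estimates, are zeroed); (ii) each probe's
p is smoothed by a correlation-adjusted Stouffer-Liptak combination
over its ±500 bp neighbourhood,
$z_\mathrm{comb} = \sum_i z_i / \sqrt{\mathbf 1^\top \Sigma \mathbf 1}$
with $\Sigma$ from the binned ACF; (iii) probes with smoothed
p < 0.01 seed regions, merging seeds within 500 bp; (iv) each region
is scored by the same combination applied to the *original* p-values
of all probes it spans; (v) the region p is Sidak-corrected with
exponent $\max(1, B/w)$ where $B$ is the total probe-covered bases
(single-base probes) and $w$ the region width. Single-probe regions
are suppressed; p-values are clipped to $[10^{-15}, 1-10^{-15}]$
before the normal transform. None of the window/seed/merge defaults
are externally mandated; all are exposed in configuration.

*Known limitation.* The Sidak exponent $B/w$ understates the effective
multiplicity when probes are densely clustered relative to the total
tested set, so at desk scale (hundreds of probes with island-like
clustering) the region caller is anticonservative under the null; the
package's null checks therefore use an unclustered layout (uniform
positions, ~1 probe per 75 kb), under which uniform p-values yield no
significant regions in ≥95% of runs. Genome-scale runs (hundreds of
thousands of probes) place the exponent in the thousands and behave
conservatively for isolated chance minima.

**Enrichment.** Called DMPs are mapped to genes; each GMT set is
tested by the one-sided Fisher exact (hypergeometric upper-tail)
probability of the overlap within the assayed-gene universe, with the
odds ratio from the 2×2 table. Genic-feature percentages (TSS1500,
TSS200, 5'UTR, first exon, body, 3'UTR) are reported among genic DMPs
and sum to 100 within rounding.

# The synthetic-data generator

`simulateDataset()` draws a cohort whose defaults emulate the target
study design: 27 survived and 23 deceased subjects followed for 16.8
years, with an optional surplus of engineered QC failures (so a
56-sample run shrinks to 50 after sample QC), and an EPIC-like probe
set (20,000 by default; the scale knob is free).

- **Methylome backbone.** Per-probe M-value means come from a
  three-component mixture mimicking the canonical bimodal methylome
  (hypo- and hypermethylated shoulders plus a mid-range class);
  per-probe M noise SD is uniform on 0.15-0.35, giving mid-range
  beta-scale SDs of roughly 0.03-0.06, typical of array replicates.
  Betas are the logistic transform of Gaussian M-values, clamped
  strictly inside (0,1).
- **Planted group effects.** DMP probes receive an M-scale shift
  solved numerically (Gauss-Hermite integration over the M noise) so
  that the induced *beta-scale* mean difference equals the configured
  Δβ (default 0.10), because the calling rule operates on the beta
  scale. Signs alternate, so hyper- and hypomethylated calls both
  occur. Region probes are contiguous within a configured span
  (default 5 probes within 500 bp) and share a per-sample random
  deviation that induces the spatial autocorrelation the region
  caller estimates. DVP probes are generated directly on the beta
  scale (survivor SD 0.02) with the deceased SD inflated by the
  square root of the configured variance ratio, so the planted ratio
  is calibrated on the scale the test measures. Bimodal probes are
  balanced two-mode mixtures at 0.2/0.8.
- **Cell composition.** Per-sample fractions are Dirichlet with a
  free concentration vector (the cohort's true composition is
  unknown, so the default is a plausible blood profile dominated by
  granulocytes); they are linearly mixed through a synthetic
  reference over a designated probe subset.
- **Survival and the latent clock.** Each subject carries a latent
  age acceleration (SD 5 years). Survival follows an exponential
  hazard $\lambda_i = \lambda_0 e^{\gamma a_i}$ with
  $\lambda_0 = 0.03/\mathrm{yr}$ and $\gamma = 0.1$ per year of
  acceleration (HR ≈ 1.65 per SD, plausible for a high-risk cohort),
  administratively censored at 16.8 years. Exact group sizes are
  obtained by nested case-control selection from a larger latent pool
  — mirroring how the real cohort was selected from a followed
  population — so group status coincides with event status, the
  hazard model stays exact, and with $\gamma = 0$ a Cox fit on the
  latent acceleration covers HR = 1 at the nominal rate. A configured
  subset of CpGs (default 30) is *linear in the acceleration on the
  beta scale* (slopes ~0.01/yr around mid-range means), so the
  bundled toy clock — weights proportional to those slopes — equals
  67 + acceleration exactly when probe noise is set to zero, and
  correlates with it above 0.99 at the default noise of 0.02.
  `makeToyClock(config)` rebuilds the identical model from the
  configuration alone because probe-level and sample-level structure
  come from independent substreams of the single master seed.
- **Nuisance structure.** Balanced array batches add a small M-scale
  wobble to null probes only (planted probes stay exactly
  calibrated); detection p-values sit near zero with configurable
  sample- and probe-level failures; sex-chromosome placement and
  exclusion-flag rates are configurable and zero only when a test
  needs a clean cascade.

What the generator does *not* emulate: dye-bias or background
artifacts (upstream of this pipeline), genuine genomic probe
coordinates, linkage between cell composition and group, or
non-exponential baseline hazards. Passing tests therefore demonstrate
the pipeline's statistical behaviour under its stated model, not
performance on raw instrument output.

# Problem sizes and determinism

The test suite and the acceptance script size their simulations to
run comfortably on one CPU: 2000 null replicates for the type-I check,
500 for power, a 10,000-probe cohort for DMP recall/FDR, 25
small-cohort replicates plus a 20,000-probe null for DVP, 100
replicates each for the region-caller null and Cox coverage, and a
200-probe/6-type deconvolution recovery. Every random draw derives
from a single integer seed through tagged substreams, so identical
configurations reproduce byte-identical datasets and result tables;
the pipeline manifest records the configuration hash, seed, parameter
values and row counts per stage.
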