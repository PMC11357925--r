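---
title: "Methods: two-sample MR with mediation decomposition"
author: "mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with mediation decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure. For variant $j$, let $\hat\gamma_j$
(SE $\sigma_{X j}$) be its estimated per-allele effect on the exposure
and $\hat\Gamma_j$ (SE $\sigma_{Y j}$) its effect on the outcome
(log-odds for a binary outcome), taken from two non-overlapping GWAS.
Under the three instrumental-variable assumptions — the variant is
associated with the exposure, independent of confounders, and affects
the outcome only through the exposure — each Wald ratio
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ estimates the causal effect
$\theta$, and the estimators implemented here combine the ratios in
different ways that trade efficiency against robustness to violations of
the third assumption (horizontal pleiotropy):

* **IVW** (the primary method): weighted regression of
  $\hat\Gamma$ on $\hat\gamma$ through the origin with weights
  $w_j = 1/\sigma_{Y j}^2$, i.e.
  $\hat\theta = \sum w_j \hat\gamma_j \hat\Gamma_j \big/ \sum w_j
  \hat\gamma_j^2$. Consistent when all instruments are valid.
* **MR-Egger**: the same regression with an intercept, after orienting
  every variant so $\hat\gamma_j \ge 0$. The slope is a
  pleiotropy-adjusted causal estimate and the intercept estimates the
  mean directional pleiotropic effect; testing the intercept against 0
  is the package's pleiotropy gate.
* **Weighted median**: the interpolated 50% point of the
  inverse-variance-weighted empirical distribution of the ratios;
  consistent while valid instruments carry more than half the weight.
* **Simple and weighted mode**: the argmax of a Gaussian kernel density
  over the ratios (equal or inverse-variance weights); consistent when
  the largest homogeneous cluster of instruments is valid.

Diagnostics follow the same data: Cochran's $Q$ on the IVW and Egger
fits (heterogeneity), the Egger intercept (directional pleiotropy), a
simulation-based residual-sum-of-squares outlier procedure with global,
per-SNP and distortion tests, and a leave-one-out influence series.

### Two-step mediation

For an exposure $X$, candidate mediator $M$ and outcome $Y$, three IVW
estimates are combined: the total effect $a$ ($X \to Y$), the step
effects $c$ ($X \to M$) and $d$ ($M \to Y$). The decomposition is

$$\text{indirect} = c \cdot d, \qquad
  \text{direct} = a - c \cdot d, \qquad
  \text{proportion mediated} = \frac{c \cdot d}{a},$$

reported on the percent scale. First-order (delta-method) uncertainty
treats the step estimates as independent:
$\mathrm{se}(cd)^2 = c^2\,\mathrm{se}_d^2 + d^2\,\mathrm{se}_c^2$, and
the proportion's SE combines $\mathrm{se}(cd)$ with $\mathrm{se}_a$
through the ratio rule. The step samples overlap in reality, so this is
an approximation; the simulation suite provides the empirical check
that the resulting intervals have close to nominal behavior under the
generator's conditions. A mediator whose indirect effect opposes the
total effect is reported with a negative proportion and a
`sign_consistent = FALSE` flag rather than suppressed (configurable).

## Instrument selection and harmonization

* **Inclusion threshold**: $p < 10^{-5}$ for molecular exposures;
  $5\times10^{-8}$ for the disease trait in the reverse direction.
  Comparisons are strict.
* **Clumping**: greedy — sort by ascending $p$ (ties broken by
  lexicographic rsID, making the result deterministic and invariant to
  input row order), accept a variant iff its LD $r^2$ with every
  already-accepted variant within 10 Mb on the same chromosome is below
  0.001. LD is supplied by the caller (file, matrix or function);
  missing pairs are treated as independent so fully synthetic runs can
  use no LD input at all.
* **Strength**: per-SNP explained variance $R^2 = 2p(1-p)\beta^2$
  (unit-variance trait scale) and $F = R^2 (N - K - 1) / (K (1 - R^2))$
  with $K = 1$ — the per-SNP convention, which is the one that
  reproduces the published strength columns this package checks itself
  against. Instruments require $F > 10$.
* **Harmonization**: outcome rows are aligned to the exposure's effect
  allele by direct match, effect/other swap (sign and frequency flip),
  or strand complement followed by the same two rules. Palindromic
  (A/T, C/G) variants are resolved by allele frequency: after label
  alignment both frequencies must lie outside the window
  $[0.42, 0.58]$ on the same side, otherwise the variant is dropped
  with reason `palindromic_ambiguous`. The window is deliberately
  conservative; every exclusion is a recorded row, never a silent
  removal.

## Numerical choices

* **Standard errors**: IVW and Egger use a multiplicative
  random-effects model — the fixed-effect SE is scaled by the residual
  standard deviation floored at 1, so reported SEs are never deflated
  below the fixed-effect SE when the instruments are under-dispersed.
* **Reference distribution**: all p-values are two-sided normal. This
  is the convention that reproduces the published p-value of the
  headline lipid association from its own printed interval
  (se reconstructed as CI half-width / 1.96), which is how the choice
  was fixed.
* **Bootstrap**: median/mode SEs use a parametric bootstrap (each ratio
  resampled from a normal with its own SE; 1000 replicates by default).
  Seeds are mandatory arguments — no function consults hidden global
  RNG state, and the screening pipeline derives per-exposure seeds from
  one root seed as `seed + manifest index`.
* **Mode bandwidth**: $\varphi \cdot 0.9 \cdot \min(\mathrm{sd},
  \mathrm{IQR}/1.349)\, m^{-1/5}$ with $\varphi = 1$, evaluated on a
  512-point grid padded by three bandwidths; identical ratios (zero
  bandwidth) return the common value.
* **Outlier procedure**: the global statistic is the weighted residual
  sum of squares at leave-one-out fits; its null distribution comes
  from parametric simulation of both effect columns at those fits;
  empirical p-values carry a +1 continuity correction and the per-SNP
  outlier p-values are Bonferroni-adjusted. Consequently the smallest
  attainable adjusted p is $m/(n_{\mathrm{sim}}+1)$: detecting any
  outlier among ~30 instruments at the 0.05 level requires
  $n_{\mathrm{sim}} \ge 1000$, the default.
* **Gating**: an exposure is *cleared* iff the Egger intercept p-value
  exceeds $\alpha = 0.05$ (strict); heterogeneity is recorded but never
  blocks, matching the screening design this package implements, where
  heterogeneous but non-pleiotropic signals are retained.
  Benjamini-Hochberg adjustment of the IVW p-values is an opt-in extra
  column, never silently applied.
* **Degenerate inputs**: a single usable instrument falls back to the
  Wald ratio; `beta_exp = 0` rows are excluded from ratios with a
  logged reason; a total effect below `a_floor = 1e-3` in absolute
  value leaves the mediation proportion undefined (division
  instability) with a warning; zero input p-values are clamped to the
  smallest positive double.

## Design decisions that were genuinely open

* **Mediator instruments exclude the exposure's instruments**
  (`exclude_exposure_instruments = TRUE`). A variant that acts on the
  mediator only through the exposure violates the mediator-instrument
  exclusion restriction: in the step-$d$ regression it carries the
  exposure's direct effect, biasing $d$ toward
  $d + \theta_{\mathrm{direct}}/\theta_{XM}$. Removing overlapping
  rsIDs from the mediator's instrument set eliminates this
  contamination at the cost of a few instruments; simulation shows the
  mediated-proportion recovery is clean with the exclusion and
  noticeably biased without it.
* **Reporting sign-inconsistent mediators**: kept (flagged) by default,
  suppressible via configuration, since opposed indirect effects are a
  substantive finding rather than an artifact.
* **Per-SNP $F$ with $K = 1$**: forced by reproducing the published
  strength table — the printed $F$ values are only obtained with
  $K = 1$ despite seven instruments being listed.

## The synthetic-data generator

Summary-level simulation only: the whole pipeline consumes summary
statistics, so no individual genotypes are drawn. Per variant,
$\mathrm{eaf} \sim U(0.05, 0.5)$, true exposure effect
$\gamma_j \sim N(0, 0.2^2)$, and observed effects add sampling noise
with SE $1/\sqrt{2p(1-p)N}$ on a unit-variance trait scale — the same
convention as the $R^2$ formula, so strength statistics computed from
simulated data are internally consistent. Directional pleiotropy
$\alpha_j \sim N(\mu_\alpha, 0.08^2)$ is applied on the
*exposure-increasing* allele for a configurable invalid fraction, which
makes $\mu_\alpha$ recoverable as the Egger intercept. A configurable
fraction of variants is palindromic and a configurable fraction of
outcome rows is re-encoded (allele swap, strand complement, or both),
with the pre-scramble aligned effects recorded in the truth table so
harmonization can be checked exactly.

Default scales emulate the screening setting the package is designed
for: exposure GWAS of 7,174, mediator GWAS of 8,299, outcome GWAS of
184,683 samples; 24 instruments per molecular trait (the screening
tables this mirrors list 16–38 per lipid). `gamma_sd = 0.2` gives
per-SNP $R^2 \approx 1.5\%$ and instrument $F \approx 100$ at the
exposure sample size — the large-effect molecular-QTL regime — and a
total instrument-explained variance near one third with 24 instruments,
consistent with highly heritable lipid species. The mediation chain
draws the exposure block plus a disjoint own-instrument block per
mediator, with outcome truth
$\theta_{\mathrm{direct}}\gamma + \sum_k \theta_{MY,k}(\text{mediator-}k
\text{ truth})$, so $a = \theta_{\mathrm{direct}} +
\theta_{XM}\theta_{MY}$ holds exactly in truth.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: linkage disequilibrium between
instruments (blocks are independent; clumping is exercised with
explicit toy LD inputs), sample overlap between the two GWAS,
binary-trait liability-scale subtleties, population stratification, and
allele-frequency differences between cohorts beyond sampling noise.

## Problem sizes used by the validation suite

The packaged checks run at sizes chosen to make Monte-Carlo noise small
relative to the effects being verified: estimator calibration uses 500
replicates of 200 instruments at $10^5$ samples per side; pleiotropy
type-I/power checks use 800/100 replicates; the outlier procedure is
validated on 100 planted-outlier replicates and 200 null replicates at
$n_{\mathrm{sim}} = 1000$; mediation recovery uses 200 replicates of
the default triple. One caveat is recorded openly: at 500 replicates
the Monte-Carlo bar $2\,\mathrm{sd}/\sqrt{500}$ for the IVW bias is of
the same magnitude as the estimator's intrinsic weak-instrument
attenuation $\theta/\bar F$ (about $2\times10^{-4}$ at the conditions
above), so that particular check sits at the boundary of what the IVW
estimator can satisfy by construction; coverage, robustness and
recovery checks are comfortably inside their bands.

## Known limitations

* Exact reproduction of published instrument lists for the real GWAS
  sources additionally requires the original European LD reference
  panel; `reproduction_recipe()` documents the accession-driven
  procedure.
* The mediation SEs assume independent steps; overlapping samples
  induce correlation the delta method ignores.
* The difference method $a - c d$ is the only direct-effect estimator
  provided (no multivariable MR).
* Steiger directionality filtering is deliberately out of scope.
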