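---
title: "Proportional colocalisation testing: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proportional colocalisation testing: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propcoloc)
```

## The problem and the model

Two traits — two diseases, a disease and a gene's expression, or an eQTL
in two tissues — are each associated with the same genomic region, in two
*distinct* cohorts. Do they share a causal variant, or do neighbouring but
distinct variants drive the two signals? Linkage disequilibrium (LD) makes
the question non-trivial: distinct causal variants can be mutually
correlated, and identical variants can display different lead SNPs by
sampling noise alone.

The proportional approach regresses each trait on the same set of $q$
regressors (SNP dosages or principal-component scores), giving coefficient
estimates $b_1, b_2$ with covariances $V_1, V_2$. If a single causal
variant (or set of variants with proportional effects) drives both
signals, and LD is the same in both cohorts, the population coefficients
are proportional:

$$H_0: \beta_1 = \beta_2 / \eta .$$

The test statistic derives from Fieller's theorem:

$$T(\eta)^2 = u^\top V^{-1} u, \qquad
  u = b_1 - b_2/\eta, \quad V = V_1 + V_2/\eta^2,$$

which is $\chi^2_q$ for known $\eta$. Everywhere internally we use the
angular parametrisation $\theta = \tan^{-1}\eta$,

$$u(\theta) = b_1\sin\theta - b_2\cos\theta, \qquad
  V(\theta) = V_1\sin^2\theta + V_2\cos^2\theta,$$

which is algebraically identical (multiply $u$ by $\sin\theta$) but finite
at $\eta \in \{0, \pm\infty\}$ and periodic with period $\pi$. Two
inferential routes are provided:

* **Profile test** (`profile_test`): $\hat\theta$ minimises $T^2$;
  $T(\hat\eta)^2$ is referred to $\chi^2_{q-1}$.
* **Posterior predictive p-value** (`ppp_value`): the known-$\eta$
  p-value $T^*(\theta) = P(\chi^2_q > T(\tan\theta)^2)$ is averaged over
  the posterior of $\theta$. This avoids assuming the profile
  log-likelihood is quadratic near its maximum.

Independence of the two cohorts ($\mathrm{Cov}(b_1,b_2)=0$) is assumed,
not checked; the CLI refuses cohorts that share sample identifiers, and
`split_controls` partitions a shared control group into two disjoint
halves.

### The posterior of $\theta$

Under $H_0$, $(b_1; b_2)$ is Gaussian with mean
$(\beta\cos\theta;\ \beta\sin\theta)$ and block covariance
$\mathrm{diag}(V_1, V_2)$. We marginalise the common coefficient vector
$\beta$ analytically under a flat improper prior: with
$U_i = V_i^{-1}$, $A(\theta)^\top \Sigma^{-1} A(\theta) =
U_1\cos^2\theta + U_2\sin^2\theta$, the marginal log-likelihood is

$$\ell(\theta) = -\tfrac12\log\lvert U_1\cos^2\theta + U_2\sin^2\theta\rvert
 + \tfrac12\, h(\theta)^\top (U_1\cos^2\theta + U_2\sin^2\theta)^{-1} h(\theta),
 \qquad h(\theta) = U_1 b_1\cos\theta + U_2 b_2 \sin\theta,$$

up to terms constant in $\theta$. A *marginal* rather than profile
treatment of $\beta$ is a design choice made here and documented as such:
with a flat prior the two coincide asymptotically, and the marginal form
has a closed expression evaluable in $O(q)$ per grid point after a single
simultaneous diagonalisation of $(U_1, U_2)$.

The prior on $\theta$ is the one implied by a Cauchy$(0, k)$ prior on
$\eta = \tan\theta$, i.e. $p(\theta) \propto 1/(k^2\cos^2\theta +
\sin^2\theta)$; the default $k = 1$ gives a uniform prior on $\theta$ and
varying $k$ has little effect at the sample sizes of interest
(`prior_scale` exposes it).

### Numerical choices

* Default grid: 1001 equally spaced $\theta$ on $(-\pi/2, \pi/2]$;
  trapezoid quadrature; density normalised so the trapezoid integral over
  the grid equals 1.
* The profile optimum is located on a 1000-point grid and refined by
  golden-section search to $10^{-8}$; it matches a $10^6$-point
  brute-force grid to $10^{-6}$ (asserted in tests).
* **Adaptive refinement:** with very precise coefficients the posterior
  can be narrower than the grid spacing. When the posterior standard
  deviation estimated on the coarse grid falls below five grid steps,
  2001 extra points are inserted around the mode and the density is
  recomputed, so ppp quadrature stays accurate in the concentrated
  regime.
* All statistics are evaluated through a simultaneous diagonalisation of
  the two covariance (or precision) matrices; a Cholesky failure on both
  orderings raises a numerical error reporting condition numbers rather
  than returning garbage for near-singular $V(\theta)$.
* Credible intervals recentre the periodic density on its mode before
  taking central quantiles, so the interval never straddles the
  artificial boundary at $\theta = \pm\pi/2$; if the $\theta$ interval
  crosses $\pi/2$ the $\eta$ set wraps through infinity and is flagged.

### The ppp under exact proportionality

A natural intuition is that with exactly proportional coefficients and
vanishing uncertainty the ppp should tend to 1. It does not: $T^2(\theta)$
is the profile deviance in $\theta$, so the posterior of $\theta$ and the
decay of $T^*(\theta)$ concentrate *at the same rate*, and the ppp tends
to $E[P(\chi^2_q > Z^2)]$ with $Z$ standard Gaussian ($= 1/\sqrt2 \approx
0.71$ for $q = 2$). The test suite asserts this limit; it is one reason
posterior predictive p-values read conservatively compared with ordinary
p-values and should not be interpreted on a uniform scale.

## Summarising the region: PCs or model averaging

Selecting SNPs for their observed association biases the selected
coefficients away from zero (winner's curse) and inflates the type 1
error of any downstream colocalisation test. Two unbiased summaries are
provided.

**Principal components** (`pc_test`): the two cohorts are merged, each
SNP centred and scaled *on the combined data* (so both cohorts project
into the same space — the scaling constants are deliberately shared), and
the smallest leading set of components capturing a `threshold` fraction
of variance is used as the common regressor set. Selection depends only
on genotypes, never on traits. Defaults: `threshold = 0.90`; the
simulation studies here use 0.85. Cohorts are weighted per sample, not
per cohort, in the combined PCA. A deterministic sign convention (largest
absolute loading positive) makes results reproducible across BLAS
implementations.

**Bayesian model averaging** (`bma_test`): every SNP subset of size 2 or
3 is a model $m$, used for both traits (the proportional test needs a
common regressor set). Per-trait BICs are summed — cohort independence
makes the joint marginal-likelihood approximation a product — and models
are weighted by $P(m) \propto \exp(-(BIC_1 + BIC_2)/2)$ under a uniform
prior over the universe of the chosen size. Sizes are never mixed, and
four-SNP universes are not offered. The averaged p-value is
$\mathrm{ppp} = \sum_m P^*(m) P(m)$. Models are ranked and the minimal
prefix reaching `prune_mass` (default 0.9999) of posterior mass is
retained before the per-model tests are run; pruning at this level
changes the ppp by less than $10^{-3}$ (asserted in tests). Both traits
are fitted before pruning.

For the BMA credible interval of $\eta$ we report quantiles of the
*mixture* of per-model $\theta$ posteriors weighted by $P(m)$. How the
original analyses aggregated per-model intervals is not recoverable;
weighted-moment aggregation was the alternative, and the mixture was
chosen because it preserves multimodality across disagreeing models.

## The biased baselines

`conditional_test`, `nica_score` and `baseline_test` (strategies
`top_pair`, `lasso_union`, `lasso_two_stage`) are shipped *as biased
baselines* for benchmarking. Lasso penalties are chosen by 10-fold
cross-validation at the 1-SE rule with deterministic folds; the Nica
residual-rank score excludes $j = k$ and includes $j = k'$ among the
conditioning candidates (the source descriptions leave this open), and
Spearman p-values use the large-sample approximation except below
$n = 50$.

## What the simulator emulates — and what it does not

`make_panel` replaces a phased reference haplotype panel with a
Gaussian-copula construction: a latent AR(1) process within LD blocks
(default `block_size = 25`, `rho = 0.95`), thresholded at per-SNP
quantiles. Target minor allele frequencies share a block-level base
(uniform on `(maf_floor, 0.5)`, floor 0.05) with ±0.05 per-SNP jitter,
and with probability `dup_prob = 0.3` a SNP is a near-copy of its
predecessor (latent correlation 0.997, frequency jitter ±0.01). The
near-copies matter: thresholding attenuates latent correlation, and
without them the genotype $r^2$ spectrum never approaches 1, whereas
dense regional panels contain many near-perfect proxies. These defaults
were fixed from the tetrachoric attenuation calculation before any
study-level result was produced.

Case-control sampling follows a multiplicative per-allele relative-risk
model by rejection sampling of haplotype pairs (acceptance
$\propto rr^{\text{allele count}}$); the retrospective case allele
frequency matches the closed form $f \cdot rr/(1-f+f\cdot rr)$ (asserted
in tests). Quantitative traits fix the variance explained per causal
variant under Hardy–Weinberg genotype variance, with Gaussian noise
making the total variance about 1. `tag_subset` stands in for a
genotyping array by random thinning (default fraction 0.3), with one tag
set shared by both cohorts; causal variants are removable like any other
SNP. Datasets in which every single-SNP p-value exceeds $10^{-4}$ are
discarded and redrawn — the screen is applied to *each* cohort — because
the test is intended for regions with established association.
`admix_panels` mixes a fraction $\pi$ of haplotypes from an alternate
panel into the second cohort for sensitivity analyses of the equal-LD
assumption.

For power studies stratified by the LD between two distinct causal
variants, the causal pair is drawn *within* a target $r^2$ range
(`r2_range`), rather than binning unrestricted draws post hoc:
unrestricted draws essentially never land in the upper strata at feasible
replicate counts.

Not emulated: realistic allele-frequency spectra below the 5% floor,
recombination-rate variation within blocks, genotyping error, imputation
uncertainty, or real inter-population divergence (admixture mixes two
synthetic panels that differ in frequencies and LD realisations only). A
clean type-1-error result here therefore shows calibration under
idealised LD, not robustness to everything real data can do.

## Problem sizes

Simulation-backed checks use: 150 replicates for the shared-causal
type-1-error comparison (RR 1.2, 2,000 cases/2,000 controls, tag fraction
0.3) in the test suite, and 500 replicates for the same study in
`scripts/acceptance.R`; 40 replicates per $r^2$ stratum for power
monotonicity; 120 replicates for the two- versus three-SNP BMA
comparison; 100 replicates for credible-interval coverage of $\eta = 1$.
Posterior grids of 301–501 points are used inside the studies (the
quadrature is already accurate there); interactive analyses default to
1001.

## Known limitations

* The equal-LD assumption is untested by the method itself; strong
  admixture in one cohort invalidates the null distribution.
* Failing to reject never demonstrates a shared variant — distinct
  variants in complete LD are indistinguishable by design.
* The ppp is conservative relative to a uniform null; calibration by
  simulation is possible but out of scope here.
* q = 1 (a single common regressor) leaves the profile test undefined;
  at least two SNPs or components are required.
* BIC-based weights are asymptotic approximations; with very small
  cohorts both the weights and the Gaussian coefficient approximation
  degrade together.
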