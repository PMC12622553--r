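---
title: "Synaptic density connectomes, imaging transcriptomics and covariance networks"
author: "SynDensityNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synaptic density connectomes, imaging transcriptomics and covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynDensityNet)
```

# Overview

SynDensityNet implements a network-level analysis of synaptic density as
measured by SV2A PET imaging, together with the statistics that connect such
networks to regional gene expression, and a parallel rodent arm based on
group-level covariance networks. Because voxel-level patient data and
donor-level transcriptomes are rarely shareable, the package also ships a
seeded synthetic-data module that generates cohorts with planted,
quantitatively known effects; every statistical guarantee the package makes
is demonstrated on those cohorts in the test suite.

The pipeline has four scientific stages:

1. **Similarity connectome.** For one subject, each region of interest (ROI)
   contributes a vector of voxel-level tracer uptake values. The
   distribution of each ROI is estimated by Gaussian kernel density
   estimation, and every pair of ROIs is compared with the symmetric
   Kullback–Leibler (KL) divergence
   $$D(P,Q)=\sum_i P_i\log\frac{P_i}{Q_i}+Q_i\log\frac{Q_i}{P_i},$$
   mapped to a bounded edge weight by the KL similarity
   $KLS(P,Q)=e^{-D(P,Q)}\in(0,1]$. With a 246-region parcellation this
   yields a 246 × 246 unthresholded adjacency matrix per subject.
2. **Nodal inference.** Nodal connectivity strength (the sum of a node's
   off-diagonal edge weights) is compared between cases and controls per ROI
   with ordinary least squares, adjusting for age and sex, and corrected
   across ROIs by Benjamini–Hochberg FDR. The signed t-map (case minus
   control) is the regional response for the next stage.
3. **Imaging transcriptomics.** A regions × genes expression matrix —
   assembled from probe-level data by intensity filtering,
   differential-stability probe collapse and scaled robust sigmoid
   normalization — predicts the t-map through partial least squares (PLS)
   regression. Component-1 gene weights are normalized to z-scores by
   bootstrapping regions, the component's score–response correlation is
   tested by permuting the response, and genes with $z>3$ / $z<-3$ form the
   PLS+ / PLS− sets.
4. **Covariance networks (rodent arm).** For each animal group, regional SUV
   values are z-scored and correlated across animals; per-edge significance
   comes from a random-shift permutation null, and the thresholded networks
   are summarized by density, degree, signed strength, signed weighted
   clustering and top-quartile hubs, with group differences assessed per
   edge by permutation and globally by a Kolmogorov–Smirnov test on edge
   weights.

# The similarity connectome in detail

`estimateDensity()` evaluates a Gaussian-kernel density on a uniform grid of
$2^9 = 512$ points. The bandwidth is selected automatically; the default is
Silverman's rule of thumb, with the Sheather–Jones plug-in available through
`bandwidthMethod = "sj"`, and the method used is recorded in the matrix
metadata. Several numerical choices deserve explanation because the
underlying method leaves them open:

* **Shared evaluation grid.** The divergence is only meaningful when both
  densities are evaluated at the same points. `buildSimilarityMatrix()`
  re-evaluates each pair of ROI densities on a common uniform grid spanning
  the union of the two sample ranges, extended by three bandwidths on each
  side, so essentially all kernel mass falls inside the grid.
* **Discrete masses.** Density values are multiplied by the grid spacing and
  renormalized to sum to one, making $D$ a proper discrete divergence; with
  the natural logarithm its unit is nats.
* **Density floor.** Densities are floored at $\varepsilon = 10^{-12}$
  before normalization. Without the floor, ROIs with disjoint supports give
  infinite divergence and an edge weight of exactly zero; with it, extreme
  pairs get tiny but positive similarities, keeping every weight in
  $(0,1]$.
* **Diagonal.** $KLS(P,P)=1$ identically, so the diagonal is set to 1
  rather than computed.

Because every edge touches two regions, a deficit planted in a few ROIs is
not confined to them: unaffected regions lose similarity to the affected
ones and their nodal strength shifts too. Group differences in similarity
networks are therefore expected to spread beyond the primary lesion — the
recovery tests assert sensitivity for the planted regions, not exclusivity.

A numerical consequence worth knowing: when a region is far from all others,
its off-diagonal similarities can fall below the double-precision resolution
of the unit diagonal, so nodal strength is computed from a zero-diagonal
copy of the matrix rather than as `rowSums(m) - 1`.

# Nodal inference

The per-ROI model is `strength ~ group + age + sex` with group coded
0 = control, 1 = case, so positive t-values mean higher strength in cases.
Two-sided p-values are used throughout; the q-values are Benjamini–Hochberg.
The model family is deliberately minimal — a linear model with a group
indicator and the stated covariates — and the design matrix is shared across
ROIs, so all 246 fits reduce to one least-squares solve. A rank-deficient
design (for instance age perfectly confounded with group) is refused with a
diagnostic error rather than silently dropped terms.

# The PLS stage

With a univariate response, component-1 PLS has a closed form: after
z-scoring predictors and response, the gene weight vector is
$w \propto X^\top y$ normalized to unit length, and the regional scores are
$Xw$. `fitPLS()` implements NIPALS so further components (with deflation)
are available, but the reported object is always component 1. Choices the
method description leaves open, and how this package resolves them:

* **Weights vs loadings.** Bootstrap z-scores are computed on the
  *weights* of the standardized fit; loadings are exposed on the result
  object as an alternative.
* **Sign convention.** A PLS component is defined up to sign. The package
  fixes the correlation between component scores and the response to be
  nonnegative, and aligns every bootstrap replicate to the observed weight
  vector by the sign of their inner product before computing
  $z_g = w_g/\mathrm{sd}^*(w_g)$.
* **Permutation statistic.** The permutation test permutes the response
  across regions and compares score–response Pearson correlations, with the
  add-one correction $p=(1+\#\{r_{perm}\ge r_{obs}\})/(n_{perm}+1)$, so
  $p=0$ is never reported and the null p-value distribution is slightly
  conservative.
* **Gene–map correlations** are plain Pearson correlations of a single
  gene's regional profile with the response map, without partialing out
  other genes.

The expression matrix itself is assembled as in standard microarray
practice: probes below 1.5 × background in *all* samples are removed
(strict inequality, so a probe exactly at threshold survives); one probe per
gene is kept by differential stability (mean inter-donor Spearman
correlation of the regional profile, ties broken to the lexicographically
smallest probe id); and each gene is normalized by a scaled robust sigmoid
$s_i = (1+\exp(-(x_i-\mathrm{med})/(\mathrm{IQR}/1.35)))^{-1}$, min–max
rescaled to $[0,1]$. The 1.35 constant makes the IQR a normal-consistent
scale estimate. The sigmoid is not idempotent, so
`buildExpressionMatrix()` applies it exactly once and records the fact in
an attribute.

# Covariance networks

`buildCovarianceNetwork()` z-scores each region across animals (which leaves
Pearson correlations unchanged but matches the stated procedure) and builds
the null by independently permuting every region's values across animals,
destroying inter-regional covariance while preserving marginals. A circular
shift variant is available but off by default. The retained per-edge p
compares the empirical correlation against the null *magnitude*
($|r_{null}|\ge|r_{obs}|$, add-one corrected), which makes the null edge
rate at $p<0.05$ approximately 5%; the one-sided positive- and
negative-tail p matrices are kept in the network metadata for analyses that
need the tails separately.

The signed weighted clustering coefficient follows the
Costantini–Perugini generalization:
$$C_i=\frac{\sum_{j\ne k} w_{ij}w_{ik}w_{jk}}{\sum_{j\ne k}|w_{ij}w_{ik}|},$$
which multiplies triangle weights with their signs and reduces to ordinary
weighted clustering on all-positive networks (and to exactly 1 on complete
unit-weight graphs). Hubs are nodes at or above the 75th percentile
(quantile with linear interpolation, ties all included) of total absolute
strength or of degree. Negative strength is reported as a magnitude
($\ge 0$); "higher negative strength" therefore means more/stronger
negative edges. Between-group edge tests use the plain correlation
difference as statistic by default; a Fisher-z variant is available.

# The synthetic-data module

The generators define the study conditions for every test in the package:

* **Human cohorts.** ROI baselines are Gaussian across ROIs (mean 1.2,
  SD 0.15 on an SUVR-like scale), voxel values Gaussian within ROI with
  SD 0.1 by default. The method description gives no voxel-level model;
  Gaussian baselines keep the oracles analytic (the case–control shift in
  an affected ROI is exactly `effectShift` control SDs). Ages are uniform
  on [18, 60] and sex Bernoulli(0.5), independent of group unless the
  confounding knob is turned to exercise covariate adjustment. One global
  seed expands into per-subject substreams, so enlarging a cohort never
  perturbs existing subjects.
* **Gene matrices.** Planted genes are exact-correlation blends
  $\pm r\,z(\mathrm{map})+\sqrt{1-r^2}\,\epsilon$; everything else is
  independent noise. The probe-level long table adds donor effects, probe
  noise (later probes per gene are noisier, so differential stability has
  something to choose between) and a background level for the intensity
  filter. The full-scale configuration mirrors a 246-region × 5451-gene
  matrix.
* **Mouse cohorts.** Two groups of 12 animals × 22 regions by default,
  drawn from multivariate Gaussians whose correlation structure is a block
  partition with per-block correlation; positive semi-definiteness is
  validated at construction.

What these generators deliberately do *not* emulate: spatial voxel
autocorrelation, partial-volume effects, scanner noise, donor-to-atlas
assignment from real coordinates, or spatially autocorrelated gene maps.
Passing tests therefore demonstrate the correctness and calibration of the
statistics under clean conditions, not robustness to the artefacts of real
PET or microarray data.

# Problem sizes, runtime and reproducibility

The heavy simulations in the test-suite and in `scripts/acceptance.R` use
deliberately chosen sizes: planted-deficit recovery runs 50 seeded cohorts
of 20 + 20 subjects with 30 ROIs × 100 voxels on a 128-point grid (an
affected minority of 10 ROIs at a one-SD deficit); PLS recovery runs 20
seeded datasets of 246 regions × 2000 genes with 20 + 20 planted genes at
$|r|=0.8$ and 500 bootstrap resamples; edge-null calibration uses 50 seeds
at 1000 permutations. These sizes give stable Monte-Carlo estimates of the
quantities being checked while keeping a full run in the minutes range on a
single core. All randomness flows through explicit integer seeds into R's
Mersenne–Twister stream, and every stochastic function restores the
caller's RNG state.

# Known limitations

* The KLS connectome is sensitive to the bandwidth selector on small ROIs;
  both selectors are exposed and recorded, but no attempt is made to match
  any particular historical choice.
* The per-pair evaluation grid means each edge is computed on its own grid;
  a common global grid would be marginally faster but changes edge values
  slightly, and neither convention is canonical.
* The permutation and bootstrap inferences are Monte-Carlo; with the
  default add-one corrections their p-values are conservative at the
  resolution of $1/(n+1)$.
* Spatially autocorrelated null models for gene-map correlations (spin
  tests and variants) are out of scope; the permutation test here permutes
  regions freely.
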