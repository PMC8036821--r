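---
title: "Methods: landscape metrics and maximum-likelihood spatial regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape metrics and maximum-likelihood spatial regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greensar)
```

`greensar` is built for ecological (area-level) regressions of a health
outcome rate on tree and greenspace structure measured from binary
rasters. This vignette is the package's own account of the statistical
machinery: the models and their assumptions, the measurement definitions,
every numerically consequential choice, and what the synthetic test bed
does and does not establish.

## The regression models

Let $y$ be the per-tract outcome rate (the motivating application is
asthma emergency-department visits per 10,000 residents), $X$ the design
matrix of six landscape metrics and seven socio-demographic/air-quality
covariates, and $W$ a row-standardized contiguity matrix so that $Wy$ is
the average outcome of a tract's neighbors.

* **Spatial lag (SL):** $y = \rho W y + X\beta + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2 I)$. Dependence lives in the outcome
  itself; $\rho$ measures how strongly a tract's rate follows its
  neighbors'.
* **Spatial error (SE):** $y = X\beta + \varepsilon$ with
  $\varepsilon = \lambda W \varepsilon + u$, $u \sim N(0, \sigma^2 I)$.
  Dependence is a nuisance structure in the disturbances, analogous to
  serial correlation in time series.

Both are fitted by full Gaussian maximum likelihood. Profiling $\beta$
and $\sigma^2$ out leaves a one-dimensional concentrated log-likelihood;
for the lag model

$$\ell_c(\rho) = -\tfrac{n}{2}\bigl(\log 2\pi + 1\bigr)
  - \tfrac{n}{2}\log\!\bigl(e(\rho)^\top e(\rho)/n\bigr)
  + \sum_i \log(1 - \rho\,\omega_i),$$

where $e(\rho)$ are the OLS residuals of $y - \rho Wy$ on $X$ and
$\omega_i$ are the eigenvalues of $W$. The error model concentrates the
likelihood of the spatially filtered regression of $(I - \lambda W)y$ on
$(I - \lambda W)X$, with the same Jacobian term; $\hat\beta$ is then the
GLS estimate at $\hat\lambda$.

Key implementation facts:

* **Log-determinant by eigenvalues.** $W = D^{-1}B$ for a symmetric
  binary adjacency $B$ is similar to $D^{-1/2} B D^{-1/2}$, so its
  spectrum is real and computed once with a symmetric eigensolver;
  $\log|I - \rho W| = \sum_i \log(1-\rho\omega_i)$ is then $O(n)$ per
  likelihood evaluation. The tract counts this package targets (hundreds
  to a few thousand) are comfortably within dense-eigen range, so no
  sparse or Chebyshev approximation is used. The suite verifies the
  identity against direct dense determinants on lattices up to 8×8 at
  $10^{-8}$.
* **For the lag model the profile RSS is an exact quadratic in $\rho$**
  ($e(\rho) = e_0 - \rho e_L$ with both residual vectors precomputed), so
  each evaluation costs $O(n)$ and fitting is effectively instant.
* **Optimizer.** Bounded scalar maximization (`stats::optimize`,
  tolerance $10^{-9}$) on $(1/\omega_{\min} + \delta,\;
  1/\omega_{\max} - \delta)$, $\delta = 10^{-5}$ — the admissible
  interval of the spatial parameter. An optimum within $10^{-4}$ of a
  boundary is flagged as non-converged with a warning. The optimizer is
  cross-checked against a grid search of step 0.001.
* **Standard errors** come from the numeric Hessian of the *full*
  log-likelihood in $(\beta, \rho\text{ or }\lambda, \sigma^2)$ at the
  optimum, by central differences with step
  $h_i = \varepsilon^{1/4}\max(|\theta_i|, 0.01)$ (machine epsilon
  $\varepsilon$). One scheme serves both models uniformly. The $\sigma^2$
  row is estimated jointly but not reported.
* **Fit statistics.** `loglik` is the maximized log-likelihood; AIC uses
  $K = \#\beta + 1\,(\sigma^2) + 1$ (spatial parameter, lag/error only) —
  a convention fixed here by documentation, since published tables in
  this literature are often ambiguous about $K$. "R-squared" for all
  three models is the squared Pearson correlation between observed and
  predicted outcomes, with the reduced form
  $(I-\hat\rho W)^{-1}X\hat\beta$ as the lag model's prediction and
  $X\hat\beta$ as the error model's; for OLS this equals the classical
  $R^2$. Standardized coefficients are
  $\hat\beta_j\,\mathrm{sd}(x_j)/\mathrm{sd}(y)$, undefined for the
  constant. Significance stars mark the 0.10/0.05/0.01 two-tailed
  levels.
* At $\rho = 0$ (or $\lambda = 0$) the concentrated likelihood equals the
  Gaussian OLS log-likelihood exactly; the suite asserts this, together
  with invariance of all estimates under tract reordering.

## Diagnostics

* **Moran's I** on OLS residuals,
  $I = (n/S_0)\, z^\top W z / z^\top z$ with $z$ the deviations of the
  residuals from their mean (identical to the raw residuals when the
  model has an intercept; residuals are never studentized). Expectation
  under the null is $-1/(n-1)$. Inference is analytic under the
  normality assumption by default — the familiar single $I$/z/p report —
  with a permutation scheme (default 999 relabelings, seeded and
  deterministic, two-sided empirical p) as the alternative; which scheme
  a published z-score used is typically unstated, so both are provided.
  The gate is advisory: a significant $I$ motivates the spatial models,
  but the pipeline always fits and reports all three columns.
* **VIF**: $1/(1 - R^2_j)$ from regressing predictor $j$ on the others
  (auxiliary regressions include an intercept); exact collinearity is
  reported as infinite with the offending column named. The conventional
  screen keeps all values below 5.

## Landscape measurement

All metrics are defined per tract, on the cells whose centers fall in the
tract (no area-weighted cell splitting: unambiguous at raster resolution,
with error bounded by the one-cell boundary ring).

* **Patches** are maximal connected components of canopy cells,
  delineated within each tract independently (a canopy crossing a tract
  boundary is split, because every metric is a per-tract quantity).
  Connectivity is 8-neighbor by default — crowns touching diagonally read
  as one canopy — with 4-neighbor selectable. Labelling is union-find
  with path halving, verified against a brute-force flood fill.
* **TreeCov** is the canopy cell fraction of the tract.
* **TreeClus** is the *median* patch area (patch-size distributions are
  right-skewed); an even patch count takes the mean of the two central
  order statistics. Areas are kept in the raster's native squared units;
  reporting layers may convert.
* **TreeAgr** is the average nearest-neighbor index of patch centroids:
  $\bar d_{obs} / \bar d_{exp}$ with
  $\bar d_{exp} = 0.5/\sqrt{n/A}$ for $n$ points in tract area $A$.
  No edge correction is applied (the conventional formula); this carries
  a small upward bias for sparse patterns near boundaries, visible in the
  CSR calibration test, whose Monte-Carlo acceptance band is therefore
  [0.95, 1.10] rather than symmetric about 1.
* **Greenspace stratification** overlays the binary greenspace raster
  with the land-use map; each green cell feeds exactly one of private
  (residential, commercial, office, industrial), semi-public (golf,
  education, cemetery, agriculture), public (parks/recreation), or an
  explicitly reported unclassified remainder.
* **Degenerate tracts**: no patch leaves `TreeClus` undefined, fewer than
  two patches leaves `TreeAgr` undefined. Both are flagged, never
  imputed, and the filtering stage drops flagged tracts — the synthetic
  analogue of removing uninhabited park/forest tracts from a real study.
  The uninhabited-tract rule (residential land share below 5% by
  default) is applied *first*, so a tract excluded for having no
  residents is logged as such even if its metrics are also degenerate.

## The synthetic generator

The generator exists so that every downstream stage has a known ground
truth. Its defaults are the package's fixed reference conditions, chosen
once to mimic a large urban county:

* **Canopy**: per-tract target cover drawn from a Beta law with mean 0.11
  and sd 0.06 (the dispersion printed for the motivating study region);
  patch seeds placed uniformly (log-uniform intensity between 0.01 and
  0.05 seeds per unit area, i.e. roughly 4–20 patches in a 20×20-cell
  tract) and grown by stochastic frontier dilation until the tract's
  target cell count is met exactly. Fewer seeds at equal cover give
  larger, more aggregated patches, which is precisely the contrast
  `TreeClus`/`TreeAgr` measure; `patch_growth` (default 0.5, the frontier
  fraction converted per step) tunes patch compactness.
* **Land use**: per-tract Dirichlet composition (concentration 50) around
  a base mix of 50% residential, with contiguous vertical strips per
  class and per-class green shares (e.g. 25% of residential, 85% of golf
  area green). The overlay inverse recovers the configured shares up to
  cell rounding, and this round trip is tested.
* **Covariates**: multivariate normal with a documented mild positive
  default correlation (poverty with lower attainment and more children;
  PM2.5 with ozone), margins located at the study region's printed
  means/sds, percentages clipped to [0, 100]. One printed location — the
  educational-attainment mean — is inconsistent with its own sd and
  definition in the source table and was replaced by 40%, chosen once.
  The true covariance structure of the real data is unpublished, so the
  correlation matrix is an explicit user knob, not a calibrated value.
* **Outcome**: drawn directly as a rate from the lag
  ($y = (I-\rho W)^{-1}(X\beta + \varepsilon)$), error
  ($y = X\beta + (I-\lambda W)^{-1}u$), or independent process, with the
  truth (process, parameter, $\beta$, $\sigma$, seed) recorded beside
  every dataset. Default $\rho = 0.541$ and $\lambda = 0.797$ — the
  spatial parameters reported for the motivating study — with
  $\sigma = 10$ (the source reports no residual scale; its outcome sd is
  25.4, and $\sigma = 10$ leaves roughly half the outcome variance to the
  systematic part at these defaults). Default $\beta$ follows the
  reported spatial-lag coefficient column, so synthetic studies keep the
  qualitative sign structure (canopy protective, poverty and pollution
  adverse). The rate is not truncated at zero: the DGP is the linear
  Gaussian model the estimators assume.
* **Pipeline order**: metrics and filtering run *before* the outcome is
  drawn, and the weights used for the DGP are the queen weights on the
  retained tracts — so the recorded truth refers to the same $W$ the
  estimators see, making parameter recovery a well-posed check. All
  randomness flows from one integer master seed via fixed per-stage
  offsets; every output is bit-identical under a repeated (config, seed).

What the generator does **not** emulate: irregular tract geometry (tracts
are square grid cells, so queen adjacency is analytically known),
population weighting or count sampling in the outcome (the rate itself is
modelled, matching the motivating analysis), measurement error in the
rasters, and any non-Gaussian or heteroskedastic error structure. Passing
recovery tests therefore show the estimators are correct for the model
they claim to fit — not that the model is adequate for any particular
real landscape.

## Test and reproduction scale

The suite's simulation sizes are chosen to give tight Monte-Carlo checks
at interactive cost: parameter recovery uses 100 replicates on a 30×30
lattice ($n = 900$; mean $\hat\rho$ within [0.45, 0.55] of $\rho = 0.5$,
mean $\hat\lambda$ within [0.54, 0.66] of $\lambda = 0.6$, mean
$\hat\beta$ within 5% of truth), model selection 100 replicates at
$n = 400$, the Moran null calibration 1000 replicates at $n = 100$, and
the CSR calibration 500 replicates of 200 points. `scripts/acceptance.R`
runs two 20×20-tract end-to-end studies (lag- and error-process) and
writes every headline quantity it computes as JSON; all of it re-derives
from the seed at run time.

## Known limitations

* Dense eigendecomposition and dense solves cap practical problem size at
  a few thousand tracts — ample for county-scale studies, not for
  national grids.
* NNI has no edge correction; per-tract values for very sparse patch sets
  are noisy and small-sample biased upward.
* Islands (tracts without neighbors) are excluded from estimation with a
  logged reason rather than accommodated, since their spatial lag is
  undefined.
* The real-data path expects rasters already aligned to the tract grid
  frame; resampling/reprojection is out of scope, as is any LiDAR
  processing upstream of the binary canopy raster.
* No Lagrange-multiplier specification tests, spatial Durbin terms, or
  GMM/heteroskedasticity-robust variants; model choice rests on Moran's
  I, AIC and the recovery properties above.
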