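---
title: "Methods: Bayesian geostatistical mapping of under-five mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian geostatistical mapping of under-five mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`geomort` estimates under-five mortality from cluster-survey data of the kind
produced by Demographic and Health Surveys: each cluster $j$ contributes a
GPS location, a number of live births $n_j$ and a number of under-five
deaths $y_j$. The model is a binomial spatial regression on a raster
lattice:

$$
y_j \sim \mathrm{Binomial}(n_j, p_j), \qquad
\operatorname{logit}(p_j) = \alpha_{t(j)} + \mathbf{x}_j^\top \boldsymbol\beta
  + \zeta_{c(j)},
$$

where $t(j)$ is the survey wave of cluster $j$, $\mathbf{x}_j$ are
ecological covariates read off raster surfaces at the cluster location,
and $\zeta$ is a zero-mean Gaussian Markov random field indexed by lattice
cell $c(j)$. The under-five mortality rate is reported as $1000 \, p$,
deaths per 1000 live births.

Key assumptions: deaths are conditionally binomial given the cell-level
risk; covariate effects are linear on the logit scale; residual spatial
structure is captured by a single field shared across surveys, while the
overall level moves between surveys through the survey-specific
intercepts. When several surveys are modeled together, the data are
stacked and share one field; survey-by-space interactions are out of
scope (a per-survey fit achieves the same effect by subsetting).

### The spatial field

The field prior is a first-order *intrinsic* conditional autoregression
(ICAR) with rook neighborhood: the structure matrix $Q_0$ is the graph
Laplacian of the lattice, the full precision is $Q_0/\sigma_\zeta^2$, and
the improper constant direction is removed by a sum-to-zero constraint, so
"zero-mean" holds exactly. ICAR is the simplest GMRF with the qualitative
behavior required here — local smoothing with data-driven strength — and
it is exactly testable: on a full $n_r \times n_c$ lattice the spectrum is
available in closed form (the Kronecker sum of path-graph Laplacian
spectra), which the package uses both for the field density's generalized
determinant and for exact spectral simulation. A Matérn/SPDE field would
be a natural extension point but is not implemented.

The field is indexed by lattice cell rather than by observation: clusters
falling in one cell share one $\zeta$ value, which makes the fitted
likelihood and the predicted surface use literally the same field.

### Priors

* $\alpha_t, \beta_k \sim N(0, 10^2)$ — weakly informative on the logit
  scale; covariates are standardized, so effects are per standard
  deviation and well inside $\pm 10$.
* $\sigma_\zeta \sim \text{Half-Normal}(1)$ — the field SD on the logit
  scale; national-scale mortality fields have logit SDs well below 1.

All prior scales are arguments (`priors = list(fixed_sd, sigma_sd)`).

## Preprocessing

**Extraction.** Covariates are read at cluster coordinates by nearest
cell, with ties on cell boundaries resolved by rounding the fractional
index half-down. No interpolation: at kilometre-scale rasters the
within-cell gradient is negligible, and the rule is exactly testable.
Clusters outside the extent or on NODATA cells are hard errors naming the
offending cluster ids — silent dropping of observations is never
appropriate in a mortality analysis.

**Collinearity screen.** The full Pearson correlation matrix is computed
and covariates are walked in declared order; one of each pair with
$|r| \ge 0.8$ is excluded — always the later-ordered member, so the
declared order encodes scientific preference. The default threshold 0.8
separates near-duplicate pairs (a temperature/altitude pair at
$r \approx -0.98$, which carries essentially one signal) from the
moderately correlated pairs around $|r| \le 0.65$ that remain jointly
estimable in a binomial regression of this size. The screen is idempotent
and order-stable.

**Standardization.** Retained columns are centred and scaled by their own
mean and SD; the record is stored in the fit and reused verbatim at
prediction time. Reported coefficients are therefore per-SD effects. This
is a deliberate choice: raw ecological covariates live on wildly
different scales (mm of rain, persons per km², metres of altitude), and
per-SD effects are the only scale on which their magnitudes can be
compared.

## Inference

The posterior is sampled by blocked adaptive Metropolis MCMC:

1. **$(\alpha, \beta)$** jointly, by random-walk Metropolis. The chain is
   initialized at the IRLS solution of the no-field binomial regression,
   overdispersed by three standard errors per chain, and the IRLS Fisher
   covariance seeds the proposal, which is then adapted (covariance and
   scale, targeting 23% acceptance) during burn-in only.
2. **$\zeta$** by a chromatic checkerboard sweep: under the rook ICAR
   prior, same-colored cells are conditionally independent given the other
   color, so each color is proposed and accepted cell-wise in one
   vectorized step (scale adapted to 44% acceptance). After each sweep the
   field is centred and the mean transferred into the intercepts — a
   likelihood-invariant projection that keeps the sum-to-zero constraint
   exact at every iteration.
3. **$\sigma_\zeta$** by random-walk Metropolis on the log scale.
4. **Joint rescaling** $(\zeta, \sigma_\zeta) \to (c\zeta, c\sigma_\zeta)$:
   the ICAR quadratic form is invariant under this map, so the move
   decouples the field amplitude from its scale parameter — the classic
   slow pair when the field is weakly informed.
5. **Interweaving** (when the covariate rasters are passed to
   `fit_mortality`): for each coefficient, a shear
   $\beta_k \to \beta_k + \delta$, $\zeta \to \zeta - \delta Z_k$ along
   the centred covariate surface $Z_k$. Because extraction is
   nearest-cell, every cluster's linear predictor is unchanged exactly,
   and the move is accepted on the prior terms alone. This addresses
   spatial confounding — smooth covariates and the field compete to
   explain the same variation, and without this move the coefficient
   chains can show split R-hat of 2 and above on large synthetic studies.

Burn-in defaults to half the iterations; adaptation happens only there, so
the retained chain is Markov. One master seed drives everything; per-chain
seeds are derived deterministically, so identical configurations give
byte-identical draws. Convergence is summarized by split R-hat per scalar
parameter (intercepts, coefficients, $\sigma_\zeta$); any value above 1.05
produces a warning and a `converged = FALSE` flag rather than an error —
the user decides whether to lengthen the run.

Credible intervals are equal-tailed posterior quantiles (not HPD), the
usual convention for tabulated intervals; an effect is flagged
"significant" when zero lies outside its 95% interval.

## Predictive checks

All checks consume the per-draw per-observation log-likelihood matrix
$L_{si}$ stored during sampling (and recomputable from the draws).

* **CPO** uses the harmonic-mean leave-one-out identity
  $\mathrm{CPO}_i = \left[\tfrac1S \sum_s e^{-L_{si}}\right]^{-1}$,
  evaluated in log space. Harmonic means can be unstable, so each
  observation carries a reliability flag based on the effective sample
  size of its importance weights (unreliable below $0.1\,S$).
* **PIT** uses the mid-correction for discrete outcomes,
  $\mathrm{PIT}_i = \hat P(Y^{\mathrm{rep}} < y_i) + \tfrac12
  \hat P(Y^{\mathrm{rep}} = y_i)$, with the replicate distribution
  averaged under the same leave-one-out weights as the CPO. Plain PIT is
  non-uniform for discrete data even under the true model; mid-PIT
  restores approximate uniformity and is the quantity the calibration
  tests assert against Uniform(0,1).
* **WAIC** is $-2(\mathrm{lppd} - p_{\mathrm{waic}})$ with
  log-sum-exp-stable lppd and the $S-1$ denominator in the pointwise
  variances. Model ranking is ascending in WAIC with ties (below $10^{-9}$)
  broken toward fewer parameters; models are verified to be fitted to the
  same data by checksum before comparison.

## Prediction and reporting

Surfaces are posterior summaries of $p$ per cell, computed by pushing
every retained draw through the link at every cell (cells with NODATA
covariates are masked). Rates are $1000 \times$ the posterior mean
probability — the model's binomial proportion is the mortality measure
throughout; the DHS synthetic-cohort life-table estimator is a different
quantity and deliberately out of scope. Regional aggregation assigns cells
to polygons by cell centre, weights uniformly by default (optionally by a
population raster; how published regional tables aggregate is generally
not documented, so the default stays neutral), counts rather than drops
unassigned cells, and rounds only at table-writing time. The national rate
equals the weighted mean of the regional rates by construction whenever
the regions partition the grid.

Trend summaries report consecutive and first-to-last changes, a
monotone-decline flag, and a stagnation flag raised when the change
between the last two surveys is below 5% of the earlier value.

Maps are written as ESRI ASCII grids (mean and interval bounds, per-1000
units) plus a PNG with a continuous color scale; GeoJSON is the vector
format for regions. These plain-text formats keep the pipeline free of
heavyweight geospatial dependencies.

## The synthetic-data generator

The generator emulates the structure of a multi-survey national mortality
study with known ground truth:

* **Covariates**: six smooth surfaces (Gaussian-kernel-smoothed white
  noise, kernel SD 3 cells by default) in plausible units — travel time
  to care, population density (log-normal), temperature, precipitation,
  altitude, distance to water. Altitude is constructed from the
  temperature surface so their empirical correlation *equals* the target
  (default $-0.978$), reproducing the near-duplicate pair that motivates
  the collinearity screen; precipitation is moderately anti-correlated
  with temperature ($-0.645$).
* **Field**: an exact spectral draw of the fitting ICAR (so recovery
  tests are free of model mismatch), rescaled so the realized SD equals
  `spatial_sd` (default 0.3 — a moderate residual-risk field on the logit
  scale). `spatial_range = Inf` keeps the intrinsic field; finite values
  temper the spectrum into a proper CAR for experimentation.
* **Truth**: per-SD effects default to magnitudes seen in national
  ecological analyses (largest $|\beta| = 0.19$); survey intercepts are
  either given directly or calibrated by root-finding so the grid-truth
  national rate matches requested per-1000 targets exactly (default the
  declining trajectory 121, 87, 73, 60, 59).
* **Clusters**: uniform random cells, coordinates uniform within the
  cell, births uniform on 20–60 per cluster (typical DHS cluster birth
  counts), deaths binomial at the cell-and-survey truth.

What it does **not** emulate: stratified two-stage sampling and design
weights, urban oversampling, deliberate GPS displacement, covariate
measurement error, and the retrospective birth-history construction of
exposure. Tests passing on this generator therefore demonstrate that the
estimator recovers its own data-generating process and that the pipeline's
logic is correct — not that design-based biases of real surveys are
handled.

## Problem sizes used by the test suite

Simulation sizes in the tests are the package's own choices, made for
statistical power:

* GLM-limit agreement: 500 clusters, no field — posterior means match
  IRLS to well under 0.05 per coefficient.
* Coverage: 15 replicates at 2,000 clusters monitoring a small
  ($-0.007$/SD) and a moderate ($0.13$/SD) effect; with a true 95%
  interval, observed coverage at 15 replicates falls in $[86\%, 100\%]$
  about 96% of the time per parameter.
* The five-survey trend scenario uses 8,000 clusters of 40–60 births per
  survey on a $50\times50$ grid. The sizing follows from a power
  calculation: the smallest step of the target trajectory (60 to 59 per
  1000) is a 1.7% decline, and observing a strict decrease requires the
  per-survey rate standard error ($\approx 1/\sqrt{N p(1-p)}$ on the logit
  scale, about 0.4 per 1000 at $N = 4\times10^5$ births) to be well below
  that step.
* CPO validation refits a 12-cluster model leaving out one observation at
  a time and compares against the harmonic-mean estimator.

## Numerical choices

* Binomial log-likelihoods use $y\eta - n\,\mathrm{log1pexp}(\eta)$ with a
  piecewise-stable $\log(1+e^\eta)$, finite beyond $|\eta| = 40$.
* All averages over draws of likelihoods use log-sum-exp.
* The ICAR generalized determinant uses the closed-form lattice spectrum;
  the field density validates its input against the sum-to-zero
  constraint.
* Degenerate inputs are first-class: zero field SD gives an exactly zero
  field; infinite smoothness gives constant covariates; zero-variance
  columns are excluded by the screen with their own reason and refused by
  the standardizer; empty cluster tables reduce the posterior to the
  prior.
* Intercept calibration solves $\mathrm{mean}(\mathrm{logit}^{-1}(\alpha +
  \eta_0)) = r/1000$ by `uniroot` to $10^{-12}$.

## Known limitations

* ICAR only; no Matérn/SPDE option, no anisotropy, no survey-by-space
  interaction field.
* The MCMC is designed for lattices up to a few thousand cells and data
  up to a few tens of thousands of clusters; far beyond that, sparse-matrix
  Gibbs or INLA-style approximations would be the right tool.
* Harmonic-mean CPO degrades for highly influential observations (hence
  the ESS flags).
* Coefficients are reported per SD of the training design; users wanting
  natural units must back-transform with the stored record.
* With strongly smooth covariates, coefficient and field effects are only
  jointly identified (spatial confounding); the interweaving update makes
  the sampler mix over this ridge but cannot sharpen what the data do not
  identify.
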