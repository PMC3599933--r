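---
title: "Two-stage analysis of distributed lag non-linear models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage analysis of distributed lag non-linear models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-location time-series studies in environmental epidemiology — heat and
cold waves, air pollution — proceed in two stages: a regression model per
location estimates the exposure–response association, and a meta-analysis
pools the location-specific estimates. When the association is both
non-linear *and* lagged, the first stage is a distributed lag non-linear
model (DLNM): the contribution of the exposure history to the log-rate at
time $t$ is

$$s(x_t;\boldsymbol\eta)=\sum_{j=1}^{v_x}\sum_{k=1}^{v_\ell}
  z_j(x_{t-\ell})\,c_k(\ell)\,\eta_{jk},$$

a surface spanned by the tensor product of a predictor-space basis
$\mathbf Z$ (dimension $v_x$) and a lag-space basis $\mathbf C$ (dimension
$v_\ell$) applied to lags $0..L$. The fitted object has $v_x\times v_\ell$
coefficients; an unstructured multivariate meta-analysis of that many
parameters needs $k(k+1)/2$ between-location covariance terms and is
computationally impractical for even moderately flexible bases.

This package implements the dimension reduction that makes the two stages
compatible. The three uni-dimensional summaries of the surface — the
*overall cumulative* curve $\sum_\ell s(x,\ell)$, the *predictor-specific*
lag curve at $x_0$, and the *lag-specific* exposure curve at $\ell_0$ — are
linear in $\boldsymbol\eta$, with matrices

$$\mathbf M_{[x_0]}=\mathbf I_{(v_\ell)}\otimes\mathbf z_{[x_0]}^\top,\qquad
  \mathbf M_{[\ell_0]}=\mathbf c_{[\ell_0]}^\top\otimes\mathbf I_{(v_x)},\qquad
  \mathbf M_{[c]}=\bigl(\mathbf 1^\top\mathbf C\bigr)\otimes\mathbf I_{(v_x)},$$

so that $\hat{\boldsymbol\theta}=\mathbf M\hat{\boldsymbol\eta}$ and
$V(\hat{\boldsymbol\theta})=\mathbf M V(\hat{\boldsymbol\eta})\mathbf M^\top$
give the $v_\ell$ or $v_x$ coefficients of the summary on its surviving
basis. The reduction loses nothing about the summary itself (the package's
master invariant, tested to $10^{-10}$: reduced fits and standard errors
equal the matching slice or sum of the full surface), but it cannot be
reversed — $\mathbf M$ has full row rank yet fewer rows than columns
whenever $\min(v_x,v_\ell)>1$.

The reduced coefficients are pooled with multivariate meta-analysis,

$$\hat{\boldsymbol\theta}_i\sim N\!\bigl(\mathbf U_i\boldsymbol\beta,\,
  \mathbf S_i+\boldsymbol\Psi\bigr),\qquad
  \mathbf U_i=\mathbf I_{(k)}\otimes\mathbf u_i^\top,$$

with $\mathbf S_i$ the within-location covariance from the first stage,
$\boldsymbol\Psi$ the unstructured between-location covariance, and
$\mathbf u_i$ optional location-level meta-variables (meta-regression).

## Coefficient ordering

`build_crossbasis()` orders the columns of the design matrix with the
predictor-basis index $j$ varying fastest within the lag-basis index $k$,
i.e. $\boldsymbol\eta$ stacks the $v_x\times v_\ell$ coefficient matrix
column-major. This is the ordering under which the three $\mathbf M$
matrices are the literal Kronecker products above. Other DLNM
implementations order the opposite way; the convention is stated here
because every downstream contraction assumes it.

## Where the reference enters

Curves are presented as log-relative-risks against a reference exposure
(`cen`, 17 °C in the temperature application). Centering is **not** baked
into the fitted basis: the design uses the raw basis, and the subtraction
$z(x)-z(\mathrm{cen})$ happens at prediction time. For overall and
lag-specific summaries the reduced $\boldsymbol\theta$ is therefore
reference-free and any reference can be chosen after reduction. For
predictor-specific summaries the reference must be folded into the
reduction itself (the centered row $\mathbf z_{[x_0]}-\mathbf
z_{[\mathrm{cen}]}$ replaces $\mathbf z_{[x_0]}$ in $\mathbf M_{[x_0]}$),
because the surviving basis spans the lag dimension and the subtraction
cannot be applied afterwards; such a reduced fit is locked to its
reference. Either placement produces identical curves, which is all the
presentation constrains.

## First stage

`fit_first_stage()` fits a quasi-Poisson GLM of daily counts on the
cross-basis plus confounders: a natural cubic spline of the time index with
`df_per_year` (default 10) degrees of freedom per 365.25 days, knots at
equally spaced quantiles of the time index, and day-of-week indicators
against a Monday baseline (any full-rank coding is equivalent). Rows whose
exposure history is incomplete — the first $L$ days, and any window
touching a missing exposure — are dropped (complete case). Only the
cross-basis block of the coefficients and of the dispersion-scaled
covariance matrix is retained; the Pearson-based dispersion thus propagates
into the second stage through $\mathbf S_i$, and no further rescaling is
applied before pooling.

Knot placement follows the conventions of the temperature-mortality
literature: predictor knots at equally spaced values (or quantiles) of the
pooled exposure distribution, lag knots at equally spaced log-lag values,
$\exp(j\log L/n_k)$, $j=0..n_k-1$ — for $L=21$, $n_k=3$ this puts knots at
lags 1.00, 2.76, 7.61. A multi-region analysis computes boundary and knots
once from the pooled exposure distribution and applies them identically in
every region, so that coefficients are commensurate across locations.

Basis evaluation is built on `splines::splineDesign` (Cox–de Boor recursion
with boundary knots repeated degree+1 times; the first basis function is
dropped when `intercept = FALSE`). The natural cubic variant projects the
cubic B-spline basis onto the null space of the second-derivative
constraints at the boundary knots and is linear at and beyond them. Points
beyond the boundary are extended with the exact polynomial of the terminal
span (linear for natural cubic), Taylor-expanded from a point strictly
inside the terminal span — `splineDesign`'s highest derivative is
unreliable exactly at the last knot — so prediction grids may slightly
exceed the observed range without error.

## Second stage

`fit_mvmeta()` estimates $\boldsymbol\beta$ and $\boldsymbol\Psi$ by REML
(default), ML, or fixed-effects GLS. $\boldsymbol\Psi$ is parameterized by
the log-Cholesky transform (log diagonal, free sub-diagonal), giving an
unconstrained vector of length $k(k+1)/2$ and positive semi-definiteness by
construction; $\boldsymbol\beta$ is profiled out by GLS inside the
likelihood. Optimization is BFGS with an analytic gradient (the envelope
theorem removes the $\partial\hat{\boldsymbol\beta}/\partial\boldsymbol\Psi$
term), starting from $\boldsymbol\Psi = 0.1\,\mathrm{diag}(\widehat{\mathrm{var}}\,
\boldsymbol\theta)$, with relative convergence tolerance $10^{-10}$ and a
bounded restart to polish the variance parameters — the value-based
stopping rule alone leaves $O(10^{-6})$ slack in $\boldsymbol\Psi$, which
the package's own oracle tests (agreement with an independent univariate
grid search to $10^{-6}$) do not tolerate.

With few locations or little true heterogeneity the estimated
between-location correlations can truncate at $\pm 1$ (a boundary of the
parameter space, not a failure); the fit converges and pooled estimates
stay finite, and the heterogeneity statistics can guide a fall-back to
fixed effects.

Heterogeneity is summarized by the multivariate Cochran
$Q=\sum_i \mathbf r_i^\top\mathbf S_i^{-1}\mathbf r_i$ with residuals from
the fixed-effects GLS fit on the same design (also when a random-effects
model is used for pooling — the conventional definition), $df = mk-kp$,
and $I^2=\max(0,(Q-df)/Q)\times100$. Meta-variable effects are tested with
Wald chi-square statistics on the corresponding $k$ coefficients; no
small-sample (Knapp–Hartung-type) adjustment is applied, and likelihood
ratio tests across fixed-effects structures are deliberately not offered
for REML fits. Confidence intervals use the normal multiplier 1.959964
throughout.

## Derived quantities

The minimum-mortality exposure is the argmin of the pooled overall
cumulative log-RR over a 0.1-degree grid spanning the boundary knots, with
ties broken toward the reference; a minimum on the grid edge (monotone
curve) is returned with a warning. Cumulative relative risks at the summary
exposures (defaults: pooled 1st and 99th percentiles, configurable to
literal values) are read off the same pooled curve. Moving-average
comparison models are cross-bases with a constant lag basis; their overall
reduction is exactly $(\ell_{\max}+1)\mathbf I$, i.e. the original spline
coefficients rescaled by the window length.

## The synthetic world

`simulate_regions()` generates the stated reference world: 10 regions of
5113 days (14 years). Per region, exposure is a seasonal cosine (annual
mean 10.4 °C, amplitude 7 °C, peak mid-July) plus AR(1) noise
(autocorrelation 0.85, innovation sd 1.5 °C), giving an England-like
−5..25 °C range; counts are negative-binomial with mean
$\exp(\text{baseline}_t + s(x_t;\boldsymbol\eta_i) - s_\text{ref})$, where
the baseline has mean 30 deaths/day, log-scale seasonal amplitude 0.15
(winter peak) and slope −0.005/year, and the negative-binomial size is set
so that $\mathrm{Var}=\varphi\mu$ with dispersion $\varphi=1.3$
(quasi-Poisson has no generative form; the negative binomial realizes the
same mean–variance inflation). The true surface is the least-squares
projection of a closed form — a protracted, gamma-weighted cold effect
reaching cumulative RR ≈ 1.3 at 0 °C and an immediate, exponentially
decaying heat effect reaching ≈ 1.1 at 22 °C, versus 17 °C — onto the
reference cross-basis, so the truth lies exactly in the model span and
analytic summary curves are available. Between-region heterogeneity is
injected on the cross-basis coefficients
($\boldsymbol\Psi_{\text{true}} = 0.005^2\mathbf I$ by default) and then
reduced, keeping the two stages jointly consistent; an optional latitude
multiplier on the cold half of the surface supports meta-regression tests.

What the generator does **not** emulate: spatial correlation of exposure
across regions, influenza epidemics and other shared count shocks,
mortality displacement (harvesting), day-of-week structure in the truth,
and non-stationary climate. A green end-to-end test therefore establishes
that the estimator recovers the stated generative structure — not that the
first-stage confounder model is adequate for real mortality series.

## Numerical choices and degenerate inputs

* Reduction identities are exact linear algebra; tests assert $10^{-10}$.
* Covariance sandwiches are symmetrized and checked PSD to $-10^{-10}$.
* The first stage refuses rank-deficient cross-bases, non-converged IRLS
  and all-missing exposure, naming the offending region.
* `Q = 0` (identical estimates) gives $I^2 = 0$, not NaN.
* A constant exposure series is rejected at knot placement (knots
  undefined), and `L` must be smaller than the series length.
* Exposure values outside the boundary knots are basis-extended, not
  errors; this matters for prediction grids and for simulated exposures in
  the tails.

## Known limitations

Penalized or Bayesian DLNM estimation, best linear unbiased predictions,
method-of-moments or Bayesian meta-analysis, structured $\boldsymbol\Psi$,
and relative-scale pooling for locations with very different exposure
ranges are out of scope. The identical-cross-basis requirement across
locations is a real constraint when exposure distributions differ
substantially. The acceptance criterion that reproduces the published
10-region England & Wales analysis requires the original supplementary
dataset, which is not redistributable with the package; the reproduction
pipeline ships and runs as soon as the CSV is placed at
`inst/extdata/regions_england_wales_1993_2006.csv`, and the corresponding
test is red (not skipped) in its absence.
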