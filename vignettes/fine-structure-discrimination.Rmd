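---
title: "Fine structure discrimination of textured images"
author: "finestruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine structure discrimination of textured images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finestruct)
```

## The problem

Early, subclinical stages of diabetic retinopathy change the retinal
microvasculature — vessel tortuosity, caliber, wall stiffness — in ways a
trained observer cannot reliably see in a fundus photograph. Fine
structure analysis sidesteps feature detection entirely: it treats the
whole pixel lattice of a fovea-centered region of interest (ROI) as a
realization of a spatial stochastic process, summarises each image by
the parameters of that process, and discriminates groups of subjects in
parameter space. This package implements the complete chain for any two
groups of grayscale textured images, together with a synthetic cohort
generator, so that every stage can be exercised and validated without
clinical data.

## The model

### Lag-shifted autoregressive representation

Each image patch $y_{i,j}$ is modelled as a weighted sum of copies of
itself shifted by one or two pixels along rows, columns and diagonals:

$$y_{i,j} \;=\; b_0 + \sum_{k=0}^{2}\sum_{l=0}^{2} b_{k,l}\,
  y_{i-k,\,j-l} + u_{i,j}, \qquad k + l > 0,$$

with $u_{i,j}$ a zero-mean error process. The 8 lag coefficients
$b_{k,l}$ plus the intercept $b_0$ are estimated by ordinary least
squares: the valid lattice sites (those whose 8 lagged neighbours all
lie inside the patch, i.e. rows and columns $\ge 3$) are stacked into a
single response vector in column-major order, each lag contributes one
design column, and a column of ones absorbs the nonzero sample mean.
The fit is computed by QR decomposition; the normal-equations form
$(X^\top X)^{-1} X^\top y$ appears in the test suite only, as an
independent oracle. The residual variance is estimated with
$n - 9$ degrees of freedom.

Two properties of this estimator matter downstream and are asserted as
invariants: the lag coefficients are invariant under affine intensity
maps $y \mapsto a y + c$ (only the intercept rescales), and residuals
are orthogonal to every design column to near machine precision.

### Weighted Fisher discriminant

For groups of $N_1$ and $N_2$ images, the per-image coefficient vectors
form matrices $B_1$ and $B_2$ (one column per image), and $B_p$ is their
column-wise concatenation. With sample covariances $\Omega_1, \Omega_2,
\Omega_p$ the projection direction $v$ solves the generalized
eigenproblem

$$\bigl(n_1 \Omega_p - n_2 \Omega_1 - n_3 \Omega_2\bigr)\, v
  \;=\; \gamma_1 \bigl(n_2 \Omega_1 + n_3 \Omega_2\bigr)\, v,$$

with $n_1 = N_1 + N_2 - 1$, $n_2 = N_1 - 1$, $n_3 = N_2 - 1$. This
weighting makes the left-hand matrix *exactly* rank one: writing $d$
for the difference of group mean coefficient vectors, the pooled
sum-of-squares identity gives

$$n_1 \Omega_p - n_2 \Omega_1 - n_3 \Omega_2
  \;=\; \frac{N_1 N_2}{N_1 + N_2}\, d\, d^\top ,$$

so exactly one eigenvalue $\gamma_1$ is nonzero up to floating-point
noise, and $v \parallel (n_2\Omega_1 + n_3\Omega_2)^{-1} d$ — the
classical two-class Fisher direction under the pooled within-group
covariance. Both facts are asserted in the test suite
($|\lambda_2| / |\gamma_1| < 10^{-6}$; angle to the closed form
$< 10^{-6}$ rad).

The package also exposes a `legacyBetween` switch that replaces
$\Omega_2$ by $\Omega_1$ a second time on the between side. That variant
appears in some descriptions of the method but destroys the rank-one
structure; it is retained off-by-default purely for comparison, and a
test documents that its spectrum is not rank one.

Numerically, the right-hand matrix $M = n_2\Omega_1 + n_3\Omega_2$ is
symmetric positive definite whenever $N_1 + N_2 - 2 \ge \dim(b)$ (11
images for the default 9 coefficients — smaller cohorts get a clear
singularity error). The problem is reduced by the Cholesky factor of
$M$ to an ordinary symmetric eigenproblem, which guarantees a real
spectrum; both sides are symmetrized as $(A + A^\top)/2$ beforehand to
remove rounding asymmetry. The eigenvector is unit-normalized with its
sign fixed so that group 1 projects above group 2, making reports
reproducible (either sign classifies identically; a test asserts this).

### Kullback–Leibler scoring

Each image's scalar projection $z = v^\top b$ is scored with the
Gaussian log-likelihood ratio

$$L(z) \;=\; \ln\frac{s_2}{s_1} + \frac{(z - m_2)^2}{2 s_2^2}
  - \frac{(z - m_1)^2}{2 s_1^2},$$

where $(m_g, s_g)$ are the sample mean and SD ($N-1$ denominator) of
each group's projections. Positive $L$ assigns group 1, negative
group 2, and $|L|$ ranks the confidence of the call
(`likelihoodStrength()`). The discrimination rate is the percentage of
images whose sign matches their true group, reported both exactly and
rounded to the nearest percent. A one-sample Kolmogorov–Smirnov
statistic of the standardized projections against the standard normal
is reported per group as a diagnostic of the Gaussian assumption; it
never gates classification, and because the mean and SD are estimated
from the same sample the p-value is conservative.

Two evaluation modes are provided. *Resubstitution* fits the direction
and the Gaussian summaries on the full cohort and scores the same
images — the in-sample protocol of the original method, optimistic by
construction. *Leave-one-out* re-solves the entire chain (covariances,
eigenproblem, projections, summaries) without the held-out image before
scoring it; it is the honest error estimate and is never larger than
resubstitution on average (asserted over seeded replicates). An exact
$L = 0$ tie is assigned to group 2 with a warning — deterministic and
conservative for the positive-means-group-1 convention. A leave-one-out
fold whose reduced group degenerates to zero variance is reported as
indeterminate and excluded from the rate with a warning.

## Region of interest

ROIs are circular and user-positioned (`roiSpec()`): the field this
method comes from centers them on the fovea by hand, and this package
deliberately does not guess a localization algorithm. The default
radius is 1000 px — for typical 2392 × 2048 fundus frames that circle
covers the macula; physical scale in mm/px is carried as metadata only.
Color input is converted with the ITU-R BT.601 luma weights
(0.299, 0.587, 0.114), the de-facto standard for fundus pipelines.

The circle is cut as its square bounding box (clipped at image borders
rather than rejected, for robustness to off-center fovea positions)
with an in-circle boolean mask. How the circular boundary should enter
a lattice regression is genuinely open, so it is an option:

* `zero_fill` (default): outside-mask pixels are set to 0 and all
  valid-region sites enter the regression — deterministic and shape
  independent, at the cost of a boundary artifact in the fitted
  coefficients that is common to all images and therefore largely
  cancels in the *difference*-based discriminant;
* `interior_only`: only sites whose own cell and all 8 lagged cells are
  inside the mask are kept.

## The synthetic cohort generator

The generator is the package's study population: a two-group cohort of
stationary causal autoregressive random fields whose classes differ in
their lag coefficients. Defaults were chosen once to emulate the
structure of the motivating clinical cohort and are not tuning knobs:

* group sizes 16 and 17 — the nondiabetic-control vs
  diabetic-without-retinopathy split of the motivating study;
* base coefficients $b_{0,1} = b_{1,0} = 0.20$, $b_{1,1} = 0.10$,
  $b_{0,2} = b_{2,0} = 0.04$, $b_{1,2} = b_{2,1} = 0.02$, $b_{2,2} = 0$
  ($\sum|b| = 0.62$) — moderate, anisotropy-free short-range
  correlation with headroom below the stationarity bound;
* class gap: $+0.1$ on the two first-order lags $b_{0,1}, b_{1,0}$ for
  the separated class (a `gap` argument scales this);
* innovation SD 0.05 on unit-interval intensities; between-image
  coefficient jitter SD 0.005 within each class;
* field size 256 × 256 after cropping a 64-pixel burn-in margin — large
  enough that coefficient-estimation noise (MAE well under 0.02) is
  small against the class gap, small enough that a 33-image cohort
  simulates and fits in seconds.

Generation is a raster-scan recursion (compiled, since it is inherently
sequential) with out-of-range lags seeded at the stationary process
mean $b_0 / (1 - \sum b_{k,l})$; the burn-in margin is cropped from the
top and left to remove the remaining transient, and quadrant means and
variances of the result agree within 5 % (tested). Stationarity is
enforced through the sufficient condition $\sum |b_{k,l}| < 1$ —
conservative, but cheap and safe; jittered per-image coefficients are
re-drawn on violation (at most 100 attempts). All randomness flows
through R's RNG: per-image sub-seeds are drawn under the master seed,
so every cohort is a pure function of its spec, and the generators
restore the caller's RNG state.

By default fields are min-max rescaled to `[0, 1]` like quantized
images, with the affine parameters recorded in metadata. Rescaling
shifts the recoverable intercept but not the lag coefficients (OLS
affine equivariance), so recovery checks compare only $b$; tests that
need the raw process (e.g. the stationary-mean check) pass
`rescale = FALSE`.

A second generator, `simulateVesselPhantom()`, draws dark vessel-like
curves of Gaussian cross-section whose sinusoidal angular perturbation
grows with a `tortuosity` parameter (arc length is strictly increasing
in it, verified against numeric integration). It is a qualitative
testbed for the claim that the method is sensitive to vessel
morphology; it makes no attempt at photorealistic fundus texture —
no microaneurysms, no optics or sensor model, no illumination field.

What passing tests on these cohorts do *not* show: that the method
separates real clinical groups at any particular rate. The synthetic
classes differ by construction in exactly the statistic the model fits;
real retinal texture differs in unknown, weaker and less homogeneous
ways, and the clinical images behind the motivating study are not
publicly available. The end-to-end tests therefore validate the
machinery (power rising from the null optimism band to 100 % as the
class gap grows), not any clinical effect size.

## Numerical and design choices

* Valid-region (edge-dropping) boundary handling in the design matrix,
  rather than wraparound or zero-imputed lags: standard causal-AR
  practice that fabricates no pixel values. A patch must provide at
  least 10 usable sites, so anything smaller than 6 × 6 is rejected.
* The intercept is carried into the discriminant by default
  (`useInterceptInB = TRUE`): the ones column is part of the estimated
  parameter set, and the projection simply ignores it when it carries
  no class information. The switch exists because excluding it is also
  defensible.
* Resubstitution is the default evaluation mode to mirror the original
  in-sample protocol; leave-one-out is recommended for honest error
  estimates.
* Report floats are serialized at 17 significant digits; reruns with
  identical configuration are byte-identical (tested), and run logs
  contain no timestamps.
* Eigenvalues below $10^{-9} |\gamma_1|$ are treated as numerically
  zero in the rank-one diagnostic.
* Problem sizes in the test suite: parameter recovery at 512 × 512 over
  20 seeds; the power curve at 256 × 256, group sizes 16/17, 50 seeds
  per class-gap level — the package's chosen trade-off between
  statistical resolution and a test suite that runs in minutes.

## A worked run

```{r example, eval = FALSE}
library(finestruct)

co <- generateCohort(cohortSpec(seed = 3, gap = 0.1))
B1 <- groupCoeffMatrix(lapply(co$group1, fitImage), "control")
B2 <- groupCoeffMatrix(lapply(co$group2, fitImage), "case")

fld <- solveFld(B1, B2)
rankOneRatio(fld)          # ~1e-16: one direction carries the signal

report <- discriminateGroups(B1, B2, mode = "leave_one_out")
report                     # rate, confusion counts
head(likelihoodStrength(report))
```

File-based cohorts run through `runDiscrimination()` on a CSV manifest
(`path,group,center_row,center_col,radius_px`, 0-based indices), or the
`inst/scripts/finestruct.R` command-line wrapper.

## Limitations

* Two groups only; no multi-class extension, no shrinkage covariance,
  no ROC analysis.
* The discriminant needs $N_1 + N_2 \ge \dim(b) + 2$; tiny cohorts fail
  with a singularity error rather than a silently regularized fit.
* Resubstitution rates are optimistic by design; on exchangeable groups
  they average roughly 60–75 % rather than 50 %.
* The ROI center is user input; there is no fovea detector,
  illumination correction or vessel segmentation.
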