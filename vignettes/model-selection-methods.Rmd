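---
title: "Selecting among non-nested longitudinal growth models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting among non-nested longitudinal growth models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Child growth trajectories are routinely modelled with tools as different as
spline mixed-effects models and functional data analysis. These families are
not nested, so likelihood-ratio tests, AIC or BIC cannot arbitrate between
them. `growthsel` implements the alternative this package is built around:
compare models by *out-of-sample predictive accuracy*, using subject-specific
error metrics tailored to growth data, under hold-out patterns that mimic the
prediction tasks clinicians actually face.

```{r setup}
library(growthsel)
```

## The three model families

All models act on sparse longitudinal data $(t_{ij}, Y_{ij})$: height in cm
for child $i$ at age $t_{ij}$ months, $j = 1, \dots, m_i$, with a binary sex
indicator $X_i$ (1 = male by default).

**Spline linear mixed effects (LME).** The population mean is a truncated
cubic spline in age with knots at 3, 6, 12 and 18 months — the ages where
infant growth velocity changes the most — plus a time-invariant sex effect:

$$Y_{ij} = \beta_0 + b_{0i} + (\beta_1 + b_{1i})\,t_{ij} + \beta_2 t_{ij}^2 +
\beta_3 t_{ij}^3 + \sum_{k \in \{3,6,12,18\}} \gamma_k (t_{ij}-k)_+^3 +
\alpha_1 X_i + \epsilon_{ij}.$$

The random intercept and slope $(b_{0i}, b_{1i})$ have an unstructured
$2\times 2$ covariance $G$; the within-subject errors follow a
continuous-AR(1) process, $\mathrm{Cor}(\epsilon_{ij}, \epsilon_{il}) =
\rho^{|t_{ij}-t_{il}|}$ with variance $\sigma^2$, which soaks up the serial
correlation a random intercept/slope alone leaves behind in densely sampled
growth data. Because $\rho$ is a per-month correlation its magnitude depends
on the age unit — everything in this package is months. Estimation is REML
through `nlme::lme()`. Subject effects for *any* child — including one never
seen during fitting — are predicted by the BLUP
$\hat b_i = G Z_i^\top V_i^{-1}(y_i - X_i\hat\beta)$ under the frozen
population parameters, which is also exactly how `predict_lme()` conditions
on a held-out child's in-sample records.

**Sparse functional PCA (fPCA).** $Y_{ij} = f_0(t_{ij}) + b_i(t_{ij}) +
\epsilon_{ij}$, where $b_i$ is a zero-mean Gaussian process with covariance
$C(s,t)$. The pipeline is the classical conditional-expectation approach for
sparse functional data: smooth the pooled mean, smooth the within-subject
cross-products $r_{ij} r_{il}$ ($j \ne l$) into a covariance surface,
eigendecompose it with trapezoid quadrature, keep the leading $K$
eigenfunctions, and score each child by the BLUP
$\hat\xi_i = \Lambda \Phi_o^\top (\Phi_o \Lambda \Phi_o^\top +
\sigma^2 I)^{-1} (y_i - f_0(t_i))$.

**Functional concurrent regression (FCR).** fPCA plus the same
time-invariant sex effect as the LME: $Y_{ij} = f_0(t_{ij}) + \alpha_1 X_i +
b_i(t_{ij}) + \epsilon_{ij}$. fPCA is the special case $\alpha_1 = 0$, which
is what makes the three-way comparison interesting: FCR shares covariate
structure with the LME and flexibility with fPCA.

## Numerical choices in the functional pipeline

These are the decisions the model description leaves open; each is a
package choice, stated here so results can be interpreted:

* **Grid.** 101 equally spaced ages spanning the training data (or the full
  monitoring window when out-of-range predictions will be requested — only
  visit *times*, never held-out heights, inform the grid). Mean and
  eigenfunctions are linearly interpolated off the grid; requesting ages
  outside it is an explicit error, never a silent clamp.
* **Mean smoother.** Penalized spline via `mgcv` with an *adaptive* penalty
  (`bs = "ad"`, basis dimension 25). Infant growth concentrates its curvature
  in the first months; a single global smoothing parameter, chosen against
  residuals dominated by ±2 cm subject-level deviations, oversmooths the
  neonatal bend and leaves a 0.3–0.5 cm boundary bias. The adaptive penalty
  removes it while keeping straight lines in the penalty null space. Data
  with fewer than 15 distinct ages fall back to a cubic regression spline.
* **Covariance smoother.** Off-diagonal cross-products are aggregated into a
  25 × 25 age-pair bin grid (weighted by bin counts) and smoothed with a
  tensor-product cubic spline, `te(k = c(6,6))`. Binning makes the smoother's
  cost independent of the ~10^5 raw cross-products; the low marginal basis
  dimension reflects that growth covariance surfaces are very smooth, and
  measurably reduces spurious high-order eigenvalues that would inflate the
  selected rank.
* **Smoothing-parameter criterion.** REML throughout. On simulated rank-2
  truth it selects the correct number of components more reliably than GCV,
  which occasionally undersmooths the covariance surface into a spurious
  third component.
* **Noise variance.** $\hat\sigma^2$ is the average positive gap along the
  diagonal between a 1-D smooth of $r_{ij}^2$ (targeting $C(t,t)+\sigma^2$)
  and the fitted surface (targeting $C(t,t)$), floored at $10^{-8}$ so
  noiseless fixtures cannot produce singular scoring systems.
* **Rank.** Smallest $K$ whose eigenvalues reach 99% of the positive
  eigenvalue mass (`pve = 0.99`); negative eigenvalues are truncated.
  Eigenfunction signs are fixed (nonnegative integral, ties broken by a
  positive leftmost value) so score-recovery tests are deterministic.
* **FCR estimation.** Backfitting: initialize $\hat\alpha_1$ from the
  sex-group difference of residuals around a common smooth mean, then
  alternate a full fPCA fit of the sex-adjusted heights with a weighted
  least-squares update of $\alpha_1$ (children weighted equally via $1/m_i$
  observation weights, so heavily sampled children do not dominate). The raw
  iteration is a linear contraction with ratio ≈ 0.95, because the subject
  BLUPs absorb most of each $\alpha_1$ update; Aitken extrapolation jumps to
  the fixed point, and the loop typically converges in 3 iterations at
  tolerance $10^{-4}$ cm.
* **LME numerics.** The fast `optim` path of `nlme` occasionally hits a
  backsolve singularity on ill-conditioned splits (e.g. half the cohort
  missing all early ages); fitting transparently retries with `nlme`'s
  default `nlminb` machinery before reporting failure.

## The four metrics

All metrics are subject-specific, computed over each child's evaluated
records ($m_i$ is that count — in hold-out evaluation, the child's
out-of-sample count):

* **MSE**: $\frac{1}{m_i}\sum_j (Y_{ij} - \hat Y_{ij})^2$, in cm².
* **nMSE**: $\frac{1}{m_i}\sum_j (Y_{ij} - \hat Y_{ij})^2 / Y_{ij}^2$ —
  squared relative errors, unit-free, so taller (older) children do not
  dominate the comparison.
* **aMSE**: per age stratum $s$, $\frac{1}{m_i}\sum_{j \in s}
  (Y_{ij}-\hat Y_{ij})^2$. The divisor is deliberately the subject's *total*
  $m_i$, so the strata values sum exactly to the subject's MSE (default
  strata 0–6–12–18–24 months, matching the spline knots); a
  within-stratum-mean variant is available via `per_stratum_mean = TRUE`.
* **wMSE**: MSE divided by the child's height-velocity quartile weight
  (1–4). Velocity is the finite difference between the observations nearest
  3 and 12 months; children are percentile-ranked
  ($(\mathrm{rank}-1)/n \times 100$, average ranks for ties — the convention
  under which a fully tied cohort lands in the second quartile) and the
  slowest quartile gets weight 1, so slow-growing children — the group that
  usually matters clinically — carry the most weight.

Summaries are medians with IQR (linear-interpolation percentiles); within
each scenario × metric the model with the smallest median is flagged best.

## The four hold-out scenarios

`make_split()` induces missingness patterns on a per-child basis; models are
fit on in-sample records only and judged at the held-out points:

* **backward** — each affected child's earliest $\lceil h\,m_i\rceil$
  records held out (predicting early growth from later data);
* **forward** — the latest records held out;
* **in-range** — interior records held out, never a child's first or last
  (pure interpolation);
* **new individuals** — $\lceil h\,n\rceil$ whole children held out.

Half the children are affected in the per-child scenarios; 10/20/50% are the
usual hold-out fractions, with 20% the primary analysis. Rounding uses the
ceiling. For a new individual, population parameters are frozen from the
training fit and the child's own observations are used to predict their
subject-level effects (BLUP / conditional scores) before evaluating at those
same points — the reading of "in-range prediction on new individuals" under
which that scenario can beat all others, as the per-child conditioning
removes the hardest part of the problem; a pure population prediction is
available via `condition_new = FALSE`. By construction no held-out record
enters any design matrix, smoother or covariance estimate, and the test
suite proves it by poisoning held-out heights and asserting fits are
unchanged.

Whether the same 50% of children should be reused across backward, forward
and in-range is an open design point; splits are redrawn per scenario from
the scenario seed here.

## What the synthetic cohort emulates — and what it does not

`default_content_spec()` mimics the design of a peri-urban Peruvian birth
cohort with near-biweekly anthropometry: 215 children, 49% male, up to 39
visits from birth to 24 months, lognormal inter-visit lags with median 14
days. A two-parameter lognormal cannot also match the reported asymmetric
lag IQR of (11, 27) days; `sdlog = 0.665` matches the quartile *ratio*, and
the simulated median visit count and median lag land inside the design
targets (checked over 20 seeds in the test suite). Trajectories are
$f_0(t) + \alpha_1 X_i + \sum_k \xi_{ik}\phi_k(t) + \epsilon_{ij}$ with:

* $f_0(t) = a + bt + c\log(1+t)$ anchored at (0, 50), (12, 74),
  (24, 85) cm — a monotone, decelerating infant-growth shape;
* two orthonormal eigenfunctions — a level shift and a velocity contrast
  (centered linear) — with variances $\lambda = (4, 1)$ cm²;
* sex effect 1 cm; measurement noise 0.5 cm, optionally CAR(1)-correlated;
* a Uniform(0, 0.5)-month birth-age jitter so the covariance estimate is not
  degenerate at the left boundary;
* one independent random stream per child derived from the master seed, so
  growing the cohort does not reshuffle existing children.

The generator underpins every recovery test: the LME recovers its
generating fixed effects and $\rho$, fPCA the rank, leading eigenvalue and
eigenfunctions, FCR the sex effect (and its absence under the null). What
passing those tests does *not* show: real growth data have skewness,
outliers, informative dropout, seasonal measurement artifacts and mean
shapes outside this family — none are emulated, and no claim about the
models' ranking on real cohorts follows from the synthetic results. The
generator's truth is a stand-in chosen by this package, not an estimate of
any real cohort.

## Problem sizes and degenerate inputs

The test suite exercises the statistical claims at the sizes the package
treats as its reference conditions: 50 replicate LME fits at $n = 200$
children (~20 visits each), 20 replicate fPCA/FCR fits on the full
215-child cohort, and a 10-seed sensitivity sweep (3 scenarios × fractions
0.1 and 0.5 × 3 models) on one default cohort. Degenerate inputs are
contracts, not accidents: duplicate (subject, age) rows keep the first
occurrence (a CAR(1) correlation of $\rho^0 = 1$ makes duplicates
singular); constant-height data short-circuit the mean smoother; a
covariance surface with no positive eigenvalues, a single-subject LME fit,
a single-sex FCR fit, and holding out a child's every record in a per-child
scenario are all explicit errors; fewer than 4 children make velocity
quartiles meaningless and fall back to unit weights with a warning.

## Known limitations

* The covariance smoother is a binned tensor-product approximation to
  leave-one-subject-out-tuned approaches; its smoothing parameter is chosen
  by REML on the binned products, not by subject-level cross-validation.
* FCR's sex effect is estimated by backfitting, a two-stage procedure; a
  joint estimator could differ at small $n$.
* Functional predictions outside the training age range rely on the
  penalized splines' own (linear) extrapolation and should be read with the
  usual caution; the LME extrapolates its cubic polynomial by construction.
* Metrics are means of squared errors and inherit their outlier
  sensitivity; robust variants are out of scope.
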