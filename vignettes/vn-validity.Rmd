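---
title: "Testing the statistical validity of meta-analysis summaries with Vn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the statistical validity of meta-analysis summaries with Vn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metavalid)
```

## The question and the model

A meta-analysis pools study effects into a summary, but a reader in a
particular clinical setting needs more than a pooled number: they need
the parameter the model estimates to *equal* the true effect in their
setting. We call that property statistical validity. `metavalid`
operationalises it for the study-level random-effects model

$$y_i = X_i\beta + \delta_i + \varepsilon_i,\qquad
  \delta_i \sim N(0,\tau^2),\quad \varepsilon_i \sim N(0, v_i),$$

where $y_i$ is study $i$'s effect on the analysis scale (log relative
risk, logit PPV, ...), $v_i$ its within-study sampling variance treated
as known, and $\tau^2$ the unexplained between-study variance. With an
intercept only, the single coefficient is the summary effect $\mu$; with
study-level covariates, the fitted value at a setting's covariates is a
summary estimate *tailored* to that setting. Fitting is by restricted
maximum likelihood throughout.

## The Vn statistic and its null distribution

Omitting each study in turn and refitting gives a genuine out-of-sample
prediction $\hat y_{-i}$ for the omitted study (at its covariates, for a
regression), with model variance $\mathrm{var}(\hat y_{-i}) =
x_i^\top \mathrm{cov}(\hat\beta_{-i}) x_i$. The validation statistic is

$$V_n \;=\; \sum_{i=1}^k
  \frac{(y_i - \hat y_{-i})^2}{v_i + \mathrm{var}(\hat y_{-i})}.$$

Each $\hat y_{-i}$ is a weighted least-squares combination of the other
effects, so the vector of prediction errors is $A y$ for a $k \times k$
matrix $A$ whose $i$-th row is $e_i - h_i$, $h_i$ being the hat row with
weights $w_{-ij} = 1/(v_j + \hat\tau^2_{-i})$. $A$ has unit diagonal,
its rows sum to zero whenever the model has an intercept, and its rank
is $k - p$; the null hypothesis of validity is exactly $A\mu = 0$. For a
meta-analysis the kernel of $A$ is the constant vectors — validity holds
only under homogeneity. With $p - 1$ covariates the kernel is the
$p$-dimensional space of means lying on the fitted plane, so a tailored
model can be valid even though the studies are heterogeneous.

Writing $V_n = y^\top A^\top W^* A y$ with
$W^* = \mathrm{diag}\{1/(v_i + \mathrm{var}(\hat y_{-i}))\}$ and
standardising $y$ under the null gives

$$V_n \sim \sum_{i=1}^{k} \lambda_i \chi^2_1,$$

the $\lambda_i$ being the eigenvalues of
$B = W^{-1/2} A^\top W^* A W^{-1/2}$, $W = \mathrm{diag}(1/v_i)$. The
distribution is exact when the $v_i$ are known and asymptotic when they
are estimated. Exactly $k - p$ eigenvalues are non-zero (rank–nullity),
and the implementation drops eigenvalues below $10^{-10}\lambda_{\max}$
as numerical noise after symmetrising $B$.

Two modelling choices deserve note, since the linearisation behind $A$
is not unique:

* the leave-one-out $\hat\tau^2_{-i}$ (one per row) are plugged into the
  weights of $A$ and treated as fixed, mirroring the asymptotic
  argument; `vn_test(..., tau2_weights = "common")` substitutes the
  full-data $\hat\tau^2$ in every row. The two spectra differ only
  slightly; the default reproduces the published case-study p-values.
* the denominator of $V_n$ uses the sampling variance $v_i$ only. Under
  the null the marginal variance *is* the sampling variance, so adding
  $\hat\tau^2$ (available via `denominator_tau2 = TRUE`) would be
  conservative; it is off by default.

## Computing tail probabilities

The mixture $\sum_i \lambda_i\chi^2_1$ has no closed form. The default
evaluator is the Ruben expansion (as used in Farebrother's algorithm):
with scale $\beta = \lambda_{\min}$,

$$P\!\left(\textstyle\sum_i \lambda_i \chi^2_1 \le q\right)
  = \sum_{j\ge 0} c_j\, F_{\chi^2_{k+2j}}(q/\beta),$$

whose coefficients are non-negative and sum to one, so the tail of the
series is bounded by the unaccumulated mass — a *certified* truncation
error, reported with every p-value. The series is truncated when that
bound drops below `tol` (default $10^{-6}$) relative to the accumulated
probability, with a floor of $10^{-13}$, so p-values as small as
$10^{-9}$ are still resolved; the upper tail is accumulated in survival
form to avoid cancellation. When all eigenvalues are equal the mixture
collapses to a scaled $\chi^2_k$ and the series terminates after one
term. If the series were ever to hit its term cap ($10^5$), the p-value
falls back to characteristic-function inversion and the result is
flagged.

Two independent evaluators back the series. `imhof_cdf()` inverts the
characteristic function: the inversion integrand oscillates with slowly
decaying envelope, so it is integrated lobe-by-lobe between consecutive
zeros of the phase (which is eventually monotone) and the alternating
lobe series is summed with Euler acceleration, reaching ~$10^{-10}$
absolute accuracy even for a single weight. `mc_cdf()` is the
brute-force empirical CDF of $\sum_i \lambda_i z_i^2$. `satterthwaite_cdf()`
is the classical moment-matched scaled-$\chi^2$ approximation, provided
for comparison only. The test suite holds Ruben and Imhof within
$10^{-6}$ of each other across random spectra and both within
Monte-Carlo error of the empirical oracle.

## REML fitting

$\hat\tau^2$ maximises the restricted likelihood profiled over $\beta$,
by Fisher scoring with step-halving, updates projected to
$\tau^2 \ge 0$, convergence at $|\Delta\tau^2| < 10^{-8}$ and at most
100 iterations (non-convergence is flagged on the returned object, never
silent); a one-dimensional direct optimisation backs the scoring path if
it degenerates. The tests pin the fitter against a dense grid search of
the restricted log-likelihood (step $10^{-5}$, agreement within
$10^{-4}$) and against an independent mainstream implementation.
Coefficient covariance is $(X^\top WX)^{-1}$ at the converged weights
$1/(v_i+\hat\tau^2)$; intervals use normal quantiles (no small-sample
adjustment — this choice reproduces the published case intervals), and
prediction intervals add $\hat\tau^2$ inside the half-width,
$z\sqrt{\hat\tau^2 + x_0^\top \mathrm{cov}(\hat\beta)x_0}$.

Interpretation aids: Cochran's $Q$ (fixed-effect weights $1/v_i$,
$\chi^2_{k-p}$ reference), the Higgins–Thompson typical standard error
$\bar{se} = [(k-1)\sum w_i/((\sum w_i)^2 - \sum w_i^2)]^{1/2}$, and
$I^2 = 100\,\hat\tau^2/(\hat\tau^2 + \bar{se}^2)$. The $\tau^2$-based
$I^2$ (rather than $(Q - df)/Q$) is deliberate: evaluated on the two
case datasets it reproduces the published 92.2% and 59.75%, while the
$Q$-based form gives 92.1% and 61.0%. The ratio $\hat\tau/\bar{se}$ is
the axis along which the power of both tests grows.

## Case data

Two published datasets are built in. `berkey_bcg()`: 13 BCG vaccine
trials, log relative risk, latitude moderator. `leeflang_galactomannan()`:
7 diagnostic studies of the galactomannan assay, logit PPV at an optical
density index threshold of 0.5, logit prevalence moderator. Neither
source prints the raw 2×2 tables, so effects are the printed per-study
estimates and variances are reconstructed from the printed 95% CIs via
$[(u-\ell)/2z_{0.975}]^2$ with the full-precision quantile 1.959964.
Because estimates and intervals are printed to two decimals, every
downstream statistic inherits that rounding; the acceptance checks
therefore compare at 2% relative tolerance (0.5 points for $I^2$). For
datasets supplied as counts, `effect_log_rr()` and `effect_logit_ppv()`
construct the effects, adding a 0.5 continuity correction to every cell
if and only if some cell is zero (the convention used for the one
corrected study in the PPV dataset).

```{r cases}
fit <- rema(y ~ 1, berkey_bcg())
vn_test(fit)
vn_test(rema(y ~ lgtprev, leeflang_galactomannan()))
```

## What the simulation harness emulates

`run_sim_cell()` rebuilds the reference simulation design: each study's
patient-level data are $n$ draws from $N(\mu_i, \sigma^2)$, summarised
into $y_i$ (mean), $\hat\sigma_i^2$ (sample variance) and
$v_i = \hat\sigma_i^2/n$ — so the $v_i$ are *estimated*, as in practice,
which is exactly what inflates the small-$k$, small-$n$ type-1 error of
Vn relative to Q. Under the meta-analysis null all $\mu_i$ equal a
single $N(0,1)$ draw; under the regression null two anchor means are
drawn from $N(0,\tau^2)$ and the rest placed exactly on the line through
them in the covariate (kernel membership by construction); under the
alternative $\mu_i \sim N(0,\tau^2)$ i.i.d. The anchor variance for the
regression null is not pinned down by the reference design's type-1
tables; the rejection rate is empirically insensitive to it (it moves by
less than one Monte-Carlo standard error across $\tau^2 \in
\{0, 0.25, 0.5\}$, as expected since the null holds regardless), and the
harness adopts the grid midpoint $\tau^2 = 0.25$ for its anchor cell.

Default replications per cell are 4000, giving a Monte-Carlo standard
error of about 0.0035 for rates near 5% — enough to check calibration
while a cell completes in seconds; the reference design used 40 000,
which `reps` accepts directly. Per-cell seeds are derived from a master
seed and the cell's own parameters, so a grid's results are independent
of cell order. Failed replications (singular designs, non-convergent
fits) are dropped, counted, and flagged if they exceed 1% — in practice
they are absent at these grid points.

What the generator does *not* emulate: real meta-analyses have unequal
study sizes and variances, non-normal patient-level data, selective
publication, and correlated covariates. Passing the calibration checks
here demonstrates the statistic and its null distribution are computed
correctly under the stated model, not that the model describes any
particular literature.

## Numerical choices and limitations

* Problem sizes in the test-suite: case datasets as published (k = 13
  and 7); calibration by simulation uses 4000-replication cells and a
  $10^4$-draw Kolmogorov–Smirnov check of the null law with known
  variances (distance < 0.02).
* The method-of-moments $\tau^2$ estimator is not provided; REML is the
  estimator used for every published quantity the package reproduces.
* Vn is univariate: no bivariate sensitivity/specificity variant.
* Leave-one-out refits need $k \ge p + 2$; with very small $k$ the
  asymptotic null distribution is used far from its comfort zone, which
  is precisely the inflation the simulation tables quantify.
* Degenerate inputs: identical studies give $V_n = 0$, $p = 1$;
  zero-variance spectra are rejected with an informative error rather
  than returning NaN; a singular leave-one-out design names the
  offending study.
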