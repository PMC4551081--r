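---
title: "Directed functional connectivity with uSEM: models, search, and temporal-order validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed functional connectivity with uSEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usemr)
```

## The model family

The unified structural equation model (uSEM) is a structural vector
autoregression for a p-variate ROI time series $y(t)$, $t = 1, \dots, T$,
with the mean fixed at zero:

$$y(t) = A\,y(t) + \Phi_1 y(t-1) + \cdots + \Phi_a y(t-a) + \zeta(t),$$

where $A$ holds contemporaneous regressions among ROIs (diagonal
structurally zero), $\Phi_q$ holds the lag-$q$ regressions, and the process
innovations $\zeta$ are serially independent with a *diagonal*
contemporaneous covariance $\Psi$.  The diagonal $\Psi$ is what
distinguishes the uSEM from a reduced-form VAR: all contemporaneous
covariation must be carried by $A$, and the model is estimated directly
rather than via a Cholesky factorization, so the result does not depend on
the declared ordering of the ROIs.

The extended uSEM (euSEM) adds two kinds of task-input terms: direct
effects $\gamma_r u(t-r)$ ($r = 0..f$) of an HRF-convolved input vector
$u$, and bilinear terms $\tau_{qr}\, y(t-q)\,u(t-r)$ that let the input
modulate lagged ROI-to-ROI connections.  GIMME (group iterative multiple
model estimation) fits uSEMs to a multi-subject sample in two stages: a
group-level structure shared by all subjects, then subject-specific
individual-level additions.

## Estimation on the block-Toeplitz lagged covariance

Write $x(t)$ for the stacked lagged variables (and, for the euSEM, the
appended input and product variables) and $e(t) = y(t)$.  The second-moment
structure of $(x, e)$ is estimated by the block-Toeplitz method: the lag-$l$
cross-covariance $C(l) = (T-l)^{-1}\sum_t y(t)\,y(t+l)'$ is computed over
every full-overlap pair and tiled, so block $(j, k)$ of the $m \times m$
matrix $S$ depends only on $k - j$ exactly.  Input and product columns are
appended from the embedded data rows; product regressors are built from the
centered series and the convolved input, then centered, keeping the
zero-mean moment structure coherent.

With the exogenous block $\Sigma_{xx}$ saturated and $\Psi$ diagonal, the
ML discrepancy concentrates analytically: $\Sigma_{xx}$ profiles to
$S_{xx}$ and $\psi_j$ to the residual variances, leaving

$$F(A, B) \;=\; \log\det S_{xx} + \sum_j \log W_{jj}
  - 2\log\lvert\det(I-A)\rvert - \log\det S, \qquad
  W = R\,S\,R', \quad R = [-B,\; I-A],$$

a smooth function of only the freed regression coefficients.  It is
minimized by BFGS with the analytic gradient (start values zero,
convergence at gradient norm $10^{-6}$, at most 500 iterations with one
restart).  $\chi^2 = (n_{\mathrm{eff}}-1)\,F$ at the optimum, with
$n_{\mathrm{eff}} = T - a$ (the number of usable embedded rows);
white-noise tests on residuals of an order-$a$ model consequently use
$(T-a)-L$.  Standard errors come from the inverse expected (Fisher)
information over *all* free parameters — regressions, innovation
variances, and the saturated exogenous block — scaled by
$2/(n_{\mathrm{eff}}-1)$; 95% intervals are $\pm 1.96\,\mathrm{SE}$.

Degrees of freedom follow the moment count
$df = m(m+1)/2 - (m-p)(m-p+1)/2 - p - k_{\mathrm{free}}$: distinct second
moments, minus the saturated exogenous block, the $p$ innovation variances,
and one per freed regression.  A specification that would drive $df$
negative is refused.

Model fit is judged by four alternative indices against the independence
baseline (diagonal implied covariance, $df_b = m(m-1)/2$): RMSEA, SRMR,
CFI (clipped to $[0,1]$), and NNFI (reported unclipped; undefined at
$df = 0$).  A model is accepted when at least 2 of the 4 tests pass at the
conventional thresholds (RMSEA $\le 0.05$, SRMR $\le 0.05$, CFI $\ge 0.95$,
NNFI $\ge 0.95$); boundary equality passes and a missing index counts as a
failed test.

## The data-driven search

The search starts from the null model (empty $A$ and $\Phi_q$; innovation
variances and the exogenous block free) and repeatedly frees the candidate
with the largest modification index (MI).  The MI is the Lagrange-multiplier
statistic: the squared fit-function gradient over the candidate's expected
information conditioned on the free parameters, scaled by
$(n_{\mathrm{eff}}-1)/2$, which approximates the $\chi^2$ drop from freeing
that one parameter and refitting.  Candidates are freed only while
significant at $\chi^2(1)$, $\alpha = 0.05$ uncorrected; ties break to the
lowest (lag, target, source).  After the search, non-significant parameters
are trimmed by Wald tests, largest p-value first, refitting after each
removal.

**Stop rule.**  The search stops as soon as the model reaches excellent fit
under the 2-of-4 rule (or earlier, when no candidate MI is significant).
This was a genuinely open design point; we resolved it by the method's own
bookkeeping: a data-driven second-order fit to the 3-ROI demonstration
scenario should spend only about 4 freed parameters (leaving residual
misfit for the validation loop to localize), which is only possible if the
search halts at excellent fit, and an uncapped rule would free on the order
of $1.4$ spurious parameters per run on pure white noise (15 candidates at
uncorrected $\alpha = 0.05$), which contradicts the family's observed
near-null sparsity.  Residual misfit beyond the 2-of-4 threshold is the
job of the a posteriori validation loop, not the search.

**Orientation of contemporaneous pairs.**  At the null model the two
orientations of a contemporaneous pair are exactly covariance-equivalent
(the classical two-variable non-identification), so the MI cannot choose
between them; the lagged structure added later does identify the direction.
The search therefore re-evaluates each freed $A$ edge against the final
structure by refitting its reversal and keeping the better-fitting
orientation, and additionally tries the coherent reversal of the whole
edge set, which escapes the locally-optimal fully-reversed configurations
that single flips cannot (e.g. a directed ring the wrong way round).  The
same applies at the group level in GIMME, scored by the total $\chi^2$
across subjects.  For data with no temporal structure at all the
orientation remains genuinely unidentified — a limitation of the model
class, not of the search.

**Input lags.**  The HRF-convolved input at adjacent lags is nearly
collinear (a one-TR shift of a smooth regressor, correlation $\approx$
0.98), so the MI locates a direct effect but not reliably its lag; the
search compares the candidate $\gamma$ lags of the same effect by refit
and keeps the best.  Even so, the exact lag is recovered less reliably
(about three quarters of the time in our tests) than the target ROI
(essentially always).

## GIMME

Stage 1 iterates over the sample: per-subject MI tables are computed at the
current group model, each candidate is scored by the number of subjects for
which it is significant, and the best candidate is freed *for everyone*
when that count reaches the grouping criterion — the smallest integer at or
above `criterion * n` (24 of 32 at the usual 75%).  Group paths are then
pruned when Wald-significant in fewer subjects than the same threshold.
Group parameters are freely estimated per subject throughout, so their
magnitudes and signs may vary across subjects.  Stage 2 runs the
individual-level search per subject with the group model as its protected
base: Wald trimming never touches group paths.

## A posteriori temporal-order validation

A fitted map's one-step-ahead prediction errors

$$\hat\zeta(t) = y(t) - \hat A y(t) - \textstyle\sum_q \hat\Phi_q y(t-q)
  - \sum_r \hat\gamma_r u(t-r) - \sum_{q,r} \hat\tau_{qr} y(t-q) u(t-r)$$

(first $a$ points dropped) should be white if the modeled order captured
all sequential dependencies.  The white-noise test fits a high-order
(default $L = 3$) VAR to $\hat\zeta$ by the same block-Toeplitz method and
tests the null that every lagged coefficient is zero: the implied
covariance is $I_{L+1} \otimes C$ with one free repeated contemporaneous
covariance $C$, giving $df = m(m+1)/2 - p(p+1)/2$ (72, 126 and 378 for
$p = 3, 4, 7$ at $L=3$) and a closed-form ML solution ($\hat C$ equals the
lag-0 block).  The test passes under the same 2-of-4 rule.  Its MI table
reports the LM statistic of each lagged residual dependency
(target, source, lag $1..L$).

When the test fails, the decision criteria choose a revision:

* **Option a** — when *a few* residual dependencies (at most
  `few_threshold`, default 3, an explicit policy knob since the notion is
  qualitative) are significant, the corresponding model parameters —
  residual dependency at lag $l$ from ROI $j$ to $k$ maps to
  $\Phi_l[k,j]$ — are freed in a confirmatory refit, raising the model
  order if needed.
* **Option b** — with more significant dependencies and no clear pattern,
  a data-driven search is run at the next order (from the group mask, for
  GIMME subjects, so the group-level structure is maintained).
* **Option c** — subdividing a long series suspected of task-related
  non-stationarity is available only as an explicit manual route
  (`validate_segments()` with `allow_subdivision = TRUE`); it is never
  auto-selected.

Escalation is stepwise: residual dependencies more than one lag above the
current order are disregarded until the intermediate order is in place.
The loop accepts when the residuals are white — after a final Wald trim
whose result is kept only if the trimmed model's residuals still pass —
and gives up when the order would exceed `max_order` (default 3) or a
previously visited specification recurs (a halting guarantee).

## The simulator

`simulate_usem()` iterates
$y(t) = (I-A)^{-1}(\sum_q \Phi_q y(t-q) + \zeta(t))$ with Gaussian
innovations (identity covariance by default), discards a 500-sample
burn-in (safely past mixing for spectral radii $\le 0.9$), and refuses
non-stationary specifications (reduced-form companion spectral radius
$\ge 1$).  Seeds pin the Mersenne-Twister/inversion RNG, so fixed seeds
give bit-reproducible series.

`scenario_3roi_lag2()` encodes the single-subject demonstration scenario:
3 ROIs, 200 time points, second order, identity innovations, six nonzero
coefficients — a first-order AR component per ROI, an additional
second-order AR component on ROI 3, a contemporaneous effect of ROI 3 on
ROI 1, and a lag-1 effect of ROI 1 on ROI 2.  The magnitudes (0.4 AR, 0.3
second-order AR, 0.5 contemporaneous, 0.4 cross-lag) are this package's
stationarity-checked defaults, chosen once as representative moderate
effects; they are exposed as arguments and never presented as estimates
from any empirical data set.

`simulate_group()` mirrors a typical resting-state configuration —
32 subjects, 4 ROIs, 160 time points — with a group structure of one
first-order AR connection per ROI plus a directed ring of four
contemporaneous connections, uniform $\pm 0.1$ between-subject coefficient
jitter (producing between-subject variation in magnitude while keeping
stationarity), one individual-level edge per subject, and one lag-2 AR
edge for a designated fraction of subjects (default 0.5, roughly the
prevalence at which higher-order dependencies appear in resting-state
samples; re-drawn up to 10 times per subject if a draw lands
non-stationary).  A machine-readable truth ledger accompanies the series
for scoring recovery.

What the generator emulates is the *statistical* structure these models
assume: linear contemporaneous-plus-lagged dynamics with Gaussian
innovations and exact stationarity.  Real BOLD data add measurement noise,
regional HRF variability, slow drifts, motion residue and non-Gaussian
artifacts, none of which are simulated; passing tests therefore certify
the estimator and search under the model's own assumptions, not robustness
to fMRI preprocessing imperfections.

## Numerical behavior and known limitations

* **Deflated null $\chi^2$.**  Because the block-Toeplitz matrix tiles
  each lagged moment into several positions of an overlapping embedding,
  the fitted $\chi^2$ is not exactly $\chi^2(df)$ distributed: under a
  true white-noise null with $p = 3$, $L = 3$ its mean is near
  $p^2 L(L+1)/2 = 54$ rather than the printed $df = 72$.  This is a
  property of the method itself (the printed df is the conventional moment
  count), and it makes the index-based test conservative: RMSEA and CFI
  pass easily near the null, and power against weak leftover dependencies
  (standardized residual correlations around 0.2 at $T = 200$) is
  moderate.  The acceptance suite measures exactly this: with the
  demonstration scenario's default magnitudes, the order-1 map's residuals
  fail the white-noise test in roughly 55--65% of replicates rather than
  nearly always; stronger generating coefficients push the rate toward 1.
* **SRMR at short $T$.**  Pure sampling noise puts SRMR near
  $1/\sqrt{T}$ ($\approx 0.07$ at $T = 200$, above its 0.05 threshold), so
  the SRMR vote is rarely decisive for white-noise tests at fMRI-typical
  lengths; the 2-of-4 rule absorbs this by design.
* **Small-sample bias.**  ML autoregressive estimates carry the classical
  downward small-sample bias; at $T = 200$ the per-parameter 95% CI
  coverage of the confirmatory true-structure fit sits between 0.89 and
  0.99 across parameters in our measurements.
* **Heywood cases** (innovation variances driven to zero) raise a warning;
  singular lagged covariances raise a warning and proceed; a singular
  $I - A$ (e.g. a strong reciprocal pair) reverts the offending step.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at deliberately modest sizes
chosen to exercise every code path with stable Monte-Carlo margins: 100
replicates of the 3-ROI/T=200 scenario for detection, escalation, recovery
and CI coverage; 200 + 200 replicates for white-noise calibration and
power; 50 random models for MI-vs-refit agreement; and 20 + 20 group
replicates of 10 subjects (4 ROIs, T = 160) for the prevalence of
order-2 subjects under 50% and 0% injected lag-2 edges.
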