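---
title: "Transductive semi-supervised regression for right-censored survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transductive semi-supervised regression for right-censored survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transurv)
```

## The problem

In survival cohorts most patients never reach the endpoint during follow-up.
A censored record $(U_i, x_i, \delta_i = 0)$ tells us only that the true
event time $T_i$ exceeds the observed time $U_i = \min(T_i, C_i)$; an event
record ($\delta_i = 1$) has $U_i = T_i$. Regression methods that treat $U_i$
as the target systematically underestimate survival for censored patients,
and with event rates of 3–20% — typical for post-prostatectomy endpoints —
the censored majority dominates the fit.

`transurv` treats each censored target as a *partially labeled* example
whose label is known to lie in $[U_i, T_{\max}]$, where
$T_{\max} = \max_i U_i$. For every censored record it searches candidate
target times in that interval, refits a base learner with only that one
target replaced, and keeps the candidate that maximizes a combined
ranking/classification criterion evaluated against the **original** observed
data. The transduced targets are then assembled into one training set and
the learner is refit once.

## The criterion

Model quality is scored by

$$\mathrm{Criterion} = \mathrm{CI} + \mathrm{Sensitivity} \times \mathrm{Specificity},$$

where CI is Harrell's concordance index (probability that of two comparable
patients the one with shorter survival receives the smaller
survival-oriented score; comparable pairs are $U_i < U_j$ with
$\delta_i = 1$, plus tied-time event/censored pairs) and
sensitivity/specificity come from stratifying the cohort at a fixed time
point $t$: events with $U \le t$ are the positive (high-risk) class, anyone
with $U > t$ is negative, and censored records with $U \le t$ are excluded
because their status at $t$ is unknown. A record is *predicted* positive
when its score falls below a threshold chosen on training data to maximize
sensitivity × specificity (midpoints of adjacent sorted unique scores;
ties break toward the smaller cutoff) and then frozen for validation. Both
terms live on a 0–1 accuracy scale, so the criterion ranges over $[0, 2]$.

Two conventions are worth stating explicitly because they are easy to get
backwards. Scores are always survival-time-oriented (larger = longer
predicted survival); the Cox learner therefore returns the *negated* linear
predictor. And the boundary convention at the stratification time point is:
an event exactly at $t$ is positive, a censored record exactly at $t$ is
excluded — this keeps the three classes exhaustive.

## Why the search must score against original times

The transduction search could trivially inflate its own criterion by
evaluating candidate fits against the very targets it is choosing. All
evaluation — during the search, for the final model, and on validation
sets — therefore uses the original $(U, \delta)$ only. Transduced times are
a training device, never an evaluation target. `report_evaluation()` and
`run_experiment()` enforce this: the only quantities ever reported are
computed from original times with a threshold frozen on training scores.

## Singular search

Optimizing all censored targets jointly over a grid of $m$ candidates each
costs $O(m^{n_c})$ fits, which is hopeless beyond a handful of censored
records. The implemented *singular* strategy searches each censored record
independently against the original dataset — selections never see each
other — for $O((m+1) \cdot n_c)$ fits, and refits once on the combined
selections. Because the unmodified time $U_i$ is always the first grid
candidate, the selected per-instance criterion can never fall below the
baseline; ties break toward the smallest candidate, i.e. the least
departure from the observed data. The joint refit on all selections is not
covered by that guarantee, so its training criterion is recorded
(`baseline_criterion` vs `final_criterion`) rather than asserted. A
sequential variant in which later searches see earlier selections would be
a possible extension; it breaks the independence that makes the cost linear
and is not implemented.

## Base learners

**Cox proportional hazards.** $h_i(t) = h_0(t)\exp(b^\top x_i)$, fit by
Newton–Raphson on the Breslow-tied partial likelihood to a gradient norm of
$10^{-8}$ (at most 100 iterations, with step halving). The baseline hazard
is deliberately not estimated: every downstream quantity (concordance,
thresholded stratification) depends only on the rank-preserving linear
predictor, from which $h_0$ cancels. Censored records enter risk sets up to
their censoring time only — which is also why transducing a censored time
changes a Cox fit at all. Monotone likelihood (perfect separation) is
detected when any coefficient passes 15 in magnitude; the fit warns and
caps rather than diverging. (On small separated fixtures the gradient
dips below tolerance near $|b| \approx 18$, so the cap must sit below
that.) No regularization by default; a ridge flag exists as an escape
hatch for separation pathologies, not a tuning device.

**SVRc.** Support vector regression whose slack penalty and
$\varepsilon$-tube differ by censoring status and residual side:

$$\min_{W,b}\ \tfrac12\lVert W\rVert^2 + \sum_i \left(C_i \xi_i + C_i^* \xi_i^*\right)$$

subject to $y_i - f(x_i) \le \varepsilon_i + \xi_i$ and
$f(x_i) - y_i \le \varepsilon_i^* + \xi_i^*$, with, for $s_i = 1 -
\delta_i$ (1 iff censored),
$C_i^* = s_i C_c^* + (1-s_i) C_n^*$ and
$\varepsilon_i^* = s_i \varepsilon_c^* + (1-s_i)\varepsilon_n^*$, and the
unstarred (lower-side) parameters completed symmetrically. A censored time
is a lower bound, so over-predicting it should be cheap: the defaults
($C_c^* = 0.2$ vs $C_n^* = 1$; $\varepsilon_c^* = 0.5\,\mathrm{sd}(y)$ vs
$0.1\,\mathrm{sd}(y)$ elsewhere) put a wide, lightly penalized tube above
censored targets, and the constructor warns when a configuration reverses
that regime. The default kernel is linear because the model's consumers
need one weight per feature; an RBF kernel is available but refuses
`feature_weights()`.

### Numerical notes on the QP

The dual is a quadratic program in $(\alpha, \alpha^*)$ with box
constraints $[0, C_i] \times [0, C_i^*]$ and one equality constraint. The
dual Hessian $\begin{pmatrix}K & -K\\ -K & K\end{pmatrix}$ is positive
semidefinite with rank at most that of $K$, so a tiny relative diagonal
jitter ($10^{-10}$ by default) is added. The primary solver is an
interior-point method (`kernlab::ipop`); when its inner Newton system goes
numerically singular — which happens occasionally among the thousands of
candidate fits a transduction run makes — an active-set fallback
(`quadprog`) is tried at escalating jitter ($10^{-6}$ to $10^{-3}$
relative) and the candidate with the best true (unjittered) dual objective
is kept. The intercept is recovered not from free support vectors (fragile
under jitter) but by exact minimization of the one-dimensional
piecewise-linear primal loss in $b$, taking the midpoint of the optimal
flat interval. Every fit certifies itself: the relative duality gap is
stored in the diagnostics and a warning is raised above $10^{-6}$.

Features are standardized on training data by default for SVRc (the
$C$/$\varepsilon$ scales are not scale-free) and not for Cox (whose
estimates are reparameterization-equivariant, so standardization only
changes the reporting scale; published clinical Cox weights are typically
on raw scales). Targets are fit on their original time scale; a
`log_time` flag exists for heavy-tailed cohorts.

## The synthetic two-endpoint generator

The clinical design this package targets trains on an early, noisy endpoint
(biochemical recurrence, event rate ~13–17%) and validates on both that
endpoint and a later, rarer clinical-failure endpoint (~3.5%) observed on
the same patients, with the key structural fact that every late-endpoint
event also experienced the early endpoint. The generator reproduces that
structure with explicit latent variables:

* covariates: i.i.d. standard normal (exchangeable; no attempt to imitate
  image-derived feature distributions);
* early event time: Weibull with shape $k$ and scale
  $\lambda\exp(-\beta^\top x/k)$, which makes the hazard exactly
  proportional, $h(t) = h_0(t)e^{\beta^\top x}$ — so Cox recovery on
  generated data is a clean calibration check;
* censoring: $C = \min(\mathrm{Unif}(0, c^*), \text{horizon})$,
  noninformative, with $c^*$ calibrated by bisection so the realized event
  rate hits the target within ±2 points (plus a $0.5/n$ allowance, since a
  cohort of $n$ records can only realize rates in steps of $1/n$);
* progression: among *true* early events, Bernoulli with probability
  $\mathrm{logit}^{-1}(0.3 + 0.6\,x_1)$; the late event time adds an
  independent Weibull(1.3, 45) gap. Both endpoints share each patient's
  censoring time, which is what guarantees nesting: an observed late event
  implies the (earlier) early event was also observed.

Defaults ($n = 340$, $d = 9$, 87% censoring, horizon 120, $\lambda = 250$,
$k = 1.5$) emulate the cohort profile above; across 50 seeds the mean
realized rates are ~13.2% early and ~3.6% late. The progression and gap
parameters were fixed once by simulation to land there and are documented
as illustrative, not calibrated to any clinical cohort — the paper-scale
studies are proprietary, and no covariate distributions or effect sizes
are published for them. Hidden truth (latent $T_i$, $C_i$, linear
predictor) is returned beside each dataset for oracle tests only; no
pipeline entry point reads it.

What passing tests on these cohorts shows — and what it does not: the
generator satisfies proportional hazards by construction and its features
are independent Gaussians, so it validates the machinery (estimation,
search, evaluation hygiene), not robustness to collinear ordinal clinical
covariates, informative censoring, or non-proportional hazards.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `grid_size` (m) | transduction | 10 | ~10 candidate increments per censored case; cost is linear in it |
| `time_point` | metrics/transduction | none (required) | the published experiments never state theirs; it is an explicit choice with units of the time column |
| `C_c_star` | SVRc | 0.2 | cheap over-prediction of censored targets |
| `eps_c_star` | SVRc | 0.5 sd(y) | wide upper tube for censored targets |
| `censor_rate_target` | generator | 0.87 | early event rate ~13% |
| `coef_cap` | Cox | 15 | separation detection threshold |

Other open choices resolved here: threshold selection is always on training
data (the published studies do not say; selecting on validation would leak);
times are stored as read with no unit conversion (all computations are
rankings or comparisons); missing covariates are rejected rather than
imputed (no imputation procedure is described for this design).

## Degenerate inputs and tie-breaks

* Datasets with zero events are rejected at construction (every fit needs
  an event); validation-only late-endpoint files can opt out.
* Stratification with an empty positive or negative class raises an error
  rather than returning 0.
* All-identical scores make threshold selection vacuous; it warns and
  returns the single value.
* Tied predicted scores earn concordance credit 0.5; tied event times are
  not comparable.
* Transduction tie-breaks go to the smallest candidate time; a censored
  record already at $T_{\max}$ has the single candidate $U_i$.
* Candidate fits that fail are skipped with a logged warning; only if all
  candidates fail does the instance error.

## Problem sizes

The shipped tests and acceptance checks run at deliberately modest scale:
oracle equivalence on fixtures of 5–15 records, transduction oracles at
$n \le 50$, a full SVRc transduction at $n = 120$ with 80% censoring and
$m = 10$ (roughly a thousand QP solves, about a minute), Cox parameter
recovery at $n = 2000$ over 20 seeds, and generator calibration over 50
seeds at $n = 340$. These sizes give stable statistics while keeping a full
run in minutes; all of them are configuration, not limits — the learners
and the search scale to cohorts in the thousands.

## Known limitations

* Only right censoring; no left truncation, interval censoring, or
  competing risks.
* No baseline-hazard estimate, hence no absolute survival-curve
  predictions from the Cox learner.
* No built-in hyperparameter search for SVRc; the defaults encode the
  censoring-aware regime, not a tuned operating point.
* The exhaustive joint search exists only as a test oracle (one censored
  record); it is intentionally not a user-facing mode.
* Weight normalization conventions differ across published tables; the
  max-absolute rule is the default, with `method = "max"` and
  `reference_feature=` as explicit alternatives.
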