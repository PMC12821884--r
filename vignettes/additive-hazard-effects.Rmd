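---
title: "Parametric additive hazards and time-constant absolute effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric additive hazards and time-constant absolute effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahazpar)
```

## The model and its assumptions

`ahazpar` fits the additive hazard model

$$h_x(t) = h_0(t) + x\beta$$

for a two-arm trial with binary treatment indicator $x$, a parametric
baseline hazard $h_0(t;\theta)$, and a treatment coefficient $\beta$
that does not depend on time. The derived distributional quantities
are

$$S_x(t) = S_0(t)\,e^{-tx\beta}, \qquad
  f_x(t) = \{h_0(t) + x\beta\}\,S_x(t),$$

so the log-likelihood over subjects $(t_i, \delta_i, x_i)$ with
$\delta_i = 1$ for an observed event is the standard parametric
survival likelihood — events contribute $\log f_{x_i}(t_i)$, censored
observations $\log S_{x_i}(t_i)$:

$$\ell(\theta,\beta)
  = \sum_i \delta_i \log\{h_0(t_i) + x_i\beta\}
  - H_0(t_i) - t_i x_i \beta .$$

The model's key assumption is *additivity*: the treated-arm hazard is
the control-arm hazard shifted by a constant. Under it, $\beta$ is a
time-constant hazard difference (events per person-year) and $1/\beta$
an NNT in *person-years of treatment*, which addresses the
time-dependence that makes Kaplan-Meier-based NNTs horizon-specific.
Additivity is an assumption like proportionality is for Cox models; the
package supports checking it informally by overlaying fitted curves on
life-table hazards and Kaplan-Meier estimates (`plot.ahaz_fit`). No
formal goodness-of-fit test is provided: such tests conflate sample
size with deviation size, are not specific to the additivity
alternative, and invert the logical role of the null hypothesis.

Right censoring is assumed independent; delayed entry, interval
censoring and competing risks are out of scope (all-cause mortality
avoids the latter). The likelihood code accepts only the single binary
covariate of an RCT arm.

## Baseline families

Seven families are supported, each with closed-form cumulative hazard
$H_0$ (so $S_0 = e^{-H_0}$ is exact, never quadrature):
exponential ($\lambda$), linear hazard rate ($a + bt$), Weibull
(shape/scale), log-logistic (shape/scale with
$S_0 = 1/\{1 + (t/\alpha)^s\}$), Gompertz ($ae^{bt}$, $b$ of either
sign), Gamma-Gompertz, and piecewise-constant hazards on fixed
cutpoints.

Two parameterization choices deserve note:

* **Gamma-Gompertz.** A Gompertz individual hazard $ae^{bt}$ with
  multiplicative gamma frailty (mean 1, variance $\sigma^2$)
  integrated out gives the population hazard
  $h_0(t) = ae^{bt} / \{1 + (\sigma^2 a/b)(e^{bt}-1)\}$. Other
  parameterizations of the same three-parameter family exist; effect
  measures are insensitive to the choice because the fitted
  $\sigma^2$ collapses toward 0 on data that look Gompertz (the family
  then degenerates to the Gompertz, which the fitter handles by the
  $\sigma^2 > 0$ boundary on the log scale), but the reported *mode*
  of a genuinely frailty-driven fit would depend on it.
* **LHR slope.** The baseline slope $b$ is kept $\ge 0$ (log
  transform). For mortality-type outcomes the baseline hazard should
  be nondecreasing, and the closed-form mode expressions assume
  $b > 0$; decreasing *treated* hazards remain representable through
  negative $\beta$. The exponential is the $b \to 0$ boundary.

Modes are closed-form where textbook expressions exist (exponential: 0
by definition; LHR $(\sqrt b - a)/b$; Weibull
$\lambda\{(k-1)/k\}^{1/k}$; log-logistic
$\alpha\{(s-1)/(s+1)\}^{1/s}$; Gompertz $\ln(b/a)/b$, each truncated
at 0); the Gamma-Gompertz and piecewise modes are found numerically by
a 1,000-point grid bracket plus local refinement to $10^{-6}$ years on
$[0,\,3\times$ observed follow-up$]$ (standalone families default the
search bound to the time where $S_0 < 10^{-4}$).

## Estimation and numerics

Optimization runs on an unconstrained scale: $\log$ for strictly
positive parameters, identity for the Gompertz slope and for $\beta$.
Starting values are deterministic occurrence/exposure quantities: the
control-arm rate seeds the baseline level, the between-arm rate
difference seeds $\beta$ (for the piecewise family, per-piece
control-arm rates seed the heights). Nelder-Mead (relative tolerance
$10^{-9}$) runs from this start plus five Gaussian-jittered restarts
(SD 0.3 on the unconstrained scale, locally seeded), each polished by
BFGS and accepted only if it improves; the likelihood returns $-\infty$
at infeasible points (non-positive treated hazard at an event time, or
negative cumulative treated hazard, which would mean $S_x > 1$), which
Nelder-Mead treats as a rejected move — a domain-honest alternative to
penalties. Restarts matter mainly for the three-parameter and
piecewise fits; `recovery_study()` uses the deterministic start alone,
which suffices for well-identified two-parameter designs.

The covariance is the inverse negative Hessian at the optimum (central
differences, step $10^{-5}$, on the unconstrained scale), mapped to the
natural scale by the delta method; `converged` is honest — it requires
optimizer convergence *and* a usable positive-definite Hessian. BIC
uses the number of **subjects** as $n$: with ~93% censoring the
subject count and event count differ by an order of magnitude, and the
subject count is the sample size of the likelihood actually maximized.

Pointwise 95% bands for fitted curves are delta-method intervals on
the $\log$ scale (hazard, density) or $\mathrm{cloglog}$ scale
(survival), so bands respect positivity and $S \le 1$; $S(0)=1$ has a
degenerate $[1,1]$ interval. Predictions beyond $1.5\times$ the
observed follow-up are flagged as extrapolation.

## Effect measures and their intervals

* `rate_difference()`: $\text{scale}\cdot\hat\beta$ with a symmetric
  Wald interval, default per 1,000 person-years.
* `nnt()`: $1/\hat\beta$ with the delta-method standard error
  $SE(\hat\beta)/\hat\beta^2$ for parametric fits. For the Lin-Ying
  fit the interval instead inverts the endpoints of the $\beta$
  interval; both conventions appear in practice, so the method is
  recorded in the result and selectable. The units are person-years —
  deliberately distinct from the dimensionless `km_nnt()`, whose
  "patients at a horizon" reading answers a different question.
* `mode_estimate()` / `mode_difference_lhr()`: delta-method intervals
  with numerical gradients of the mode map (step $10^{-4}$, large
  relative to the $10^{-8}$ mode-refinement tolerance so the gradient
  is not corrupted by optimization noise). Mode intervals are built on
  the untransformed scale and may cross zero; the exponential mode is
  a degenerate 0 with no interval.

## The Lin-Ying comparison estimator

`fit_linying()` solves the semiparametric estimating equation for a
single binary covariate; both integrals reduce to exact finite sums
over distinct observed times, ties contributing jointly. The sandwich
variance $\hat B/\hat A^2$ uses the observed-event empirical variance
$\hat B = \sum_{\text{events}}\{x_i - \bar x(t_i)\}^2$. The estimator
targets the same constant hazard difference without a baseline model —
a useful robustness check — but yields no likelihood, hence no
-2LogL/BIC row in `ahaz_model_table()`.

## What the simulator emulates — and what it does not

`simulation_design()` + `simulate_trial()` generate exactly the model:
inverse-transform event times from $S_0(t)e^{-t\beta x}$ (closed-form
inversion for exponential/LHR and for Weibull/Gompertz at $\beta = 0$;
otherwise monotone bisection to $10^{-10}$), censoring as an
administrative cut-off minus a uniform accrual offset. The shipped
`empareg_like_design()` — LHR $a = 0.021$, $b = 0.004$,
$\beta = -0.009$/PY, 2,333 vs 4,687 subjects, 4.6 years administrative
censoring with 1.5 years accrual — mirrors a large cardiovascular
outcome trial of all-cause mortality: event-sparse (~92-94%
censoring), unbalanced 1:2 randomization, staggered entry.

Simulated data are *exactly* additive-hazard with exactly independent
censoring. Passing recovery and coverage tests on them validates the
estimation machinery (likelihood, optimizer, Hessian-based intervals),
not the additivity assumption on any real trial; nor do they emulate
features of reconstructed registry/trial data such as digitization
rounding, tied event clusters from published risk tables, or
covariate-dependent censoring. Improper designs (total hazard with a
finite limit, e.g. Gompertz with $b < 0$) are legal: never-failing
subjects are censored administratively, with a warning.

## Problem sizes and reproducibility

Simulation-based tests and the acceptance script use full trial-scale
datasets (7,020 subjects) for single fits and for the calibration
studies (100-200 replicates at trial scale for coverage of $\beta$;
$10^5$ subjects per arm for distributional checks of the sampler) —
sizes chosen so Monte-Carlo error is well below the tolerances
asserted, while a complete run stays at the minutes scale on one CPU.
All randomness flows through explicit seeds; `simulate_trial()`
restores the caller's RNG state, and replicate seeds are derived
deterministically from the design seed.

## Known limitations

* One binary covariate; no adjustment covariates, no multi-arm trials.
* No left truncation, interval censoring, competing risks, or cure
  models (beyond censoring improper tails).
* Piecewise cutpoints are fixed by configuration, not estimated; the
  default grids place cuts every 12/6/3 months across the whole years
  of follow-up with an open-ended final piece.
* Delta-method intervals for reciprocals ($1/\beta$) and modes are
  first-order; they can misbehave when $\hat\beta$ is near 0 (the NNT
  is then ill-defined anyway) or when a mode sits at the boundary 0.
* The BIC comparison spans the likelihood-based rows only; the
  Lin-Ying estimator is excluded by construction.
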