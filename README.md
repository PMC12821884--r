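# ahazpar

Parametric additive hazard models for **time-constant absolute
treatment effects** in two-arm time-to-event trials.

## The problem

Randomized trials with time-to-event outcomes usually report relative
effects (hazard ratios). Absolute effect measures — risk differences,
numbers needed to treat (NNT) — are what patients and policy makers
need, but for survival outcomes they are generally *time-dependent*:
an NNT computed from Kaplan-Meier risk differences changes with the
horizon at which it is read off, which hampers communication. In
event-sparse settings such as cardiovascular outcome trials of
antidiabetic drugs (censoring above 90%), the gap between an
impressive hazard ratio and a modest absolute effect is especially
wide.

An additive hazard model resolves the time-dependence: if the hazard
of a subject with treatment indicator x is

    h_x(t) = h0(t) + x * beta,

then `beta` is a *time-constant* hazard difference (units: events per
person-year), and its reciprocal `1/beta` is an NNT in units of
**person-years of treatment per event prevented** — not a number of
patients. `ahazpar` implements this model class with fully parametric
baseline hazards h0(t; theta) estimated jointly with beta by maximum
likelihood:

| family          | h0(t)                                      | parameters |
|-----------------|--------------------------------------------|------------|
| `exponential`   | lambda                                     | 1          |
| `lhr`           | a + b t                                    | 2          |
| `weibull`       | (k/s)(t/s)^(k-1)                           | 2          |
| `loglogistic`   | from S0 = 1/(1 + (t/s)^k)                  | 2          |
| `gompertz`      | a e^(b t)                                  | 2          |
| `gammagompertz` | Gompertz with gamma frailty integrated out | 3          |
| `piecewise`     | lambda_k on fixed intervals                | K          |

An event at t contributes log f_x(t), a censored observation
log S_x(t), with `S_x(t) = S0(t) exp(-t x beta)` and
`f_x(t) = (h0(t) + x beta) S_x(t)`. Families are compared by BIC
(`-2LogL + p ln(n)`, n = subjects). Beyond the rate difference and
person-years NNT the package reports the *mode* of each fitted
event-time distribution (an interpretable location summary) and, for
the linear-hazard-rate family, the closed-form between-arm mode
difference `-beta/b` — the delay of the most probable event time under
treatment. The semiparametric Lin-Ying estimator, actuarial life-table
hazards and KM-based time-dependent NNTs are included for comparison
and diagnostics, and a trial simulator generates two-arm
additive-hazard data with administrative-plus-accrual censoring.

## Worked example

Simulate a trial shaped like a large cardiovascular outcome trial of
all-cause mortality (linear hazard rate baseline a = 0.021,
b = 0.004, hazard shift beta = -0.009/PY, 2,333 control vs 4,687
treated subjects, administrative censoring at 4.6 years with 1.5 years
of accrual, ~92% censoring), then fit and summarize:

```r
library(ahazpar)
ds  <- simulate_trial(empareg_like_design(seed = 42))
fit <- ahaz_fit(ds, "lhr")
fit
#> Additive hazard model, lhr baseline (7020 subjects, 2 + 1 params)
#> baseline parameters (natural scale):
#>      estimate           se
#> a 0.020801773 0.0022990276
#> b 0.004013011 0.0007651243
#> hazard difference: -0.009428 per person-year (rate difference -9.4 [-13.5; -5.3] per 1,000 PY)
#> -2LogL = 5506.4   BIC = 5533.0   converged: TRUE

nnt(fit)
#> -106.1 [95%-CI: -152.1; -60.06] person-years (delta-method)
mode_estimate(fit, arm = 0)
#> 10.6 [95%-CI: 9.657; 11.55] years (delta-method)
mode_difference_lhr(fit)
#> 2.349 [95%-CI: 0.9399; 3.759] years (delta-method)
```

Read: treating 1,000 patients for one year prevents about 9.4 deaths
(equivalently, about 106 person-years of treatment prevent one death),
and the most probable time of death is delayed by about 2.3 years —
all close to the generating values (-9 per 1,000 PY; -beta/b =
2.25 y). `ahaz_model_table(ds)` fits the whole panel (six parametric
families, Lin-Ying, piecewise-constant hazards with 12/6/3-month
pieces) and flags the BIC-best model; `plot(fit, ds)` overlays fitted
hazard/survival/density bands on life-table and Kaplan-Meier
estimates. A thin command-line wrapper with the same workflow lives at
`inst/cli/ahazpar.R` (subcommands `fit`, `table1`, `plots`,
`simulate`, `recover`).

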