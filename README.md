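# bacens

Bayesian imputation of right-censored survival times under Weibull and
Birnbaum–Saunders lifetime models.

## What it does, and for whom

Almost every clinical or epidemiological time-to-event dataset is
right-censored: for some subjects only a lower bound `c` on the event time
is known.  Analysts who need a *complete* dataset — for descriptive
curves, for downstream methods that cannot handle censoring, or to study
how much information the censored records carry — need a principled way to
fill those times in.

`bacens` replaces each censored time by a summary (median by default, or
mean) of draws from the posterior-predictive conditional distribution of
the lifetime,

```
f(t | T >= c, D) = ∫ f(t | T >= c, θ) p(θ | D) dθ,
f(t | T >= c, θ) = f(t | θ) / S(c | θ),   t >= c,
```

so every imputed value respects its censoring bound and carries full
posterior parameter uncertainty.  Two lifetime families are built in:

* **Weibull** in the proportional-hazards rate form
  `S(t) = exp(-β t^α)`, with the AFT scale `β^(-1/α)` available for
  software that uses the other convention;
* **Birnbaum–Saunders (fatigue-life)** with shape `γ` and scale `δ`,
  computed throughout via its normal transform
  `Z = (1/γ)(√(T/δ) - √(δ/T)) ~ N(0,1)`; its median equals `δ` exactly.

Around that core the package provides the censored-data likelihood with
gamma/normal priors and a self-contained adaptive random-walk Metropolis
sampler (mode-initialised, curvature-preconditioned, adaptation frozen
after burn-in; exactly 10,000 retained draws under the default protocol),
calibration of an exponential censoring rate to a nominal censoring
fraction, a 27-scenario simulation grid per family, MCMC diagnostics
(Geweke z, effective sample size, autocorrelation, DIC with the classic
`p_D`), Kaplan–Meier comparison curves (original / omit-censored /
imputation-augmented), ggplot2 `autoplot()` methods, and a small CLI.

## Worked example

```r
library(bacens)

# one cell of the simulation design: Weibull shape 2, n = 200,
# exponential censoring at the 20%-nominal working rate
d <- simulate_scenario("weibull", shape = 2, n = 200, theta = 0.06,
                       b1 = -3, b2 = 0.3, seed = 7)
mean(d$status == 0)
#> [1] 0.215

fit <- fit_survival_bayes(d, "weibull", control = mcmc_control(seed = 7))
tidy(fit)
#> # A tibble: 3 × 6
#>   term  estimate median std.error conf.low conf.high
#> 1 shape    2.24   2.24      0.135   1.98       2.51
#> 2 b1      -3.37  -3.37      0.249  -3.86      -2.88
#> 3 b2       0.334  0.332     0.162   0.0170     0.655
```

The posterior recovers the generating values (shape 2, b1 = −3,
b2 = 0.3) within its 95% intervals.  Chain quality, at the default
10,000-retained-draw protocol:

```r
diagnose(fit)
#> # A tibble: 3 × 7
#>   term  geweke_z   ess acf_lag1 acf_lag10 geweke_ok ess_ok
#> 1 shape   0.0654 6927.    0.127  -0.00363 TRUE      TRUE
#> 2 b1     -0.133  6424.    0.137  -0.00208 TRUE      TRUE
#> 3 b2      1.18   7030.    0.158   0.00353 TRUE      TRUE
```

Every chain clears the working thresholds (|z| ≤ 2, ESS ≥ 1000).
Imputation draws 10,000 truncated samples per censored record — one per
retained posterior draw — and summarises them:

```r
imp <- impute_censored(d, fit, summary = "median", seed = 7)
imp$summaries
#> # A tibble: 43 × 6
#>     row  time     x draw_mean draw_median imputed
#> 1     3 1.38      0      4.21        3.99    3.99
#> 2     9 0.206     0      3.99        3.82    3.82
#> 3    14 3.27      0      5.14        4.84    4.84
#> ...
```

Every imputed value sits above its censoring time.  The three comparison
curves (and per-censor draw bands) come from `curve_set(d, imp)` and plot
with `autoplot()`; model choice between families uses `glance(fit)$dic`
(lower is better).  Calibrating a censoring rate to a 20% target for this
scenario:

```r
calibrate_theta(0.2, event_mixture("weibull", 2, b1 = -3, b2 = 0.3))
#> [1] 0.06234676
```

— close to the bundled two-decimal working value 0.06.

## Command-line interface

A thin wrapper over the same functions lives in `inst/cli/bacens.R`:

```sh
Rscript inst/cli/bacens.R impute    --input data.csv --family bs --out-dir out/
Rscript inst/cli/bacens.R simulate  --family weibull --shape 2 --n 200 --p 0.2
Rscript inst/cli/bacens.R study     --family weibull --out-dir study/
Rscript inst/cli/bacens.R calibrate --family weibull --shape 1 --p 0.5
Rscript inst/cli/bacens.R diagnose  --chains out/chains.csv --family weibull
```

Outputs are plain text: augmented CSV, chains CSV, curves TSV,
diagnostics JSON, config echo YAML.

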