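# doublecox

Parametric survival regression for clustered right-censored data in
which the hazards are **not** proportional across strata, with a
cluster-shared gamma frailty.

## The model

The classical parametric proportional-hazards model attaches a single
Cox-regression term to the *scale* of a Weibull or Gompertz baseline
hazard. When hazard shapes differ across strata, `doublecox` adds a
second, separate Cox term on the *shape* parameter,
`b(u) = b·exp(β_shape·u)` — the **double-Cox** model. Given a
cluster-shared frailty `Z` with mean 1 and variance `σ²`, the
conditional cumulative hazards are

    Weibull:  H̃(t|u,Z) = Z · exp(β_scale·u) · t^B / a
    Gompertz: H̃(t|u,Z) = Z · a · exp(β_scale·u) · (e^{Bt} − 1) / B

with effective shape `B = b·exp(β_shape·u)`. The gamma frailty
integrates out in closed form, giving the marginal survival
`S(t|u) = (1 + σ²H)^(−1/σ²)` and a closed-form marginal likelihood that
the package maximizes directly (with an analytic score) or by EM.

Inference accounts for the boundary at `σ² = 0`:

* **Wald** intervals from the inverse observed information
  (log scale for `a`, `b`);
* a **truncated-normal / point-mass mixture** interval for the frailty
  variance, valid at and near its boundary;
* **profile-likelihood** intervals inverting `2Δl ≤ 3.84`, the
  recommended default.

A simulation layer generates clustered data from the model (covariates,
shared frailty, inverse-hazard event times, uniform censoring with a
Monte-Carlo-calibrated rate) and runs bias / coverage study grids.

## A worked example

```r
library(doublecox)

sp  <- dcox_spec("gompertz", scale = c("success", "score"),
                 shape = c("success", "score"))
cfg <- dcox_sim_config("gompertz",
  dcox_params(1e-4, 0.1, beta_scale = c(0.5, 1),
              beta_shape = c(0.05, 0.1), sigma2 = 1),
  n = 2000, n_clusters = 100, p_cens = 0.4)
dat <- dcox_simulate(cfg, seed = 42)   # tibble: time, status, cluster, success, score
fit <- dcox_fit(dat, sp)
fit
#> Double-Cox gompertz frailty model (direct ML)
#>   n = 2000, clusters = 100, events = 1198
#>   logLik = -4918.4984
#>             a             b scale_success   scale_score shape_success
#>     9.252e-05     1.020e-01     7.143e-01     9.461e-01    -9.903e-03
#>   shape_score        sigma2
#>     1.021e-01     8.308e-01
```

The estimates sit near the generating truth
(`a = 1e-4, b = 0.1, β_scale = (0.5, 1), β_shape = (0.05, 0.1), σ² = 1`);
with 1198 events the shape coefficients are the noisiest, as expected.
`tidy()` attaches intervals — Wald for the regression and baseline
parameters, the boundary mixture for `σ²`:

```r
tidy(fit, conf.int = TRUE)
#> # A tibble: 7 × 6
#>   term            estimate std.error   conf.low conf.high conf.method
#>   <chr>              <dbl>     <dbl>      <dbl>     <dbl> <chr>
#> 1 a              0.0000925 0.0000166  0.0000650  0.000132 wald
#> 2 b              0.102     0.00256    0.0971     0.107    wald
#> 3 scale_success  0.714     0.249      0.226      1.20     wald
#> 4 scale_score    0.946     0.251      0.453      1.44     wald
#> 5 shape_success -0.00990   0.0397    -0.0876     0.0678   wald
#> 6 shape_score    0.102     0.0382     0.0272     0.177    wald
#> 7 sigma2         0.831     0.120      0.596      1.07     boundary_mixture
```

Profile intervals: `confint(fit, method = "profile")` or
`tidy(fit, conf.int = TRUE, conf.method = "profile")`. Marginal survival
curves: `autoplot(fit)`. The baseline truth above implies a mean
survival time of

```r
dcox_life_expectancy(dcox_spec("gompertz"), dcox_params(1e-4, 0.1, sigma2 = 1))
#> [1] 69.1467
```

(69.1 years — a human-longevity-scale baseline; the Weibull counterpart
`a = 20, b = 1.5, σ² = 1` gives 17.8, a device-lifetime scale).

Study grids:

```r
sc  <- dcox_study_config(cfg, replications = 300, seed = 1)
res <- dcox_run_bias_study(sc)      # per-parameter mean, bias, SD, MC-SE
dcox_study_table(res)               # long-format table for export
autoplot(res)
```

A command-line front end with `fit`, `simulate`, `study` and `lifeexp`
subcommands is installed at `inst/cli/doublecox.R`
(`Rscript <path> fit --family gompertz --data data.csv ...`).

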