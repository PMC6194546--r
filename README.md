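# cigtaxsim

Tools for appraising cigarette excise tax policy in low- and middle-income
countries. The package implements a two-stage analysis:

1. **Elasticity estimation.** The price elasticity of cigarette demand is
   estimated from a country-year panel with the log-log demand model

   ```
   ln C_it = β_1i + β₂ ln P_it + β₃ ln GNI_it + β₄ FCTC_it + ε_it
   ```

   where `C_it` is annual per-capita cigarette consumption (aged 15+),
   `P_it` the real retail price per 20-pack (US$), `GNI_it` real GNI per
   capita, and `FCTC_it` a 0/1 indicator of WHO Framework Convention on
   Tobacco Control ratification. Country intercepts `β_1i` are absorbed by
   the within transformation; price is treated as endogenous and
   instrumented with its own lag and the lagged consumer price index
   (fixed-effects two-stage least squares). Inference is cluster-robust by
   country (CR1 small-sample correction), and each fit carries a Hausman
   fixed-vs-random effects test, a cluster-robust first-stage
   (Kleibergen–Paap-type) weak-identification F, and the within R².
   Because price responsiveness varies with income, estimation runs
   separately within six income clusters cut on 2015 GNI per capita at
   US$1000 / 2000 / 3000 / 4000 / 6000.

2. **Policy simulation.** A deterministic comparative-static chain converts
   a fractional real-price increase `dP` (the mean or maximum historical
   annual increment) into:

   - consumption change `dC = β₂ · dP` (linear in the increment),
   - excise revenue change `dRev = ((τ + dP)/τ)(1 + dC) − 1`, with `τ` the
     total excise share of the retail price (specific + ad valorem); the
     whole increment is treated as new specific excise, and countries with
     no excise have an undefined revenue baseline,
   - smoker reduction `= prevalence × pop15+ × |dC|` (all of the decline on
     the quitting margin),
   - averted smoking-attributable deaths `= smoker reduction × MAF`, where
     the mortality adjustment factor combines the age mix of quitters with
     age-specific risk-avoidance fractions (95/75/70/50/10% for ages 15–29,
     30–39, 40–49, 50–59, 60+) and a baseline smoker death risk of 0.5.

The package bundles hand-transcribed inputs for 22 Asia-Pacific low- and
middle-income countries (excise structure, prevalence, per-income-group
elasticities, historical price increments) together with the published
simulation results as a benchmark, a synthetic panel generator with known
ground truth for validating the estimator, and an end-to-end pipeline.

## Worked example

Simulating the bundled Asia-Pacific countries under their historical mean
and maximum annual price increments:

```r
library(cigtaxsim)
inputs <- apac_country_inputs()
out <- simulate_policy(inputs, apac_country_elasticities(),
                       apac_price_scenarios())
subset(out, country == "China")
#>    country kind     dP      dC dRevenue smoker_reduction    maf sads_averted
#> 21   China mean 0.0945 -0.1232  0.15388         43152200 0.3716     16035358
#> 43   China  max 0.5096 -0.6645 -0.09274        232702234 0.3716     86472153
```

A mean annual price rise of 9.45% cuts Chinese per-capita consumption by
12.32% (elasticity −1.304), raises excise revenue by 15.4%, and averts
about 16.0 million smoking-attributable deaths among 43.2 million quitters
(MAF 0.372). Under the maximum increment (50.96%) consumption falls by
66.45% and revenue *declines* by 9.3% — the volume loss outruns the higher
per-pack take. Regionally:

```r
aggregate_region(out)
#>   kind      dP       dC dRevenue smoker_reduction sads_averted n_countries
#> 1  max 0.29650 -0.10591   0.7855        248426726     91355376          22
#> 2 mean 0.09508 -0.03196   0.2893         49349462     17964160          22
```

Estimating elasticities on a synthetic panel with known truth
(β₂ = −1.304):

```r
pan <- generate_panel(panel_dgp_params(seed = 1))
fit_fe_2sls(pan)
#> Fixed-effects 2SLS cigarette demand fit
#>          estimate     se sig
#> ln price  -1.2571 0.0287  **
#> ln GNI     0.7678 0.0201  **
#> FCTC      -0.1065 0.0067  **
#> within R^2 = 0.938; weak-id F = 242.45; Hausman chi^2(3) = 1.67 (p = 0.643) [indefinite covariance]
#> n = 352 observations, 22 countries
```

The full pipeline (`synth/load → estimate → simulate → report`) is driven
by `run_pipeline(run_config(...))` or a YAML file via `load_run_config()`;
artifacts are a fit JSON, a simulation CSV and a markdown report.

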