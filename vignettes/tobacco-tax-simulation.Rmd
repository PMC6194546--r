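---
title: "Cigarette demand elasticities and excise tax simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cigarette demand elasticities and excise tax simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cigtaxsim)
```

## The demand model

Cigarette demand is modelled in logs on a country-year panel:

$$\ln C_{it} = \beta_{1i} + \beta_2 \ln P_{it} + \beta_3 \ln GNI_{it}
  + \beta_4\, FCTC_{it} + \varepsilon_{it}$$

`C` is annual per-capita consumption among those aged 15+, `P` the real
retail price of a 20-pack in US$, `GNI` real GNI per capita in US$, and
`FCTC` a 0/1 ratification indicator. $\beta_2$ is the price elasticity of
demand and the quantity the whole package revolves around; $\beta_{1i}$ are
country intercepts capturing time-invariant heterogeneity (consumption
culture, market structure).

Three econometric concerns shape the estimator:

* **Correlated heterogeneity.** Country intercepts are absorbed by the
  within transformation (subtracting country means). A Hausman test
  comparing the within estimator with random-effects GLS checks whether the
  cheaper random-effects assumption would have been tenable; rejection
  means the fixed-effects estimates should be used.
* **Price endogeneity.** Retail prices respond to demand conditions, so
  log price is instrumented with its own one-year lag and the lagged log
  consumer price index, by two-stage least squares on the
  within-transformed data (`fit_fe_2sls()`). The first observation of each
  country is lost to lagging. Instrument relevance is checked with a
  cluster-robust Wald F of the two excluded instruments in the
  within-transformed first stage; with one endogenous regressor this equals
  the Kleibergen–Paap rk Wald F. A plain within estimator is available with
  `iv = FALSE`.
* **Serial dependence.** Errors within a country are arbitrarily
  correlated over years, so the covariance of the slopes is cluster-robust
  by country with the CR1 small-sample factor
  $\frac{G}{G-1}\,\frac{N-1}{N-k}$, where $G$ is the number of countries
  and $k$ counts the three slopes plus the absorbed country intercepts
  (the same convention as cluster-robust LSDV, which the tests verify
  against an independent sandwich-estimator oracle). CR0/CR2 variants are
  not offered.

Because price responsiveness varies with income, estimation runs separately
in six income clusters cut on reference-year (2015) GNI per capita at the
fixed thresholds US$1000 / 2000 / 3000 / 4000 / 6000, the boundary value
falling in the upper group (`assign_income_clusters()`).

### Estimator details and degenerate inputs

* The Hausman statistic is
  $H = d^\top (V_{FE} - V_{RE})^{-1} d$, $d = b_{FE} - b_{RE}$, over the
  three slopes (df = 3), computed from the non-IV within estimator and the
  Swamy–Arora random-effects GLS on the same unlagged sample, each with its
  conventional covariance. When $V_{FE} - V_{RE}$ is not positive definite
  the Moore–Penrose pseudo-inverse is used and the result is flagged
  `indefinite = TRUE` — reported, never hidden.
* Random-effects GLS uses Swamy–Arora variance components: the
  idiosyncratic variance from the within residuals
  ($\hat\sigma^2_e$, df $N - G - k$), the intercept variance from the
  between regression truncated at zero with a warning if negative, and
  quasi-demeaning with
  $\theta_i = 1 - \sqrt{\hat\sigma^2_e / (T_i \hat\sigma^2_u + \hat\sigma^2_e)}$.
  With zero idiosyncratic variance $\theta = 1$ and the quasi-demeaned
  intercept column vanishes; the GLS solve uses pivoted QR so the aliased
  intercept is dropped rather than crashing, and the slopes equal the
  fixed-effects slopes, the correct limit.
* The weak-identification F is capped at $10^6$ when the first stage fits
  perfectly (e.g. an instrument equal to the regressor), where the Wald
  form would divide by a zero residual variance.
* Countries reduced to a single observation (after lagging) carry no within
  variation and are dropped with a warning; estimation with fewer than two
  countries is refused because clustering is meaningless. Rank-deficient
  designs (for instance an FCTC dummy that never switches within the
  sample) raise an error naming the collinear column.
* The reported R² is the within R² of the second stage, computed from the
  structural residuals.

## The policy simulator

The simulator is a one-shot comparative static around the latest observed
year; there is no multi-year cohort projection, illicit-trade margin or
product substitution. For a fractional real-price increase $dP$ (taken from
the mean or maximum historical annual increment of each country's price
series, `historical_increments()`):

* **Consumption**: $dC = \beta_2 \, dP$. The response is linear in the
  increment, not the constant-elasticity power form
  $(1+dP)^{\beta_2} - 1$: the linear form is the accounting convention the
  bundled published benchmark follows, and the acceptance tests confirm it
  reproduces that benchmark to the printed precision while the power form
  does not.
* **Revenue**: with $\tau$ the total excise share of the retail price
  (specific plus ad valorem, as published),
  $dRev = \frac{\tau + dP}{\tau}(1 + dC) - 1$. The entire price increment
  is treated as new specific excise and ad valorem taxes are not re-applied
  to the new price; this is the accounting that matches the benchmark
  revenue column cell-by-cell. Three countries' published shares are
  rounded coarsely enough that reproduction is only near-exact there — the
  discrepancy is documented in the tests, not absorbed. Countries with zero
  or missing excise have no revenue baseline; the change is undefined
  (`NA`, rendered "-"), never zero.
* **Smokers**: the whole consumption decline is attributed to quitting
  (the prevalence margin), so
  $\Delta\text{smokers} = \text{prevalence} \times \text{pop15+} \times |dC|$.
  This attribution is required for the averted-death arithmetic below to
  apply.
* **Averted deaths**: $\Delta SAD = \Delta\text{smokers} \times MAF$, with
  the mortality adjustment factor
  $MAF = r \sum_b s_b w_b$ over five age bands: $s_b$ the age shares of
  quitters, $w_b = (0.95, 0.75, 0.70, 0.50, 0.10)$ the fractions of
  quitters aged 15–29, 30–39, 40–49, 50–59, 60+ who escape their former
  habit's mortality, and $r = 0.5$ the baseline probability that a
  continuing smoker dies of smoking. The 0.5 default follows the
  attributable-death convention of the tobacco-control literature; it is
  consistent with the implied factors in the bundled benchmark
  (all between 0.25 and 0.38, necessarily $\le r$). $MAF \le r$ and
  $\Delta SAD \le \Delta\text{smokers}$ always.

All quantities are computed at full precision; percentages are multiplied
by 100 and rounded to two decimals only in the reporting layer, and person
counts are rounded to whole persons only at the averted-death step.

### Open choices, decided

* **Mean increments** average *all* year-over-year changes by default;
  whether declines should be excluded is genuinely ambiguous, so a
  `positive_only` flag is provided (the positive-only mean is never smaller,
  a property the tests check). Changes are computed only across consecutive
  calendar years; gaps contribute nothing.
* **Regional aggregation** of rates is the unweighted country mean by
  default, which reproduces the benchmark's regional mean price increment.
  The benchmark's regional consumption and revenue aggregates follow some
  undocumented weighting that the bundled inputs cannot reconstruct, so
  aggregation is configurable (`aggregate_region(method = "weighted")`
  with caller-supplied weights) and those two aggregates are not used for
  validation. Person counts are summed, which does reproduce the benchmark
  totals.
* **Bundled inputs.** Adult population and the quitters' age mix are not
  part of the transcribed input tables, so `apac_country_inputs()` backs
  them out of the benchmark itself: the implied population solves the
  smoker-reduction identity, the implied MAF is the published
  deaths-to-quitters ratio, and `calibrate_age_shares()` constructs a
  synthetic five-band age profile consistent with that MAF (a
  piecewise-linear blend between the uniform profile and an extreme one,
  chosen because it spans the whole achievable MAF range
  $[r\,\min w_b,\ r\,\max w_b]$ with a single parameter). These derived
  inputs are labelled as such and live in code, not in the transcription.

## The synthetic panel generator

`generate_panel()` realises the demand model exactly, so the estimator can
be validated against known truth. What it emulates:

* country intercepts $\beta_{1i} \sim N(\mu_\alpha, \sigma_\alpha^2)$,
  optionally loaded on the country's mean log price
  (`alpha_price_gamma`) to create the correlated heterogeneity a Hausman
  test should detect;
* log real price as a stationary AR(1) around a country-specific mean
  (default $\rho = 0.9$, innovation SD 0.08, country means
  $N(0.5, 0.4^2)$ in log-US$ — prices of roughly \$0.7–\$3.5, the range
  seen across low- and middle-income Asia-Pacific countries). Persistence
  is what makes the lagged price a relevant instrument;
* GNI per capita with geometric growth and country-specific drift
  (lognormal base around US$2500, drift 1–6%/yr) so income clusters are
  distinguishable;
* staggered one-way FCTC adoption (a single adoption year drawn uniformly
  in 2004–2010; ratification is never reversed);
* a CPI path with 2–8% annual inflation, used only to construct the lagged
  instrument (panel prices are already real);
* errors $\varepsilon_{it} = \sigma(\sqrt{\rho_c}\,u_i +
  \sqrt{1-\rho_c}\,\eta_{it})$, equicorrelated within country
  ($\rho_c = 0.3$ by default) — the unmodelled dependence cluster-robust
  inference is meant to absorb.

Identical seeds give identical panels, and `write_panel()` writes numerics
at 17 significant digits so regeneration is byte-identical and a write/read
round trip is exact.

What it does **not** emulate: real countries' historical series (the
bundled transcription serves that purpose), price-GNI cross-correlation,
measurement error in consumption (smuggling, untaxed products), or
structural breaks. Passing the validation harness therefore shows the
estimator recovers the parameters of this data-generating process, not that
the published elasticities are correct — the original market-research panel
is proprietary and the coefficient table is deliberately not a validation
target.

## Validation design and problem sizes

* **Oracle equivalences** (exact): within-FE equals least-squares-dummy-
  variables to 1e-8; 2SLS with the regressor as its own instrument equals
  within-OLS to 1e-10; the clustered covariance matches an independent
  sandwich-estimator implementation on LSDV, and collapses to HC1 when
  every observation is its own cluster; noise-free panels return the true
  coefficients to machine precision.
* **Monte Carlo recovery**: 500 panels at the study scale (22 countries ×
  17 years, elasticity −1.304, error SD 0.05): the mean estimate must sit
  within ±0.02 of truth and 95% confidence intervals (t with G−1 df on
  cluster-robust SEs) must cover between 90% and 98% of the time.
* **Hausman size**: 500 replicates with intercepts independent of the
  regressors and no error equicorrelation (so the random-effects assumption
  holds exactly); rejection at the 5% level must land in [2%, 8%].
* **Hausman power**: 200 replicates with intercepts loaded on the country
  mean price (`alpha_price_gamma = 1`) and variance components scaled to
  `error_sd = 0.2`, `alpha_sd = 0.15`. Under the generator defaults
  ($\theta \approx 0.96$) quasi-demeaning absorbs nearly all between
  variation and RE is numerically indistinguishable from FE, so *no* test
  could have power there; the power study's alternative is designed with
  $\theta \approx 0.7$, where random effects are genuinely biased.
  Rejection must exceed 80%.

These replicate counts keep the whole suite under a minute of Monte Carlo
while leaving the binomial noise on the measured rates well inside the
asserted bands. The AR(1) property of generated prices is checked on
500-year series (tolerance 0.05 on the autocorrelation, averaged over
countries).

## Known limitations

* The elasticity is a within-country, annual, aggregate-demand elasticity;
  it conflates participation and intensity responses, which is why the
  simulator must assume the quitting margin when converting to smokers.
* The revenue rule credits the whole price rise to excise; pass-through
  below or above 1 and industry price responses are out of scope.
* The Hausman comparison uses the non-IV within estimator, as is classical;
  comparing IV variants is not offered.
* Overidentification (Sargan-type) testing is not implemented: with two
  instruments for one endogenous regressor the degree of overidentification
  is one, but the construction the headline diagnostics would need is not
  settled enough here to report responsibly.
* Single-year price series, countries without two consecutive years of
  prices, and empty scenario sets raise errors rather than guessing.
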