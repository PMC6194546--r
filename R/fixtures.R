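#' Bundled Asia-Pacific country inputs and published benchmark
#'
#' The package ships hand-transcribed inputs for 22 low- and middle-income
#' Asia-Pacific countries: excise tax structure (specific and ad valorem
#' shares of retail price, as fractions), age-standardised adult smoking
#' prevalence, 2015 consumption and real price (`apac_tax_policy()`); the
#' per-income-group demand model estimates with diagnostics
#' (`apac_elasticities()`); and the published simulation results —
#' mean/max price increments, consumption and revenue changes, smoker
#' reductions and averted smoking-attributable deaths — used as the
#' benchmark the simulator is validated against (`apac_benchmark()`).
#' Bhutan's excise shares and the two countries without an excise baseline
#' (Bhutan, Maldives) carry `NA` revenue entries in the benchmark.
#'
#' @return data.frames; shares and prevalence are fractions, benchmark
#'   percentage columns are in percent as published, person counts are
#'   signed as published (negative = reduction).
#' @name apac_fixtures
NULL

fixture_path <- function(file)
  system.file("extdata", file, package = "cigtaxsim", mustWork = TRUE)

#' @rdname apac_fixtures
#' @export
apac_tax_policy <- function() {
  read.csv(fixture_path("apac_tax_policy.csv"), stringsAsFactors = FALSE)
}

#' @rdname apac_fixtures
#' @export
apac_elasticities <- function() {
  read.csv(fixture_path("apac_elasticities.csv"), stringsAsFactors = FALSE)
}

#' @rdname apac_fixtures
#' @export
apac_benchmark <- function() {
  read.csv(fixture_path("apac_benchmark.csv"), stringsAsFactors = FALSE)
}

#' Per-country price elasticities from the bundled group estimates
#'
#' Maps each bundled country to its income group's estimated price
#' elasticity.
#'
#' @return named numeric vector of elasticities by country.
#' @export
apac_country_elasticities <- function() {
  pol <- apac_tax_policy()
  el <- apac_elasticities()
  stats::setNames(el$beta_price[match(pol$income_group, el$group_id)],
                  pol$country)
}

#' Price-rise scenarios from the bundled benchmark
#'
#' The published mean and maximum historical annual real-price increments
#' per country, as fractional increases.
#'
#' @return data.frame with columns `country`, `kind`, `dP`.
#' @export
apac_price_scenarios <- function() {
  b <- apac_benchmark()
  out <- rbind(
    data.frame(country = b$country, kind = "mean", dP = b$dP_mean_pct / 100,
               stringsAsFactors = FALSE),
    data.frame(country = b$country, kind = "max", dP = b$dP_max_pct / 100,
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Full simulator inputs for the bundled countries
#'
#' Population aged 15+ and the mortality adjustment factor are not part of
#' the transcribed input tables; they are backed out of the published
#' benchmark (a derived-oracle construction): the implied population solves
#' `smokers_mean = prevalence * pop15plus * |elasticity * dP_mean|`, and
#' the implied MAF is the published ratio of averted deaths to smoker
#' reduction. A synthetic age-share profile consistent with each implied
#' MAF (via [calibrate_age_shares()]) is attached so the table satisfies
#' the full policy-input schema.
#'
#' @param mp a [mortality_params()] object.
#' @return data.frame with the policy-input columns plus `income_group`,
#'   `maf`, and the five age-share columns.
#' @export
apac_country_inputs <- function(mp = mortality_params()) {
  pol <- apac_tax_policy()
  b <- apac_benchmark()
  el <- apac_country_elasticities()
  stopifnot(identical(pol$country, b$country))
  dC_mean <- simulate_consumption_change(unname(el[pol$country]),
                                         b$dP_mean_pct / 100)
  pop <- abs(b$smokers_mean) / (pol$prevalence * abs(dC_mean))
  maf <- abs(b$sads_mean) / abs(b$smokers_mean)
  shares <- t(vapply(maf, calibrate_age_shares, numeric(5), mp = mp))
  out <- data.frame(country = pol$country, income_group = pol$income_group,
                    specific_share = pol$specific_share,
                    advalorem_share = pol$advalorem_share,
                    prevalence = pol$prevalence, pop15plus = pop,
                    maf = maf,
                    share_15_29 = shares[, 1], share_30_39 = shares[, 2],
                    share_40_49 = shares[, 3], share_50_59 = shares[, 4],
                    share_60plus = shares[, 5], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
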