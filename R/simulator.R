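#' Mortality parameters for averted-death accounting
#'
#' Quitters avoid smoking-attributable death with a probability that falls
#' with age at cessation: by default 95%, 75%, 70%, 50% and 10% of quitters
#' aged 15-29, 30-39, 40-49, 50-59 and 60+ escape the mortality consequences
#' of their former habit. `smoker_death_risk` is the baseline probability
#' that a continuing smoker eventually dies of smoking (default 0.5, the
#' convention of the Goodchild-style attributable-death literature).
#'
#' @param avoidance_weights five fractions in `[0,1]` for the age bands
#'   15-29, 30-39, 40-49, 50-59, 60+.
#' @param smoker_death_risk fraction in `[0,1]`.
#' @return a validated list of class `mortality_params`.
#' @export
mortality_params <- function(avoidance_weights = c(0.95, 0.75, 0.70, 0.50, 0.10),
                             smoker_death_risk = 0.5) {
  if (length(avoidance_weights) != 5 ||
      any(avoidance_weights < 0 | avoidance_weights > 1))
    stop("invalid parameter 'avoidance_weights': five fractions in [0,1]",
         call. = FALSE)
  if (smoker_death_risk < 0 || smoker_death_risk > 1)
    stop("invalid parameter 'smoker_death_risk': fraction in [0,1]",
         call. = FALSE)
  structure(list(avoidance_weights = avoidance_weights,
                 smoker_death_risk = smoker_death_risk),
            class = "mortality_params")
}

#' Mean and maximum historical price increments
#'
#' Year-over-year fractional changes of a real price series, computed only
#' across consecutive calendar years. The maximum increment and the
#' arithmetic mean increment (over all changes, or over positive changes
#' only) are the price-rise scenarios fed to the simulator.
#'
#' @param prices numeric vector of positive real prices.
#' @param years matching calendar years; defaults to consecutive years.
#' @param positive_only if `TRUE`, the mean is taken over positive changes
#'   only (the maximum is unaffected).
#' @return list with `mean` and `max` fractional increments.
#' @examples
#' historical_increments(c(1, 1.1, 1.21))  # 10% a year
#' @export
historical_increments <- function(prices, years = NULL, positive_only = FALSE) {
  if (is.null(years)) years <- seq_along(prices)
  stopifnot(length(prices) == length(years))
  o <- order(years)
  prices <- prices[o]; years <- years[o]
  if (any(prices <= 0)) stop("prices must be positive", call. = FALSE)
  if (length(prices) < 2)
    stop("need at least two years of prices", call. = FALSE)
  consec <- which(diff(years) == 1)
  if (!length(consec))
    stop("no consecutive-year price pairs in the series", call. = FALSE)
  ch <- prices[consec + 1] / prices[consec] - 1
  mch <- if (positive_only) {
    pos <- ch[ch > 0]
    if (length(pos)) mean(pos) else NA_real_
  } else mean(ch)
  list(mean = mch, max = max(ch))
}

#' Consumption response to a price increase
#'
#' The comparative-static consumption change is linear in the price
#' increment: `dC = elasticity * dP`. A constant-elasticity power response
#' `(1+dP)^elasticity - 1` is deliberately not used; the linear form is the
#' one consistent with the bundled published benchmark.
#'
#' @param elasticity price elasticity of demand (typically negative).
#' @param dP fractional real-price increase, `> -1`.
#' @return fractional consumption change.
#' @examples
#' simulate_consumption_change(-1.304, 0.0945)  # about -0.1232
#' @export
simulate_consumption_change <- function(elasticity, dP) {
  if (any(dP <= -1)) stop("dP must exceed -1", call. = FALSE)
  elasticity * dP
}

#' Excise revenue response to a price increase
#'
#' Baseline excise take per pack is the total excise share of the retail
#' price, `tau = specific_share + advalorem_share`. The entire price
#' increment is treated as new specific excise, so per-pack excise grows by
#' the factor `(tau + dP) / tau` while volume scales with surviving
#' consumption:
#' `dRevenue = ((tau + dP) / tau) * (1 + dC) - 1`.
#' Countries with zero or missing excise have no revenue baseline; the
#' change is undefined (`NA`).
#'
#' @param tau total excise share of retail price in `[0,1]`, or `NA`.
#' @param dP fractional price increase.
#' @param dC fractional consumption change.
#' @return fractional excise-revenue change, or `NA` when `tau` is zero or
#'   missing.
#' @examples
#' simulate_revenue_change(0.1315, 0.0646, -0.0024)  # about +0.488
#' @export
simulate_revenue_change <- function(tau, dP, dC) {
  if (any(!is.na(tau) & (tau < 0 | tau > 1)))
    stop("total excise share must lie in [0,1]", call. = FALSE)
  ifelse(is.na(tau) | tau == 0, NA_real_,
         ((tau + dP) / tau) * (1 + dC) - 1)
}

#' Reduction in smoker numbers from a consumption change
#'
#' All of the consumption decline is attributed to the prevalence margin
#' (quitting), none to reduced intensity among continuing smokers, so the
#' number of quitters is `prevalence * pop15plus * |dC|`.
#'
#' @param prevalence adult smoking prevalence fraction in `[0,1]`.
#' @param pop15plus population aged 15 and over.
#' @param dC fractional consumption change (`<= 0`).
#' @return number of persons quitting (non-negative).
#' @export
simulate_smoker_reduction <- function(prevalence, pop15plus, dC) {
  if (any(is.na(prevalence)) || any(is.na(pop15plus)))
    stop("missing prevalence or population", call. = FALSE)
  if (any(dC > 0)) stop("dC must be <= 0 for a price increase", call. = FALSE)
  prevalence * pop15plus * abs(dC)
}

#' Country mortality adjustment factor
#'
#' The fraction of quitters whose death is thereby averted:
#' `maf = smoker_death_risk * sum(age_share * avoidance_weight)` over the
#' five age bands. Always bounded above by `smoker_death_risk`.
#'
#' @param age_shares five fractions summing to 1: shares of quitters aged
#'   15-29, 30-39, 40-49, 50-59, 60+.
#' @param mp a [mortality_params()] object.
#' @return factor in `[0,1]`.
#' @examples
#' mortality_adjustment_factor(rep(0.2, 5))  # 0.5 * 0.60 = 0.30
#' @export
mortality_adjustment_factor <- function(age_shares, mp = mortality_params()) {
  if (!inherits(mp, "mortality_params")) mp <- do.call(mortality_params, mp)
  if (length(age_shares) != 5 || abs(sum(age_shares) - 1) > 1e-9 ||
      any(age_shares < 0))
    stop("age_shares must be five non-negative fractions summing to 1",
         call. = FALSE)
  mp$smoker_death_risk * sum(age_shares * mp$avoidance_weights)
}

#' Averted smoking-attributable deaths
#'
#' `sads = smoker_reduction * maf`, reported to the nearest person.
#'
#' @param smoker_reduction persons quitting (>= 0).
#' @param maf mortality adjustment factor in `[0,1]`.
#' @return averted deaths (persons).
#' @export
averted_sads <- function(smoker_reduction, maf) {
  if (any(smoker_reduction < 0)) stop("smoker_reduction must be >= 0",
                                      call. = FALSE)
  if (any(maf < 0 | maf > 1)) stop("maf must lie in [0,1]", call. = FALSE)
  round(smoker_reduction * maf)
}

#' Construct an age-share profile with a target mortality adjustment factor
#'
#' Inverse of [mortality_adjustment_factor()]: returns one plausible
#' five-band age distribution of quitters whose MAF equals `target_maf`
#' under the given mortality parameters. The profile is a piecewise-linear
#' blend between the uniform distribution and an all-youngest
#' (or all-oldest) extreme, so any target in the achievable range
#' `[risk * min(w), risk * max(w)]` is matched exactly. Used to build
#' synthetic country inputs consistent with an implied MAF.
#'
#' @param target_maf desired factor.
#' @param mp a [mortality_params()] object.
#' @return five age shares summing to 1.
#' @export
calibrate_age_shares <- function(target_maf, mp = mortality_params()) {
  risk <- mp$smoker_death_risk
  w <- mp$avoidance_weights
  uniform <- rep(0.2, 5)
  m_unif <- risk * mean(w)
  lo <- risk * min(w); hi <- risk * max(w)
  if (target_maf < lo - 1e-12 || target_maf > hi + 1e-12)
    stop(sprintf("target maf %.4f outside achievable range [%.4f, %.4f]",
                 target_maf, lo, hi), call. = FALSE)
  extreme <- numeric(5)
  if (target_maf >= m_unif) extreme[which.max(w)] <- 1
  else extreme[which.min(w)] <- 1
  m_ext <- risk * sum(extreme * w)
  lambda <- if (abs(m_ext - m_unif) < 1e-15) 0
            else (target_maf - m_unif) / (m_ext - m_unif)
  lambda <- min(max(lambda, 0), 1)
  (1 - lambda) * uniform + lambda * extreme
}

#' Simulate tax-policy outcomes for a set of countries and scenarios
#'
#' Runs the full deterministic chain for each country-scenario pair:
#' consumption change from the elasticity, excise revenue change from the
#' excise share, smoker reduction from prevalence and population, and
#' averted smoking-attributable deaths from the mortality adjustment
#' factor. The MAF is taken from an explicit `maf` column if present,
#' otherwise computed from the five age-share columns.
#'
#' @param policy data.frame with columns `country`, `specific_share`,
#'   `advalorem_share`, `prevalence`, `pop15plus` and either `maf` or the
#'   five `share_*` age-share columns.
#' @param elasticities named numeric vector of price elasticities by
#'   country.
#' @param scenarios data.frame with columns `country`, `kind`
#'   (`"mean"`/`"max"`) and `dP` (fractional price increase).
#' @param mp a [mortality_params()] object.
#' @return data.frame of class `sim_outcome` with one row per
#'   country-scenario: `country`, `kind`, `dP`, `dC`, `dRevenue` (`NA`
#'   when the excise baseline is zero or missing), `smoker_reduction`,
#'   `maf`, `sads_averted`.
#' @export
simulate_policy <- function(policy, elasticities, scenarios,
                            mp = mortality_params()) {
  stopifnot(all(c("country", "kind", "dP") %in% names(scenarios)))
  if (!nrow(scenarios)) stop("no scenarios to simulate", call. = FALSE)
  if (!all(scenarios$kind %in% c("mean", "max")))
    stop("scenario kind must be 'mean' or 'max'", call. = FALSE)
  miss <- setdiff(scenarios$country, policy$country)
  if (length(miss))
    stop("no policy inputs for country: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss_e <- setdiff(scenarios$country, names(elasticities))
  if (length(miss_e))
    stop("no elasticity for country: ", paste(miss_e, collapse = ", "),
         call. = FALSE)

  i <- match(scenarios$country, policy$country)
  pol <- policy[i, , drop = FALSE]
  tau <- pol$specific_share + pol$advalorem_share   # NA if either missing
  eps <- unname(elasticities[scenarios$country])

  dC <- simulate_consumption_change(eps, scenarios$dP)
  dRev <- simulate_revenue_change(tau, scenarios$dP, dC)
  smokers <- simulate_smoker_reduction(pol$prevalence, pol$pop15plus,
                                       pmin(dC, 0))
  maf <- if ("maf" %in% names(pol)) pol$maf else {
    share_cols <- c("share_15_29", "share_30_39", "share_40_49",
                    "share_50_59", "share_60plus")
    apply(as.matrix(pol[, share_cols]), 1,
          mortality_adjustment_factor, mp = mp)
  }
  out <- data.frame(country = scenarios$country, kind = scenarios$kind,
                    dP = scenarios$dP, dC = dC, dRevenue = dRev,
                    smoker_reduction = smokers, maf = maf,
                    sads_averted = averted_sads(smokers, maf),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sim_outcome", "data.frame")
  out
}

#' Aggregate simulation outcomes over a region
#'
#' Regional price increment and consumption/revenue changes are averaged
#' across countries (unweighted by default; optionally weighted), while
#' smoker reductions and averted deaths are summed. Revenue aggregation
#' averages over countries with a defined excise baseline only.
#'
#' @param outcomes a `sim_outcome` data.frame (one row per country per
#'   kind).
#' @param method `"unweighted"` or `"weighted"`.
#' @param weights named numeric vector by country (e.g. baseline
#'   consumption or revenue), required for `method = "weighted"`.
#' @return data.frame with one row per scenario kind: mean `dP`, aggregated
#'   `dC` and `dRevenue`, total `smoker_reduction` and `sads_averted`, and
#'   the country count.
#' @export
aggregate_region <- function(outcomes, method = c("unweighted", "weighted"),
                             weights = NULL) {
  method <- match.arg(method)
  if (!nrow(outcomes)) stop("no outcomes to aggregate", call. = FALSE)
  if (method == "weighted" && is.null(weights))
    stop("weights required for weighted aggregation", call. = FALSE)
  agg_one <- function(d) {
    w <- if (method == "unweighted") rep(1, nrow(d))
         else unname(weights[d$country])
    ok <- !is.na(d$dRevenue)
    data.frame(kind = d$kind[1],
               dP = stats::weighted.mean(d$dP, w),
               dC = stats::weighted.mean(d$dC, w),
               dRevenue = if (any(ok))
                 stats::weighted.mean(d$dRevenue[ok], w[ok]) else NA_real_,
               smoker_reduction = sum(d$smoker_reduction),
               sads_averted = sum(d$sads_averted),
               n_countries = nrow(d), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(outcomes, outcomes$kind), agg_one))
  rownames(out) <- NULL
  out
}
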