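#' Parameters of the synthetic panel data-generating process
#'
#' Bundles and validates the parameters of the log-log cigarette demand
#' model used to generate synthetic country-year panels:
#' \deqn{\ln C_{it} = \beta_{1i} + \beta_2 \ln P_{it} + \beta_3 \ln GNI_{it}
#'       + \beta_4 FCTC_{it} + \epsilon_{it}}
#' with country intercepts \eqn{\beta_{1i}}, a stationary AR(1) log real
#' price, geometric GNI growth with country-specific drift, one-way staggered
#' FCTC ratification, and errors that may be equicorrelated within country
#' (the dependence structure cluster-robust inference is meant to absorb).
#'
#' @param n_countries number of countries (>= 2).
#' @param years inclusive vector of calendar years (span >= 3; one year is
#'   consumed by the lagged instruments).
#' @param beta_price price elasticity of demand (dimensionless, usually
#'   negative).
#' @param beta_gni income elasticity of demand (dimensionless).
#' @param beta_fctc shift in log consumption after FCTC ratification.
#' @param alpha_mean,alpha_sd mean and dispersion of the country intercepts.
#' @param alpha_price_gamma loading of the country intercept on the country's
#'   mean log price. Zero gives intercepts independent of the regressors
#'   (the random-effects assumption holds); nonzero induces the correlated
#'   heterogeneity that a Hausman test should detect.
#' @param price_rho AR(1) coefficient of log real price, |rho| < 1.
#' @param price_shock_sd innovation SD of log price (>= 0).
#' @param price_mean_log,price_mean_sd mean and SD of the country-level mean
#'   log price around which each AR(1) path is stationary.
#' @param error_sd SD of the demand error epsilon (>= 0).
#' @param error_cluster_rho within-country correlation of epsilon in [0, 1),
#'   realised as an equicorrelated country-level component plus idiosyncratic
#'   noise.
#' @param gni_base_meanlog,gni_base_sdlog lognormal parameters of baseline
#'   GNI per capita (US$).
#' @param gni_drift_range range of country-specific annual log-GNI growth.
#' @param inflation_range range of annual CPI inflation (the CPI is used only
#'   to construct the lagged instrument; prices are already real).
#' @param fctc_adoption_window year range in which each country draws its
#'   ratification year uniformly; FCTC = 1 from that year on.
#' @param seed integer seed; identical seeds give identical panels.
#'
#' @return an object of class `panel_dgp_params` (a validated list).
#' @seealso [generate_panel()]
#' @export
panel_dgp_params <- function(n_countries = 22,
                             years = 1999:2015,
                             beta_price = -1.304,
                             beta_gni = 0.769,
                             beta_fctc = -0.103,
                             alpha_mean = 1,
                             alpha_sd = 0.3,
                             alpha_price_gamma = 0,
                             price_rho = 0.9,
                             price_shock_sd = 0.08,
                             price_mean_log = 0.5,
                             price_mean_sd = 0.4,
                             error_sd = 0.05,
                             error_cluster_rho = 0.3,
                             gni_base_meanlog = log(2500),
                             gni_base_sdlog = 0.8,
                             gni_drift_range = c(0.01, 0.06),
                             inflation_range = c(0.02, 0.08),
                             fctc_adoption_window = c(2004, 2010),
                             seed = NULL) {
  p <- list(n_countries = n_countries, years = sort(unique(as.integer(years))),
            beta_price = beta_price, beta_gni = beta_gni,
            beta_fctc = beta_fctc, alpha_mean = alpha_mean,
            alpha_sd = alpha_sd, alpha_price_gamma = alpha_price_gamma,
            price_rho = price_rho, price_shock_sd = price_shock_sd,
            price_mean_log = price_mean_log, price_mean_sd = price_mean_sd,
            error_sd = error_sd, error_cluster_rho = error_cluster_rho,
            gni_base_meanlog = gni_base_meanlog,
            gni_base_sdlog = gni_base_sdlog,
            gni_drift_range = gni_drift_range,
            inflation_range = inflation_range,
            fctc_adoption_window = fctc_adoption_window, seed = seed)
  validate_dgp_params(p)
  class(p) <- "panel_dgp_params"
  p
}

validate_dgp_params <- function(p) {
  stop_param <- function(field, msg)
    stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
  if (!is.numeric(p$n_countries) || p$n_countries < 2)
    stop_param("n_countries", "need at least 2 countries")
  if (length(p$years) < 3)
    stop_param("years", "need a span of at least 3 years (lagging consumes one)")
  for (f in c("alpha_sd", "price_shock_sd", "error_sd"))
    if (!is.numeric(p[[f]]) || p[[f]] < 0) stop_param(f, "must be >= 0")
  if (abs(p$price_rho) >= 1)
    stop_param("price_rho", "must lie in (-1, 1)")
  if (p$error_cluster_rho < 0 || p$error_cluster_rho >= 1)
    stop_param("error_cluster_rho", "must lie in [0, 1)")
  if (length(p$fctc_adoption_window) != 2 ||
      p$fctc_adoption_window[1] > p$fctc_adoption_window[2])
    stop_param("fctc_adoption_window", "must be an increasing year range")
  invisible(p)
}

#' Generate a synthetic cigarette demand panel
#'
#' Realises the demand model held in a [panel_dgp_params()] object as a
#' balanced country-year panel. Log consumption satisfies the model exactly
#' up to the drawn error, so with `error_sd = 0` the demand equation holds
#' on every row to machine precision and regression recovers the true
#' coefficients — the basis of the estimator validation harness.
#'
#' @param params a `panel_dgp_params` object.
#' @return a data.frame with columns `country`, `year`, `consumption`
#'   (packs per capita aged 15+), `price` (real US$ per 20-pack), `gni`
#'   (real GNI per capita US$), `fctc` (0/1), `cpi` (index, first year =
#'   100), carrying the drawn country intercepts and the generating
#'   parameters in attribute `"truth"`.
#' @examples
#' pan <- generate_panel(panel_dgp_params(n_countries = 4, seed = 1))
#' head(pan)
#' @export
generate_panel <- function(params) {
  if (!inherits(params, "panel_dgp_params"))
    params <- do.call(panel_dgp_params, params)
  validate_dgp_params(params)
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  n <- p$n_countries
  yrs <- p$years
  t_len <- length(yrs)
  ctry <- sprintf("C%02d", seq_len(n))

  mu_p <- rnorm(n, p$price_mean_log, p$price_mean_sd)
  alpha <- p$alpha_mean + p$alpha_sd * rnorm(n) +
    p$alpha_price_gamma * (mu_p - p$price_mean_log)
  gni0 <- exp(rnorm(n, p$gni_base_meanlog, p$gni_base_sdlog))
  drift <- runif(n, p$gni_drift_range[1], p$gni_drift_range[2])
  adopt <- floor(runif(n, p$fctc_adoption_window[1],
                       p$fctc_adoption_window[2] + 1))
  u_country <- rnorm(n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    # stationary AR(1) in logs around the country mean
    lnp <- numeric(t_len)
    stat_sd <- if (p$price_shock_sd > 0)
      p$price_shock_sd / sqrt(1 - p$price_rho^2) else 0
    lnp[1] <- mu_p[i] + rnorm(1, 0, stat_sd)
    if (t_len > 1)
      for (t in 2:t_len)
        lnp[t] <- mu_p[i] + p$price_rho * (lnp[t - 1] - mu_p[i]) +
          rnorm(1, 0, p$price_shock_sd)
    lngni <- log(gni0[i]) + drift[i] * (seq_len(t_len) - 1)
    fctc <- as.integer(yrs >= adopt[i])
    infl <- runif(t_len - 1, p$inflation_range[1], p$inflation_range[2])
    cpi <- 100 * cumprod(c(1, 1 + infl))
    eps <- p$error_sd * (sqrt(p$error_cluster_rho) * u_country[i] +
                           sqrt(1 - p$error_cluster_rho) * rnorm(t_len))
    lnc <- alpha[i] + p$beta_price * lnp + p$beta_gni * lngni +
      p$beta_fctc * fctc + eps
    rows[[i]] <- data.frame(country = ctry[i], year = yrs,
                            consumption = exp(lnc), price = exp(lnp),
                            gni = exp(lngni), fctc = fctc, cpi = cpi,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(params = p, intercepts = stats::setNames(alpha, ctry),
                             adoption_year = stats::setNames(adopt, ctry))
  out
}

#' Generate a synthetic country policy table
#'
#' Draws per-country excise tax structures, smoking prevalence, adult
#' population and the age distribution of smokers, within the ranges seen
#' across low- and middle-income Asia-Pacific countries (total excise share
#' of retail price between 0 and about 0.67, prevalence between 10% and
#' 38%). Used to exercise the policy simulator on inputs with known
#' invariants; it does not mimic any specific country.
#'
#' @param n_countries number of rows (>= 1).
#' @param seed integer seed; identical seeds give identical tables.
#' @return a data.frame with columns `country`, `specific_share`,
#'   `advalorem_share`, `prevalence`, `pop15plus`, `share_15_29`,
#'   `share_30_39`, `share_40_49`, `share_50_59`, `share_60plus`; all
#'   shares are fractions, the five age shares sum to 1 in each row.
#' @export
generate_policy_table <- function(n_countries, seed = NULL) {
  if (!is.numeric(n_countries) || n_countries < 1)
    stop("invalid parameter 'n_countries': must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_countries)
  total <- runif(n, 0, 0.67)
  mix <- runif(n)               # fraction of the excise that is specific
  specific <- total * mix
  advalorem <- total - specific
  prevalence <- runif(n, 0.10, 0.38)
  pop <- exp(rnorm(n, log(5e6), 1.5))
  # age mix of smokers: Dirichlet draw centred on a young-leaning profile
  conc <- c(0.33, 0.22, 0.19, 0.15, 0.11) * 40
  g <- matrix(rgamma(n * 5, shape = rep(conc, each = n)), nrow = n)
  shares <- g / rowSums(g)
  out <- data.frame(country = sprintf("C%02d", seq_len(n)),
                    specific_share = specific, advalorem_share = advalorem,
                    prevalence = prevalence, pop15plus = pop,
                    share_15_29 = shares[, 1], share_30_39 = shares[, 2],
                    share_40_49 = shares[, 3], share_50_59 = shares[, 4],
                    share_60plus = shares[, 5], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
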