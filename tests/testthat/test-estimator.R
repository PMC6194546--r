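test_that("income clusters use the fixed GNI thresholds", {
  cl <- assign_income_clusters(c(A = 500, B = 999.99, C = 1000, D = 2500,
                                 E = 3500, F = 4500, G = 6000, H = 9000))
  expect_equal(cl$group_id[cl$country == "A"], 1)
  expect_equal(cl$group_id[cl$country == "B"], 1)
  expect_equal(cl$group_id[cl$country == "C"], 2)
  expect_equal(cl$group_id[cl$country == "D"], 3)
  expect_equal(cl$group_id[cl$country == "E"], 4)
  expect_equal(cl$group_id[cl$country == "F"], 5)
  expect_equal(cl$group_id[cl$country == "G"], 6)   # 6000 falls in the top group
  expect_equal(cl$group_id[cl$country == "H"], 6)
  expect_error(assign_income_clusters(c(A = 500, B = NA)), "B")
})

test_that("within transform demeans by country", {
  d <- data.frame(country = c("A", "A", "B", "B", "B"),
                  x = c(3, 5, 1, 1, 1), fctc = c(0, 1, 0, 1, 1))
  w <- within_transform(d, c("x", "fctc"))
  expect_equal(w$x[1:2], c(-1, 1))
  expect_equal(w$x[3:5], c(0, 0, 0))                 # constant within country
  expect_false(all(w$fctc %in% c(0, 1)))             # dummy no longer binary
  means <- tapply(w$x, w$country, mean)
  expect_true(all(abs(means) < 1e-10))
  d2 <- rbind(d, data.frame(country = "C", x = 9, fctc = 1))
  expect_warning(w2 <- within_transform(d2, "x"), "C")
  expect_false("C" %in% w2$country)
})

test_that("within FE-OLS equals least-squares-dummy-variables", {
  pan <- small_panel(seed = 21)
  fe <- fit_fe_2sls(pan, iv = FALSE)
  d <- frame_of(pan)
  lsdv <- coef(lm(lnC ~ lnP + lnGNI + fctc + factor(country), data = d))
  expect_equal(unname(fe$coefficients),
               unname(lsdv[c("lnP", "lnGNI", "fctc")]), tolerance = 1e-8)
  # recovered intercepts match the LSDV country intercepts
  icpt <- lsdv["(Intercept)"] +
    c(0, lsdv[grep("factor", names(lsdv))])
  expect_equal(unname(fe$intercepts), unname(icpt), tolerance = 1e-8)
})

test_that("2SLS with instrument equal to the regressor is OLS", {
  pan <- small_panel(seed = 22)
  a <- fit_fe_2sls(pan, instruments = "lnP")
  b <- fit_fe_2sls(pan, iv = FALSE)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-10)
  expect_equal(a$n_obs, b$n_obs)                     # no observations lagged away
})

test_that("noise-free FE-2SLS identifies the true elasticities exactly", {
  pan <- generate_panel(panel_dgp_params(n_countries = 5, error_sd = 0,
                                         seed = 31))
  f <- fit_fe_2sls(pan)
  expect_equal(unname(f$coefficients),
               c(-1.304, 0.769, -0.103), tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-8)
})

test_that("elasticity estimates are invariant to price units", {
  pan <- small_panel(seed = 23)
  pan2 <- pan
  pan2$price <- pan$price * 1000                     # dollars to tenths of cents
  f1 <- fit_fe_2sls(pan)
  f2 <- fit_fe_2sls(pan2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
})

test_that("cluster-robust vcov matches the sandwich oracle on LSDV", {
  skip_if_not_installed("sandwich")
  pan <- small_panel(seed = 24)
  fe <- fit_fe_2sls(pan, iv = FALSE)
  d <- frame_of(pan)
  m <- lm(lnC ~ lnP + lnGNI + fctc + factor(country), data = d)
  V <- sandwich::vcovCL(m, cluster = d$country, type = "HC1")
  expect_equal(unname(fe$vcov),
               unname(V[c("lnP", "lnGNI", "fctc"), c("lnP", "lnGNI", "fctc")]),
               tolerance = 1e-8)
})

test_that("singleton clusters reduce the CR estimator to HC1", {
  skip_if_not_installed("sandwich")
  set.seed(77)
  n <- 60
  X <- cbind(x1 = rnorm(n), x2 = runif(n))
  y <- drop(X %*% c(1, -2)) + rnorm(n)
  beta <- solve(crossprod(X), crossprod(X, y))
  e <- drop(y - X %*% beta)
  V_cr <- cigtaxsim:::cluster_vcov(solve(crossprod(X)), X, e,
                                   g = seq_len(n), k_absorbed = 0)
  m <- lm(y ~ 0 + X)
  V_hc <- sandwich::vcovHC(m, type = "HC1")
  expect_equal(unname(V_cr), unname(V_hc), tolerance = 1e-8)
})

test_that("degenerate designs raise rank and clustering errors", {
  pan <- generate_panel(panel_dgp_params(
    n_countries = 4, years = 1999:2015, seed = 41,
    fctc_adoption_window = c(2030, 2031)))          # FCTC never switches on
  expect_error(fit_fe_2sls(pan), "fctc")
  one <- small_panel(seed = 42)
  one <- one[one$country == one$country[1], ]
  expect_error(fit_fe_2sls(one), "2 countries")
})

test_that("random-effects GLS behaves at its limits", {
  # shared intercept, no noise: RE = pooled OLS = FE slopes
  pan <- generate_panel(panel_dgp_params(n_countries = 4, alpha_sd = 0,
                                         error_sd = 0, seed = 51))
  re <- suppressWarnings(fit_re_gls(pan))
  fe <- suppressWarnings(fit_fe_2sls(pan, iv = FALSE))
  d <- frame_of(pan)
  pooled <- coef(lm(lnC ~ lnP + lnGNI + fctc, data = d))
  expect_equal(unname(re$slopes), unname(fe$coefficients), tolerance = 1e-6)
  expect_equal(unname(re$slopes),
               unname(pooled[c("lnP", "lnGNI", "fctc")]), tolerance = 1e-6)

  # huge intercept dispersion: theta -> 1 and RE slopes -> FE slopes
  pan2 <- generate_panel(panel_dgp_params(n_countries = 10, alpha_sd = 5,
                                          error_sd = 0.05, seed = 52))
  re2 <- fit_re_gls(pan2)
  fe2 <- fit_fe_2sls(pan2, iv = FALSE)
  expect_true(all(re2$theta > 0.97))
  expect_equal(unname(re2$slopes), unname(fe2$coefficients), tolerance = 1e-3)

  # determinism
  expect_identical(fit_re_gls(pan2)$slopes, re2$slopes)
})

test_that("Hausman statistic is zero for identical estimates", {
  pan <- small_panel(seed = 61)
  fe <- fe_conventional(pan)
  h <- hausman_test(fe, list(coefficients = fe$coefficients,
                             vcov = fe$vcov * 0.5))
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  expect_equal(h$df, 3)
})

test_that("indefinite covariance differences are flagged, not hidden", {
  pan <- small_panel(seed = 62)
  fe <- fe_conventional(pan)
  # comparator with larger variance makes V_fe - V_re negative definite
  h <- hausman_test(fe, list(coefficients = fe$coefficients + 0.01,
                             vcov = fe$vcov * 2))
  expect_true(h$indefinite)
  expect_true(is.finite(h$statistic))
})

test_that("weak-identification F separates weak from strong instruments", {
  # persistent prices make the lagged price a strong instrument
  pan <- generate_panel(panel_dgp_params(price_rho = 0.9, seed = 71))
  expect_gt(weak_id_F(pan), 10)

  # pure-noise instruments on a ~500-observation panel are weak
  pan2 <- generate_panel(panel_dgp_params(n_countries = 30, seed = 72))
  set.seed(73)
  pan2$z1 <- rnorm(nrow(pan2))
  pan2$z2 <- rnorm(nrow(pan2))
  expect_lt(weak_id_F(pan2, instruments = c("z1", "z2")), 10)

  # instrument identical to the regressor: perfect first stage, capped
  pan3 <- small_panel(seed = 74)
  pan3$p_copy <- log(pan3$price)
  expect_equal(weak_id_F(pan3, instruments = c("p_copy")), 1e6)
})

test_that("estimation bias in the elasticity shrinks with the noise level", {
  bias_at <- function(sd) {
    est <- vapply(1:10, function(s) {
      pan <- generate_panel(panel_dgp_params(n_countries = 10, error_sd = sd,
                                             seed = 80 + s))
      fit_fe_2sls(pan)$coefficients[["beta_price"]]
    }, numeric(1))
    abs(mean(est) + 1.304)
  }
  expect_lt(bias_at(0.02), bias_at(0.3))
})

test_that("six income-group fits run end-to-end quickly", {
  pan <- generate_panel(panel_dgp_params(n_countries = 12, seed = 91))
  countries <- unique(pan$country)
  targets <- setNames(rep(c(500, 1500, 2500, 3500, 5000, 8000), each = 2),
                      countries)
  pan <- retarget_gni(pan, targets)
  elapsed <- system.time(
    fits <- suppressWarnings(fit_by_group(pan)))["elapsed"]
  expect_length(fits, 6)
  expect_named(fits, paste0("group", 1:6))
  for (f in fits) {
    expect_s3_class(f, "elasticity_fit")
    expect_equal(f$n_countries, 2)
    expect_equal(unname(f$se), unname(sqrt(diag(f$vcov))))
    ev <- eigen(f$vcov, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-12))                    # PSD
  }
  expect_lt(elapsed, 5)
})
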