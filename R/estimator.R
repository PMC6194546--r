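#' Assign countries to GNI income clusters
#'
#' Partitions countries into six income groups on 2015 GNI per capita
#' (US$, Atlas method) at the fixed thresholds 1000 / 2000 / 3000 / 4000 /
#' 6000: group 1 below US$1000, group 6 at US$6000 and above. Elasticities
#' are estimated separately within each group because cigarette price
#' responsiveness varies with income level.
#'
#' @param gni named numeric vector of GNI per capita (US$) by country, or a
#'   data.frame with columns `country` and `gni`.
#' @return a data.frame with columns `country`, `gni`, `group_id`,
#'   `gni_lower`, `gni_upper` (upper bound `Inf` for the top group).
#' @examples
#' assign_income_clusters(c(Cambodia = 500, China = 7000))
#' @export
assign_income_clusters <- function(gni) {
  if (is.data.frame(gni)) {
    stopifnot(all(c("country", "gni") %in% names(gni)))
    v <- stats::setNames(gni$gni, gni$country)
  } else {
    v <- gni
    if (is.null(names(v))) stop("'gni' must be named by country", call. = FALSE)
  }
  bad <- names(v)[is.na(v)]
  if (length(bad))
    stop("missing GNI for country: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cuts <- c(1000, 2000, 3000, 4000, 6000)
  gid <- findInterval(v, cuts) + 1L
  lower <- c(0, cuts)[gid]
  upper <- c(cuts, Inf)[gid]
  data.frame(country = names(v), gni = unname(v), group_id = gid,
             gni_lower = lower, gni_upper = upper,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Within (fixed-effects) transformation
#'
#' Subtracts country means from the requested variables, absorbing the
#' country intercepts of the demand model. Countries contributing a single
#' observation carry no within variation and are dropped with a warning.
#'
#' @param panel a data.frame containing `country` and the variables.
#' @param variables character vector of column names to demean.
#' @param index grouping column, default `"country"`.
#' @return a data.frame with the index column and the demeaned variables;
#'   column means within every group are zero.
#' @export
within_transform <- function(panel, variables, index = "country") {
  stopifnot(index %in% names(panel), all(variables %in% names(panel)))
  tab <- table(panel[[index]])
  singles <- names(tab)[tab < 2]
  if (length(singles)) {
    warning("dropping single-observation groups: ",
            paste(singles, collapse = ", "), call. = FALSE)
    panel <- panel[!(panel[[index]] %in% singles), , drop = FALSE]
  }
  g <- panel[[index]]
  out <- panel[, index, drop = FALSE]
  for (v in variables)
    out[[v]] <- panel[[v]] - stats::ave(panel[[v]], g)
  rownames(out) <- NULL
  out
}

# ---- internal frame construction -------------------------------------------

# log-transform the panel and attach t-1 lags of log price and log CPI
# (matched on the previous calendar year within country)
build_frame <- function(panel) {
  check_panel(panel)
  d <- panel[order(panel$country, panel$year), , drop = FALSE]
  d$lnC <- log(d$consumption)
  d$lnP <- log(d$price)
  d$lnGNI <- log(d$gni)
  key <- paste(d$country, d$year)
  prev <- match(paste(d$country, d$year - 1L), key)
  d$lnP_lag <- d$lnP[prev]
  d$lnCPI_lag <- log(d$cpi)[prev]
  rownames(d) <- NULL
  d
}

check_panel <- function(panel) {
  need <- c("country", "year", "consumption", "price", "gni", "fctc", "cpi")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (v in c("consumption", "price", "gni", "cpi"))
    if (any(!is.finite(panel[[v]]) | panel[[v]] <= 0))
      stop("column '", v, "' must be strictly positive (log-transformable)",
           call. = FALSE)
  dup <- duplicated(panel[c("country", "year")])
  if (any(dup))
    stop("duplicate (country, year) rows: ",
         paste(unique(paste0(panel$country[dup], ":", panel$year[dup])),
               collapse = ", "), call. = FALSE)
  invisible(panel)
}

demean_mat <- function(x, g) {
  x - apply(x, 2, function(col) stats::ave(col, g))
}

# CR1 cluster-robust covariance for an estimator with bread A^{-1} and
# per-observation scores s_i = w_i * e_i (rows of W times residuals)
cluster_vcov <- function(A_inv, W, e, g, k_absorbed = 0) {
  G <- length(unique(g))
  N <- length(e)
  k <- ncol(W) + k_absorbed
  S <- rowsum(W * e, g)                      # cluster score sums
  meat <- crossprod(as.matrix(S))
  cfac <- G / (G - 1) * (N - 1) / (N - k)
  cfac * A_inv %*% meat %*% t(A_inv)
}

# ---- FE-2SLS ----------------------------------------------------------------

#' Fixed-effects two-stage least squares estimation of cigarette demand
#'
#' Estimates the log-log demand model
#' \eqn{\ln C_{it} = \beta_{1i} + \beta_2 \ln P_{it} + \beta_3 \ln GNI_{it} +
#' \beta_4 FCTC_{it} + \epsilon_{it}} by two-stage least squares on
#' within-transformed data, treating log price as endogenous and
#' instrumenting it with the previous year's log price and log CPI. The
#' first observation of each country is lost to lagging. Inference is
#' cluster-robust by country with the CR1 small-sample factor
#' \eqn{G/(G-1) \cdot (N-1)/(N-k)}, where k counts the slopes plus the
#' absorbed country intercepts.
#'
#' Diagnostics bundled with the fit: the within R-squared of the second
#' stage, the cluster-robust first-stage Wald F of the excluded instruments
#' (with one endogenous regressor this equals the Kleibergen-Paap rk Wald
#' F), and a Hausman fixed-vs-random effects test computed from the non-IV
#' within estimator and the Swamy-Arora random-effects GLS on the full
#' (unlagged) sample.
#'
#' @param panel a data.frame with columns `country`, `year`, `consumption`,
#'   `price`, `gni`, `fctc`, `cpi`; at least 3 years per retained country
#'   when instrumenting.
#' @param iv logical; `FALSE` gives the plain within (FE-OLS) estimator on
#'   the full sample, with the same cluster-robust inference.
#' @param instruments character vector of instrument columns for log price,
#'   default `c("lnP_lag", "lnCPI_lag")`. `"lnP"` (the regressor itself) is
#'   allowed, in which case 2SLS collapses to within-OLS and no observations
#'   are lost to lagging.
#' @param group_id optional label stored on the fit (income group).
#' @return an object of class `elasticity_fit`: coefficients `beta_price`,
#'   `beta_gni`, `beta_fctc`; per-country intercepts; cluster-robust `vcov`
#'   and `se`; `r_squared` (within); `weak_id_F`; `hausman_stat`,
#'   `hausman_df`, `hausman_p`; `n_obs`, `n_countries`.
#' @examples
#' pan <- generate_panel(panel_dgp_params(n_countries = 6, seed = 2))
#' fit <- fit_fe_2sls(pan)
#' fit
#' @export
fit_fe_2sls <- function(panel, iv = TRUE,
                        instruments = c("lnP_lag", "lnCPI_lag"),
                        group_id = NA) {
  d <- build_frame(panel)
  full <- d                                  # unlagged sample for Hausman
  needs_lag <- iv && any(grepl("_lag$", instruments))
  if (needs_lag)
    d <- d[stats::complete.cases(d[, instruments, drop = FALSE]), , drop = FALSE]

  tab <- table(d$country)
  short <- names(tab)[tab < 2]
  if (length(short)) {
    warning("dropping countries with too few observations after lagging: ",
            paste(short, collapse = ", "), call. = FALSE)
    d <- d[!(d$country %in% short), , drop = FALSE]
  }
  g <- factor(d$country)
  G <- nlevels(g)
  if (G < 2)
    stop("cluster-robust estimation requires at least 2 countries",
         call. = FALSE)

  xn <- c("lnP", "lnGNI", "fctc")
  X <- as.matrix(d[, xn])
  y <- d$lnC
  MX <- demean_mat(X, g)
  My <- y - stats::ave(y, g)

  if (iv) {
    zn <- unique(c(instruments, "lnGNI", "fctc"))
    MZ <- demean_mat(as.matrix(d[, zn, drop = FALSE]), g)
    qz <- qr(MZ)
    if (qz$rank < ncol(MZ))
      stop("instrument matrix is rank deficient after demeaning; ",
           "collinear columns: ",
           paste(zn[setdiff(seq_len(ncol(MZ)), qz$pivot[seq_len(qz$rank)])],
                 collapse = ", "), call. = FALSE)
    p_hat <- qr.fitted(qz, MX[, "lnP"])
    Xhat <- MX
    Xhat[, "lnP"] <- p_hat
  } else {
    Xhat <- MX
  }

  A <- crossprod(Xhat, MX)
  qa <- qr(A)
  if (qa$rank < ncol(A))
    stop("design matrix is rank deficient; collinear columns: ",
         paste(xn[setdiff(seq_len(ncol(A)), qa$pivot[seq_len(qa$rank)])],
               collapse = ", "), call. = FALSE)
  beta <- drop(solve(A, crossprod(Xhat, My)))
  names(beta) <- xn
  e <- drop(My - MX %*% beta)
  A_inv <- solve(A)
  V <- cluster_vcov(A_inv, Xhat, e, g, k_absorbed = G)
  dimnames(V) <- list(xn, xn)
  se <- sqrt(diag(V))
  r2 <- 1 - sum(e^2) / sum(My^2)

  # recover absorbed country intercepts on the estimation sample
  ybar <- as.vector(tapply(y, g, mean))
  xbar <- apply(X, 2, function(col) as.vector(tapply(col, g, mean)))
  intercepts <- stats::setNames(ybar - drop(as.matrix(xbar) %*% beta),
                                levels(g))

  wF <- if (iv) first_stage_F(d, g, instruments) else NA_real_

  fe0 <- fe_ols_conventional(full)
  re0 <- fit_re_gls(full)
  hm <- hausman_test(fe0, re0)

  structure(list(
    group_id = group_id,
    coefficients = c(beta_price = unname(beta["lnP"]),
                     beta_gni = unname(beta["lnGNI"]),
                     beta_fctc = unname(beta["fctc"])),
    intercepts = intercepts, vcov = V, se = stats::setNames(se, names(beta)),
    r_squared = r2, weak_id_F = wF,
    hausman_stat = hm$statistic, hausman_df = hm$df, hausman_p = hm$p_value,
    hausman_indefinite = hm$indefinite,
    n_obs = nrow(d), n_countries = G, iv = iv, residuals = e),
    class = "elasticity_fit")
}

# cluster-robust Wald F of the excluded instruments in the within first stage
first_stage_F <- function(d, g, instruments) {
  zn <- unique(c(instruments, "lnGNI", "fctc"))
  excl <- setdiff(instruments, c("lnGNI", "fctc"))
  MZ <- demean_mat(as.matrix(d[, zn, drop = FALSE]), g)
  Mp <- d$lnP - stats::ave(d$lnP, g)
  fs <- lm.fit(MZ, Mp)
  if (fs$rank < ncol(MZ))
    stop("instruments collinear after demeaning", call. = FALSE)
  gam <- fs$coefficients
  e1 <- fs$residuals
  if (sum(e1^2) < 1e-24 * max(1, sum(Mp^2)))
    return(1e6)                              # perfect relevance
  A_inv <- solve(crossprod(MZ))
  Vg <- cluster_vcov(A_inv, MZ, e1, g, k_absorbed = nlevels(g))
  idx <- match(excl, zn)
  Vsub <- Vg[idx, idx, drop = FALSE]
  W <- tryCatch(drop(t(gam[idx]) %*% solve(Vsub, gam[idx])),
                error = function(e) Inf)
  min(W / length(idx), 1e6)
}

# non-IV within estimator with conventional covariance (Hausman comparator)
fe_ols_conventional <- function(frame) {
  g <- factor(frame$country)
  xn <- c("lnP", "lnGNI", "fctc")
  MX <- demean_mat(as.matrix(frame[, xn]), g)
  My <- frame$lnC - stats::ave(frame$lnC, g)
  fit <- lm.fit(MX, My)
  beta <- fit$coefficients
  e <- fit$residuals
  N <- nrow(MX); G <- nlevels(g); k <- length(xn)
  dfres <- N - G - k
  s2 <- sum(e^2) / dfres
  V <- s2 * solve(crossprod(MX))
  dimnames(V) <- list(xn, xn)
  list(coefficients = stats::setNames(beta, xn), vcov = V, sigma2 = s2,
       df_residual = dfres)
}

# ---- random effects ---------------------------------------------------------

#' Random-effects GLS (Swamy-Arora) estimation of cigarette demand
#'
#' Estimates the demand model treating country intercepts as random draws
#' uncorrelated with the regressors, via feasible GLS with Swamy-Arora
#' variance components: the idiosyncratic variance comes from the within
#' residuals, the intercept variance from the between (group-means)
#' regression, and estimation proceeds by quasi-demeaning with
#' \eqn{\theta_i = 1 - \sqrt{\sigma^2_e / (T_i \sigma^2_u + \sigma^2_e)}}.
#' A negative between variance component is truncated at zero with a
#' warning. With zero between variance the estimator collapses to pooled
#' OLS; as the intercept variance grows, \eqn{\theta \to 1} and the slopes
#' approach the fixed-effects estimates. Serves as the comparator of the
#' Hausman specification test.
#'
#' @param panel a data.frame as in [fit_fe_2sls()].
#' @return an object of class `re_gls_fit` with `coefficients` (intercept
#'   and slopes), conventional `vcov` of the slopes, `theta` per country,
#'   and the variance components `sigma2_e`, `sigma2_u`.
#' @export
fit_re_gls <- function(panel) {
  frame <- if (all(c("lnC", "lnP", "lnGNI") %in% names(panel))) panel
           else build_frame(panel)
  g <- factor(frame$country)
  G <- nlevels(g)
  xn <- c("lnP", "lnGNI", "fctc")
  X <- as.matrix(frame[, xn])
  y <- frame$lnC
  Ti <- as.vector(table(g))
  N <- length(y); k <- length(xn)

  # within step
  MX <- demean_mat(X, g)
  My <- y - stats::ave(y, g)
  wfit <- lm.fit(MX, My)
  s2_e <- sum(wfit$residuals^2) / (N - G - k)

  # between step
  ybar <- tapply(y, g, mean)
  xbar <- apply(X, 2, function(col) tapply(col, g, mean))
  Bx <- cbind(1, as.matrix(xbar))
  bfit <- lm.fit(Bx, ybar)
  dfb <- G - (k + 1)
  s2_b <- if (dfb > 0) sum(bfit$residuals^2) / dfb else 0
  Tbar <- mean(Ti)
  s2_u <- s2_b - s2_e / Tbar
  if (s2_u < 0) {
    warning("negative estimated intercept variance component; truncated at 0",
            call. = FALSE)
    s2_u <- 0
  }
  denom <- Ti * s2_u + s2_e
  theta <- ifelse(denom > 0, 1 - sqrt(s2_e / denom), 0)
  th_obs <- theta[as.integer(g)]

  Xs <- cbind(`(Intercept)` = 1 - th_obs,
              X - th_obs * as.matrix(xbar)[as.integer(g), , drop = FALSE])
  ys <- y - th_obs * ybar[as.integer(g)]
  # pivoted QR: with theta = 1 (zero idiosyncratic variance) the quasi-
  # demeaned intercept column vanishes and is aliased, not an error
  qf <- qr(Xs)
  beta <- qr.coef(qf, ys)
  resid <- qr.resid(qf, ys)
  s2 <- sum(resid^2) / (N - qf$rank)
  keep <- qf$pivot[seq_len(qf$rank)]
  Vk <- s2 * chol2inv(qr.R(qf)[seq_len(qf$rank), seq_len(qf$rank),
                               drop = FALSE])
  Vfull <- matrix(NA_real_, ncol(Xs), ncol(Xs),
                  dimnames = list(colnames(Xs), colnames(Xs)))
  Vfull[keep, keep] <- Vk

  structure(list(coefficients = beta,
                 slopes = stats::setNames(beta[xn], xn),
                 vcov = Vfull[xn, xn, drop = FALSE], vcov_full = Vfull,
                 theta = stats::setNames(theta, levels(g)),
                 sigma2_e = s2_e, sigma2_u = s2_u,
                 n_obs = N, n_countries = G),
            class = "re_gls_fit")
}

#' Hausman fixed-vs-random effects specification test
#'
#' Compares the within (fixed-effects) slope estimates with the
#' random-effects GLS slopes: under the random-effects assumption (country
#' intercepts uncorrelated with the regressors) both are consistent and RE
#' is efficient, so \eqn{H = d' (V_{FE} - V_{RE})^{-1} d} with
#' \eqn{d = b_{FE} - b_{RE}} is asymptotically chi-squared with one degree
#' of freedom per compared slope. Rejection indicates the fixed-effects
#' estimates should be used. When the covariance difference is not positive
#' definite the Moore-Penrose pseudo-inverse is used and the result is
#' flagged `indefinite = TRUE` (reported, not hidden).
#'
#' @param fe fixed-effects fit: a list with `coefficients` and conventional
#'   `vcov` for the slopes (as from the internal within comparator), or an
#'   `elasticity_fit` estimated with `iv = FALSE`.
#' @param re a `re_gls_fit` from [fit_re_gls()].
#' @return list with `statistic`, `df`, `p_value`, `indefinite`.
#' @export
hausman_test <- function(fe, re) {
  b_fe <- if (inherits(fe, "elasticity_fit"))
    stats::setNames(fe$coefficients, c("lnP", "lnGNI", "fctc")) else fe$coefficients
  V_fe <- fe$vcov
  b_re <- if (inherits(re, "re_gls_fit")) re$slopes else re$coefficients
  V_re <- re$vcov
  common <- intersect(names(b_fe), names(b_re))
  d <- b_fe[common] - b_re[common]
  V <- V_fe[common, common, drop = FALSE] - V_re[common, common, drop = FALSE]
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  indefinite <- any(ev <= 1e-12 * max(abs(ev), 1e-300))
  Vinv <- if (!indefinite) solve(V) else pseudo_inverse(V)
  H <- drop(t(d) %*% Vinv %*% d)
  df <- length(common)
  p <- stats::pchisq(max(H, 0), df, lower.tail = FALSE)
  if (sum(abs(d)) == 0) { H <- 0; p <- 1 }
  list(statistic = H, df = df, p_value = p, indefinite = indefinite)
}

pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd((M + t(M)) / 2)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' First-stage weak-identification F statistic
#'
#' Cluster-robust Wald F of the excluded instruments (lagged log price and
#' lagged log CPI by default) in the within-transformed first-stage
#' regression of log price. With a single endogenous regressor this equals
#' the Kleibergen-Paap rk Wald F. Values well above 10 indicate relevant
#' instruments; the statistic is capped at 1e6 when the first stage fits
#' perfectly (instrument equal to the regressor).
#'
#' @inheritParams fit_fe_2sls
#' @return the F statistic (scalar).
#' @export
weak_id_F <- function(panel, instruments = c("lnP_lag", "lnCPI_lag")) {
  d <- build_frame(panel)
  needs_lag <- any(grepl("_lag$", instruments))
  if (needs_lag)
    d <- d[stats::complete.cases(d[, instruments, drop = FALSE]), , drop = FALSE]
  g <- factor(d$country)
  first_stage_F(d, g, instruments)
}

#' Estimate elasticities for every income cluster
#'
#' Splits the panel into income groups on reference-year GNI per capita
#' (see [assign_income_clusters()]) and fits the demand model within each
#' group. Groups left with fewer than two countries cannot support
#' cluster-robust estimation and are skipped with a warning.
#'
#' @inheritParams fit_fe_2sls
#' @param reference_year year whose GNI defines the clustering (default the
#'   last year in the panel).
#' @return named list of `elasticity_fit` objects, one per populated group.
#' @export
fit_by_group <- function(panel, iv = TRUE, reference_year = max(panel$year)) {
  ref <- panel[panel$year == reference_year, c("country", "gni")]
  missing <- setdiff(unique(panel$country), ref$country)
  if (length(missing))
    stop("missing GNI for country: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cl <- assign_income_clusters(stats::setNames(ref$gni, ref$country))
  fits <- list()
  for (gid in sort(unique(cl$group_id))) {
    members <- cl$country[cl$group_id == gid]
    sub <- panel[panel$country %in% members, , drop = FALSE]
    f <- tryCatch(fit_fe_2sls(sub, iv = iv, group_id = gid),
                  error = function(e) {
                    warning(sprintf("group %d skipped: %s", gid,
                                    conditionMessage(e)), call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) fits[[paste0("group", gid)]] <- f
  }
  fits
}

#' @export
print.elasticity_fit <- function(x, digits = 4, ...) {
  stars <- ifelse(2 * stats::pnorm(-abs(x$coefficients / x$se)) < 0.05,
                  "**", "")
  cat("Fixed-effects", if (x$iv) "2SLS" else "OLS",
      "cigarette demand fit")
  if (!is.na(x$group_id)) cat(" (income group ", x$group_id, ")", sep = "")
  cat("\n")
  tab <- data.frame(estimate = round(x$coefficients, digits),
                    se = round(x$se, digits), sig = stars)
  rownames(tab) <- c("ln price", "ln GNI", "FCTC")
  print(tab)
  cat(sprintf("within R^2 = %.3f; weak-id F = %s; Hausman chi^2(%d) = %.2f (p = %.3g)%s\n",
              x$r_squared,
              if (is.na(x$weak_id_F)) "NA" else format(round(x$weak_id_F, 2)),
              x$hausman_df, x$hausman_stat, x$hausman_p,
              if (isTRUE(x$hausman_indefinite)) " [indefinite covariance]" else ""))
  cat(sprintf("n = %d observations, %d countries\n", x$n_obs, x$n_countries))
  invisible(x)
}

#' @export
print.re_gls_fit <- function(x, digits = 4, ...) {
  cat("Random-effects GLS (Swamy-Arora) fit\n")
  print(round(x$slopes, digits))
  cat(sprintf("sigma2_e = %.4g, sigma2_u = %.4g, theta in [%.3f, %.3f]\n",
              x$sigma2_e, x$sigma2_u, min(x$theta), max(x$theta)))
  invisible(x)
}
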