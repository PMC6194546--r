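# shared fixture builders; everything is generated in code at test time

# a small noisy panel for oracle-equivalence tests
small_panel <- function(n = 5, years = 2000:2009, seed = 42, ...) {
  generate_panel(panel_dgp_params(n_countries = n, years = years,
                                  seed = seed, ...))
}

# log frame with lags, as used internally by the estimator
frame_of <- function(panel) cigtaxsim:::build_frame(panel)

# non-IV within comparator with conventional vcov (Hausman input)
fe_conventional <- function(panel) {
  cigtaxsim:::fe_ols_conventional(frame_of(panel))
}

# rescale one country's GNI path by a constant factor: the demand model stays
# exact with the shift absorbed into that country's intercept, so group
# structure can be imposed on a generated panel without breaking the DGP
retarget_gni <- function(panel, targets) {
  last <- max(panel$year)
  for (ctry in names(targets)) {
    cur <- panel$gni[panel$country == ctry & panel$year == last]
    panel$gni[panel$country == ctry] <-
      panel$gni[panel$country == ctry] * targets[[ctry]] / cur
  }
  panel
}

expect_no_na <- function(x) expect_false(anyNA(x))
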