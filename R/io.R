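#' Read a country-year panel CSV
#'
#' Expects the header `country,year,consumption,price,gni,fctc,cpi`.
#' Rows are validated on load: consumption, price, GNI and CPI must be
#' strictly positive (the demand model is estimated in logs), FCTC must be
#' 0/1, and duplicate (country, year) pairs are rejected. Errors name the
#' offending line (header = line 1).
#'
#' @param path CSV file path.
#' @return validated panel data.frame.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "year", "consumption", "price", "gni", "fctc", "cpi")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("panel CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  line <- seq_len(nrow(d)) + 1L
  for (v in c("consumption", "price", "gni", "cpi")) {
    bad <- which(!is.finite(d[[v]]) | d[[v]] <= 0)
    if (length(bad))
      stop(sprintf("line %d: column '%s' must be strictly positive (got %s)",
                   line[bad[1]], v, d[[v]][bad[1]]), call. = FALSE)
  }
  bad <- which(!(d$fctc %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("line %d: fctc must be 0 or 1", line[bad[1]]), call. = FALSE)
  dup <- which(duplicated(d[c("country", "year")]))
  if (length(dup))
    stop(sprintf("line %d: duplicate (country, year) pair (%s, %s)",
                 line[dup[1]], d$country[dup[1]], d$year[dup[1]]),
         call. = FALSE)
  d
}

fmt_full <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- ""
    trimws(out)
  } else {
    out <- as.character(x)
    out[is.na(x)] <- ""
    out
  }
}

write_csv_full <- function(d, path) {
  out <- d
  for (j in seq_along(out)) out[[j]] <- fmt_full(out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a panel or policy table to CSV at full float precision
#'
#' Numeric columns are written with 17 significant digits so that a write /
#' read round trip reproduces every double exactly; writing is
#' deterministic, so regenerating with the same seed yields byte-identical
#' files.
#'
#' @param panel,policy the data.frame to write.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_panel <- function(panel, path) {
  check_panel(panel)
  write_csv_full(panel[, c("country", "year", "consumption", "price",
                           "gni", "fctc", "cpi")], path)
}

#' @rdname write_panel
#' @export
write_policy_table <- function(policy, path) write_csv_full(policy, path)

#' Read a country policy table CSV
#'
#' Expects columns `country`, `specific_share`, `advalorem_share`,
#' `prevalence`, `pop15plus` and the five age-share columns (all fractions,
#' not percent). Missing excise shares are allowed (undefined revenue
#' baseline) and surface as `NA`, never as 0.
#'
#' @param path CSV file path.
#' @return validated policy data.frame.
#' @export
load_policy_table <- function(path) {
  if (!file.exists(path)) stop("policy file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "specific_share", "advalorem_share", "prevalence",
            "pop15plus", "share_15_29", "share_30_39", "share_40_49",
            "share_50_59", "share_60plus")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("policy CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tot <- d$specific_share + d$advalorem_share
  if (any(!is.na(tot) & (tot < 0 | tot > 1)))
    stop("total excise share outside [0,1] for country: ",
         paste(d$country[!is.na(tot) & (tot < 0 | tot > 1)], collapse = ", "),
         call. = FALSE)
  sh <- as.matrix(d[, c("share_15_29", "share_30_39", "share_40_49",
                        "share_50_59", "share_60plus")])
  bad <- which(abs(rowSums(sh) - 1) > 1e-6)
  if (length(bad))
    stop("age shares do not sum to 1 for country: ",
         paste(d$country[bad], collapse = ", "), call. = FALSE)
  d
}

#' Pipeline run configuration
#'
#' Collects the choices of an end-to-end run. Two input modes exist:
#' `panel = "synthetic"` generates a panel (and policy table) with the
#' given seed, estimates elasticities per income group and simulates
#' price-rise scenarios computed from each country's own generated price
#' history; `panel = "builtin"` skips estimation and runs the simulator on
#' the bundled Asia-Pacific inputs, group elasticities and published
#' price increments. File paths may be given instead to use external CSVs.
#'
#' @param panel `"builtin"`, `"synthetic"`, or a panel CSV path.
#' @param policy `"builtin"`, `"synthetic"`, or a policy CSV path.
#' @param elasticities `"builtin"` (bundled group estimates), `"fit"`
#'   (estimate from the panel), or a named numeric vector by country.
#' @param scenarios scenario kinds, subset of `c("mean", "max")`.
#' @param positive_only_increments mean increment over positive changes
#'   only?
#' @param iv instrument price with its lag and lagged CPI when estimating?
#' @param aggregation regional aggregation method, `"unweighted"` or
#'   `"weighted"`.
#' @param seed integer seed for synthetic generation.
#' @param out_dir directory for artifacts (`fit.json`, `simulation.csv`,
#'   `report.md`); `NULL` writes nothing.
#' @param dgp optional list of [panel_dgp_params()] overrides for
#'   synthetic generation.
#' @return a `run_config` list.
#' @export
run_config <- function(panel = "builtin", policy = "builtin",
                       elasticities = "builtin",
                       scenarios = c("mean", "max"),
                       positive_only_increments = FALSE, iv = TRUE,
                       aggregation = "unweighted", seed = 1L,
                       out_dir = NULL, dgp = list()) {
  stopifnot(all(scenarios %in% c("mean", "max")))
  structure(list(panel = panel, policy = policy, elasticities = elasticities,
                 scenarios = scenarios,
                 positive_only_increments = isTRUE(positive_only_increments),
                 iv = isTRUE(iv), aggregation = aggregation,
                 seed = as.integer(seed), out_dir = out_dir, dgp = dgp),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return a `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the end-to-end pipeline
#'
#' `synth/load -> estimate -> simulate -> report`. Every stage error is
#' re-signalled with its stage name; every dropped observation or
#' undefined cell is logged to stderr; identical configuration and seed
#' give identical artifacts.
#'
#' @param config a [run_config()] object or the path to a YAML file.
#' @return invisibly, a list with the fits (if any), the outcome table,
#'   the regional aggregate, and the artifact paths.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  fits <- NULL
  panel <- NULL
  if (identical(config$panel, "synthetic")) {
    panel <- stage("synth", {
      p <- do.call(panel_dgp_params, c(config$dgp, list(seed = config$seed)))
      generate_panel(p)
    })
    pipeline_log("synth", "generated %d rows (%d countries)",
                 nrow(panel), length(unique(panel$country)))
  } else if (!identical(config$panel, "builtin")) {
    panel <- stage("load", load_panel(config$panel))
    pipeline_log("load", "read %d panel rows from %s", nrow(panel),
                 config$panel)
  }

  # policy inputs
  policy <- stage("load", {
    if (identical(config$policy, "builtin")) apac_country_inputs()
    else if (identical(config$policy, "synthetic")) {
      n <- length(unique(panel$country))
      pt <- generate_policy_table(n, seed = config$seed + 1L)
      pt$country <- sort(unique(panel$country))
      pt
    } else load_policy_table(config$policy)
  })

  # elasticities
  est <- stage("estimate", {
    if (is.numeric(config$elasticities))
      list(el = config$elasticities, fits = NULL)
    else if (identical(config$elasticities, "builtin"))
      list(el = apac_country_elasticities(), fits = NULL)
    else if (identical(config$elasticities, "fit")) {
      if (is.null(panel))
        stop("elasticities = 'fit' requires a panel", call. = FALSE)
      fits <- fit_by_group(panel, iv = config$iv)
      cl <- assign_income_clusters(stats::setNames(
        panel$gni[panel$year == max(panel$year)],
        panel$country[panel$year == max(panel$year)]))
      bp <- vapply(fits, function(f) f$coefficients[["beta_price"]],
                   numeric(1))
      got <- cl$group_id %in% as.integer(sub("group", "", names(fits)))
      if (any(!got))
        pipeline_log("estimate", "no elasticity fit for country: %s",
                     paste(cl$country[!got], collapse = ", "))
      list(el = stats::setNames(bp[paste0("group", cl$group_id)], cl$country),
           fits = fits)
    } else stop("unknown elasticities source", call. = FALSE)
  })
  el <- est$el
  fits <- est$fits

  # scenarios
  scen <- stage("simulate", {
    if (is.null(panel)) {
      sc <- apac_price_scenarios()
      sc[sc$kind %in% config$scenarios, , drop = FALSE]
    } else {
      rows <- lapply(split(panel, panel$country), function(d) {
        inc <- historical_increments(d$price, d$year,
                                     config$positive_only_increments)
        data.frame(country = d$country[1],
                   kind = c("mean", "max"),
                   dP = c(inc$mean, inc$max), stringsAsFactors = FALSE)
      })
      sc <- do.call(rbind, rows)
      rownames(sc) <- NULL
      sc[sc$kind %in% config$scenarios & sc$dP > -1, , drop = FALSE]
    }
  })
  scen <- scen[!is.na(el[scen$country]), , drop = FALSE]

  outcomes <- stage("simulate", simulate_policy(policy, el, scen))
  undef <- outcomes$country[is.na(outcomes$dRevenue)]
  if (length(undef))
    pipeline_log("simulate", "undefined revenue baseline for: %s",
                 paste(unique(undef), collapse = ", "))
  agg <- stage("simulate",
               aggregate_region(outcomes, method = config$aggregation))

  paths <- list()
  if (!is.null(config$out_dir)) {
    stage("report", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      paths$simulation <- file.path(config$out_dir, "simulation.csv")
      write_csv_full(outcomes, paths$simulation)
      if (!is.null(fits)) {
        paths$fit <- file.path(config$out_dir, "fit.json")
        jsonlite::write_json(lapply(fits, fit_record), paths$fit,
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
      paths$report <- file.path(config$out_dir, "report.md")
      writeLines(render_report(outcomes, agg), paths$report)
    })
    pipeline_log("report", "artifacts written to %s", config$out_dir)
  }
  invisible(list(fits = fits, outcomes = outcomes, aggregate = agg,
                 paths = paths))
}

fit_record <- function(f) {
  list(group_id = f$group_id,
       beta_price = f$coefficients[["beta_price"]],
       beta_gni = f$coefficients[["beta_gni"]],
       beta_fctc = f$coefficients[["beta_fctc"]],
       se = as.list(f$se), r_squared = f$r_squared,
       weak_id_F = f$weak_id_F, hausman_stat = f$hausman_stat,
       hausman_df = f$hausman_df, hausman_p = f$hausman_p,
       n_obs = f$n_obs, n_countries = f$n_countries,
       intercepts = as.list(f$intercepts))
}

#' Render simulation outcomes as a markdown table
#'
#' Percent quantities are multiplied by 100 and rounded to two decimals
#' only here, at the reporting layer; undefined revenue changes render as
#' "-". Person counts are rounded to whole persons.
#'
#' @param outcomes a `sim_outcome` data.frame.
#' @param aggregate optional regional aggregate row(s) from
#'   [aggregate_region()].
#' @return character vector of markdown lines.
#' @export
render_report <- function(outcomes, aggregate = NULL) {
  pct <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", 100 * x))
  per <- function(x) ifelse(is.na(x), "-", format(round(x), big.mark = ",",
                                                  scientific = FALSE))
  row_of <- function(d, label)
    sprintf("| %s | %s | %s | %s | %s | %s | %s |", label, d$kind,
            pct(d$dP), pct(d$dC), pct(d$dRevenue),
            per(-d$smoker_reduction), per(-d$sads_averted))
  lines <- c(
    "| Country | Scenario | Price +% | Consumption % | Revenue % | Smokers | SADs |",
    "|---|---|---|---|---|---|---|",
    unlist(lapply(seq_len(nrow(outcomes)), function(i)
      row_of(outcomes[i, ], outcomes$country[i]))))
  if (!is.null(aggregate))
    lines <- c(lines,
               unlist(lapply(seq_len(nrow(aggregate)), function(i)
                 row_of(aggregate[i, ], sprintf("All %d countries",
                                                aggregate$n_countries[i])))))
  lines
}
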