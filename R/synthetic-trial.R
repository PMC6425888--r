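#' Provenance parameters for the trial simulator
#'
#' Ground-truth description of one seed-origin population: how its radial
#' growth responds to monthly climate anomalies, its baseline growth level,
#' the speed of its juvenile age trend, and how much trees within the
#' provenance differ in level.
#'
#' @param id Provenance label.
#' @param response Climate-response weight vector of length 24: weights on the
#'   12 standardized monthly temperature anomalies followed by the 12
#'   standardized monthly precipitation anomalies (dimensionless). Its norm
#'   sets the interannual growth signal amplitude on the log scale.
#' @param baseline Baseline ring width, mm (> 0).
#' @param decay Negative-exponential age-trend decay rate, 1/year.
#' @param tree_sd Log-scale standard deviation of tree-level growth level
#'   within the provenance.
#' @return An object of class `provenance_params`.
#' @export
provenance_params <- function(id, response, baseline = 3, decay = 0.05,
                              tree_sd = 0.1) {
  if (!is.numeric(response) || length(response) != 24L ||
      any(!is.finite(response))) {
    stop_arg("`response` must be 24 finite weights (12 temperature + 12 precipitation)")
  }
  if (baseline <= 0) stop_arg("baseline growth must be > 0")
  structure(list(id = as.character(id), response = as.numeric(response),
                 baseline = baseline, decay = decay, tree_sd = tree_sd),
            class = "provenance_params")
}

#' Default set of distinct provenance response profiles
#'
#' Every provenance shares a common base response (growth favoured by
#' growing-season moisture, disfavoured by summer heat) -- the shared stand
#' signal of a conifer trial -- plus a provenance-specific deviation placed
#' on a semicircle in the plane spanned by a summer-temperature pattern and
#' a growing-season precipitation pattern:
#' `w_p = common * base + amplitude * (cos(theta_p) u_T + sin(theta_p) u_P)`
#' with `theta_p = pi (p-1)/n`. Neighbouring provenances deviate similarly,
#' distant ones differently, giving a graded, known differentiation
#' structure on top of a positive within-site common signal.
#'
#' @param n Number of provenances.
#' @param amplitude Norm of the provenance-specific deviation; the
#'   interannual log-scale growth s.d. attributable to provenance identity.
#' @param common Norm of the shared base response.
#' @return List of `provenance_params`.
#' @export
default_provenances <- function(n = 10, amplitude = 0.15, common = 0.3) {
  u_t <- stats::dnorm(1:12, mean = 7, sd = 1.5)   # summer temperature pattern
  u_t <- u_t / sqrt(sum(u_t^2))
  u_p <- stats::dnorm(1:12, mean = 6, sd = 2.0)   # growing-season precipitation
  u_p <- u_p / sqrt(sum(u_p^2))
  # shared base: wet growing season helps, hot summer hurts
  base <- c(-0.6 * u_t, 0.8 * u_p)
  base <- base / sqrt(sum(base^2))
  # deviation patterns orthogonal to the base within each block
  d_t <- stats::dnorm(1:12, mean = 4.5, sd = 1.5)  # spring temperature
  d_t <- d_t / sqrt(sum(d_t^2))
  d_p <- stats::dnorm(1:12, mean = 8.5, sd = 1.5)  # late-summer precipitation
  d_p <- d_p / sqrt(sum(d_p^2))
  lapply(seq_len(n), function(p) {
    th <- pi * (p - 1) / n
    w <- common * base + amplitude * c(cos(th) * d_t, sin(th) * d_p)
    provenance_params(sprintf("P%02d", p), w)
  })
}

#' Trial configuration
#'
#' @param trees_per_provenance Trees sampled per provenance (>= 2).
#' @param years Years simulated (>= 15).
#' @param marginality Limiting-factor strength in \[0, 1\]: 0 = growth driven
#'   purely by each provenance's own climate response; 1 = all trees share the
#'   site's water-limited growth signal (Liebig-type limitation).
#' @param noise_sd Residual log-scale noise s.d. per tree and year.
#' @param seed Master integer seed; per-tree sub-seeds are spawned from it so
#'   each tree's draw is individually reproducible.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(trees_per_provenance = 15, years = 40,
                         marginality = 0.5, noise_sd = 0.15, seed = 1L) {
  if (trees_per_provenance < 2) stop_arg("need >= 2 trees per provenance")
  if (years < 15) stop_arg("need >= 15 simulated years")
  if (marginality < 0 || marginality > 1) {
    stop_arg("marginality must lie in [0, 1]")
  }
  structure(list(trees_per_provenance = as.integer(trees_per_provenance),
                 years = as.integer(years), marginality = marginality,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "trial_config")
}

# Standardized monthly anomaly matrix (years x 24): per calendar month,
# z-scores of Tmean then precipitation. Constant months map to 0.
climate_anomaly_matrix <- function(climate, years) {
  z <- matrix(0, length(years), 24L)
  for (m in 1:12) {
    sub <- climate[climate$month == m & climate$year %in% years, ]
    sub <- sub[match(years, sub$year), ]
    for (j in 1:2) {
      v <- if (j == 1) sub$tmean else sub$prec
      s <- stats::sd(v)
      z[, (j - 1) * 12 + m] <- if (is.na(s) || s == 0) 0 else (v - mean(v)) / s
    }
  }
  z
}

# Site-level water-limited growth signal on the log scale: standardized
# May--August climatic water balance, capped above (good water years cannot
# raise growth past a ceiling: Liebig limitation acts through the deficit).
water_limit_signal <- function(climate, years, gamma_w = 0.35, cap = 0.5) {
  pet <- monthly_pet(climate)
  d <- climate$prec - pet$pet
  gs <- climate$month %in% 5:8
  wb <- tapply(d[gs], climate$year[gs], sum)
  wb <- wb[as.character(years)]
  s <- stats::sd(wb)
  z <- if (is.na(s) || s == 0) rep(0, length(years)) else (wb - mean(wb)) / s
  gamma_w * pmin(z, cap)
}

#' Simulate a provenance trial at one site
#'
#' Each tree's annual ring width is
#' `age_trend * exp((1 - m) * g_p + m * L + eps)`, where `g_p` is the
#' provenance-specific weighted climate term, `L` is the site's capped
#' water-balance signal shared by all trees, `m` is the marginality blending
#' weight, and `eps` is per-tree noise. Widths are rounded to 0.01 mm
#' (measurement precision) and floored at 0.01 mm so they stay positive.
#'
#' @param climate A `monthly_climate` table covering at least
#'   `config$years` complete years.
#' @param provenances List of `provenance_params` (>= 2).
#' @param config A `trial_config`.
#' @return A `provenance_trial` list: `rwl` (wide data frame, years x series,
#'   mm), `meta` (series, tree, provenance, site), and `truth` (every
#'   parameter and per-tree sub-seed needed to reconstruct the draw).
#' @export
simulate_provenance_trial <- function(climate, provenances, config) {
  stopifnot(inherits(config, "trial_config"))
  if (length(provenances) < 2) stop_arg("need >= 2 provenances")
  ok <- vapply(provenances, inherits, logical(1), "provenance_params")
  if (!all(ok)) stop_arg("`provenances` must be a list of provenance_params")
  yrs <- complete_years(climate)
  if (length(yrs) < config$years) {
    stop_arg("climate spans %d complete years but %d are to be simulated",
             length(yrs), config$years)
  }
  yrs <- yrs[seq_len(config$years)]
  site <- attr(climate, "site")
  z <- climate_anomaly_matrix(climate, yrs)
  lim <- water_limit_signal(climate, yrs)
  m <- config$marginality

  n_trees <- config$trees_per_provenance
  ids <- character(0)
  cols <- list()
  meta <- list()
  tree_seeds <- with_seed(config$seed, {
    sample.int(.Machine$integer.max - 1L,
               length(provenances) * n_trees)
  })
  k <- 0L
  age <- seq_len(config$years)
  for (p in seq_along(provenances)) {
    pp <- provenances[[p]]
    g <- as.vector(z %*% pp$response)
    trend <- pp$baseline * (0.3 + 0.7 * exp(-pp$decay * age))
    for (tr in seq_len(n_trees)) {
      k <- k + 1L
      draw <- with_seed(tree_seeds[k], {
        list(scale = exp(stats::rnorm(1, 0, pp$tree_sd)),
             eps = stats::rnorm(config$years, 0, config$noise_sd))
      })
      u <- (1 - m) * g + m * lim + draw$eps
      w <- round(trend * draw$scale * exp(u), 2)
      w <- pmax(w, 0.01)
      id <- sprintf("%s_%02d", pp$id, tr)
      ids <- c(ids, id)
      cols[[id]] <- w
      meta[[id]] <- data.frame(series = id, tree = tr, provenance = pp$id,
                               site = site, stringsAsFactors = FALSE)
    }
  }
  rwl <- as.data.frame(cols, check.names = FALSE)
  rownames(rwl) <- yrs
  truth <- list(seed = config$seed, site = site, config = unclass(config),
                marginality = m,
                provenances = lapply(provenances, unclass),
                tree_seeds = stats::setNames(tree_seeds, ids),
                years = yrs)
  structure(list(rwl = rwl, meta = do.call(rbind, c(meta, make.row.names = FALSE)),
                 truth = truth),
            class = "provenance_trial")
}

#' Canned simulation scenarios
#'
#' Three named scenarios sharing one simulated climate (the drought-prone
#' default site):
#' * `"null"` -- all provenances carry one identical parameter record
#'   (no genetic differentiation; marginality 0.5);
#' * `"divergent-mild"` -- distinct response profiles, marginality 0.1
#'   (a mild site where provenance identity drives growth);
#' * `"uniform-marginal"` -- the *same* provenance list, marginality 0.9
#'   (a marginal site where the shared water limitation dominates).
#'
#' The mild and marginal scenarios use the same trial seed, so they are a
#' matched pair differing only in the marginality blending weight.
#'
#' @param seed Integer seed for the whole bundle.
#' @param n_provenances,trees_per_provenance,years Scenario dimensions.
#' @param marginality_mild,marginality_marginal Blending weights of the two
#'   contrasted scenarios.
#' @return Named list of scenarios, each with `climate`, `rwl`, `meta`,
#'   `truth`.
#' @export
make_fixture_suite <- function(seed, n_provenances = 10,
                               trees_per_provenance = 15, years = 40,
                               marginality_mild = 0.1,
                               marginality_marginal = 0.9) {
  site <- default_sites()$DRY
  climate <- simulate_site_climate(site, years, seed = seed)
  provs <- default_provenances(n_provenances)
  null_provs <- lapply(seq_len(n_provenances), function(p) {
    q <- provs[[1]]
    provenance_params(sprintf("P%02d", p), q$response, q$baseline, q$decay,
                      q$tree_sd)
  })
  cfg <- function(m, s) trial_config(trees_per_provenance, years,
                                     marginality = m, seed = s)
  scen <- function(tr) list(climate = climate, rwl = tr$rwl, meta = tr$meta,
                            truth = tr$truth)
  list(
    "null" = scen(simulate_provenance_trial(climate, null_provs,
                                            cfg(0.5, seed + 1L))),
    "divergent-mild" = scen(simulate_provenance_trial(climate, provs,
                                                      cfg(marginality_mild, seed + 2L))),
    "uniform-marginal" = scen(simulate_provenance_trial(climate, provs,
                                                        cfg(marginality_marginal, seed + 2L)))
  )
}
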