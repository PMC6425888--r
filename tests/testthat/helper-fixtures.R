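# Shared fixture builders. Everything is generated in code at test time.

# A small two-provenance trial with orthogonal climate responses.
make_small_trial <- function(seed = 11, marginality = 0, trees = 8,
                             years = 35, noise_sd = 0.15) {
  site <- default_sites()$DRY
  climate <- simulate_site_climate(site, years, seed = seed)
  provs <- default_provenances(10)[c(1, 6)]   # theta 0 and pi/2: orthogonal
  trial <- simulate_provenance_trial(
    climate, provs,
    trial_config(trees, years, marginality = marginality,
                 noise_sd = noise_sd, seed = seed + 1))
  list(climate = climate, trial = trial)
}

# Random ring-width collection for I/O round trips: representable widths,
# varying start years (including mid-decade), varying lengths.
make_random_rwl <- function(seed, n_series = 4, precision = 0.01) {
  with_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    expr
  }
  with_seed(seed, {
    first <- sample(1950:1984, n_series, replace = TRUE)
    len <- sample(12:60, n_series, replace = TRUE)
    last <- max(first + len - 1)
    years <- min(first):last
    m <- matrix(NA_real_, length(years), n_series,
                dimnames = list(years, sprintf("SER%03d", seq_len(n_series))))
    for (j in seq_len(n_series)) {
      rows <- (first[j]:(first[j] + len[j] - 1)) - min(first) + 1
      m[rows, j] <- round(stats::runif(len[j], 0.2, 6), -log10(precision))
    }
    as.data.frame(m, check.names = FALSE)
  })
}

# Fabricated single-tree RWI panel (values near 1) for pointer-year tests:
# `depressions` is a named list year -> list(factor, frac_trees, provenances).
make_rwi_panel <- function(seed, n_prov = 10, trees = 10, years = 1961:2000,
                           noise_sd = 0.05, depressions = list()) {
  set.seed(seed)
  ids <- c()
  meta <- list()
  cols <- list()
  for (p in seq_len(n_prov)) {
    prov <- sprintf("P%02d", p)
    for (tr in seq_len(trees)) {
      id <- sprintf("%s_%02d", prov, tr)
      v <- 1 + stats::rnorm(length(years), 0, noise_sd)
      names(v) <- years
      for (dy in names(depressions)) {
        d <- depressions[[dy]]
        if (prov %in% d$provenances && tr <= ceiling(d$frac_trees * trees)) {
          v[dy] <- v[dy] * d$factor
        }
      }
      ids <- c(ids, id)
      cols[[id]] <- v
      meta[[id]] <- data.frame(series = id, tree = tr, provenance = prov,
                               site = "S1", stringsAsFactors = FALSE)
    }
  }
  rwi <- as.data.frame(cols, check.names = FALSE)
  rownames(rwi) <- years
  list(rwi = rwi, meta = do.call(rbind, c(meta, make.row.names = FALSE)))
}

# Constant climate table builder.
make_constant_climate <- function(tmean = 10, prec = 50, years = 1981:2000,
                                  latitude = 52, site = "CONST",
                                  diurnal_half = 4.5) {
  df <- expand.grid(month = 1:12, year = years)
  df <- df[order(df$year, df$month), ]
  monthly_climate(data.frame(year = df$year, month = df$month,
                             tmean = tmean, tmax = tmean + diurnal_half,
                             tmin = tmean - diurnal_half, prec = prec),
                  site = site, latitude = latitude)
}
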