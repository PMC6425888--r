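#' Site climate parameters for the weather generator
#'
#' Bundles the monthly climate normals and interannual variability of one
#' trial site. Temperature anomalies are additive Gaussian; precipitation is
#' drawn from a gamma distribution around the monthly normal (keeping P >= 0);
#' drought years occur with a fixed annual probability and impose a
#' multiplicative May--August precipitation reduction plus a summer warming
#' bump, mimicking the summer-drought regime that distinguishes a
#' drought-prone from a mild-moist trial site.
#'
#' @param site Site label (e.g. `"MOIST"`, `"DRY"`).
#' @param latitude Site latitude in decimal degrees.
#' @param t_norm Monthly mean-temperature normals, 12 values, degrees C.
#' @param p_norm Monthly precipitation normals, 12 values, mm (all >= 0).
#' @param t_sd Interannual temperature standard deviation, degrees C.
#' @param p_disp Precipitation dispersion: coefficient of variation of the
#'   gamma draw around each monthly normal (0 = no variability).
#' @param drought_freq Probability per year of a drought year, in \[0, 1\].
#' @param drought_severity Fractional May--August precipitation reduction in a
#'   drought year, in \[0, 1\].
#' @param diurnal_half Half of the assumed diurnal temperature range, degrees C:
#'   Tmax = Tmean + `diurnal_half`, Tmin = Tmean - `diurnal_half`.
#' @return An object of class `site_climate_params`.
#' @export
site_climate_params <- function(site, latitude, t_norm, p_norm,
                                t_sd = 0.8, p_disp = 0.35,
                                drought_freq = 0.15, drought_severity = 0.35,
                                diurnal_half = 4.5) {
  if (length(t_norm) != 12L || length(p_norm) != 12L) {
    stop_arg("monthly normals must have exactly 12 entries")
  }
  if (any(p_norm < 0)) stop_arg("precipitation normals must be >= 0")
  if (drought_freq < 0 || drought_freq > 1) {
    stop_arg("drought_freq must lie in [0, 1]")
  }
  if (drought_severity < 0 || drought_severity > 1) {
    stop_arg("drought_severity must lie in [0, 1]")
  }
  structure(list(site = site, latitude = latitude,
                 t_norm = as.numeric(t_norm), p_norm = as.numeric(p_norm),
                 t_sd = t_sd, p_disp = p_disp,
                 drought_freq = drought_freq,
                 drought_severity = drought_severity,
                 diurnal_half = diurnal_half),
            class = "site_climate_params")
}

#' Default two-site contrast used throughout the package
#'
#' A mild, moist north-eastern lowland site (`"MOIST"`) and a relatively
#' drought-prone western site (`"DRY"`) with lower summer precipitation,
#' warmer summers, and more frequent and severe drought years. The normals are
#' plausible for the Central European lowland range of Norway spruce.
#'
#' @return Named list of two `site_climate_params`.
#' @export
default_sites <- function() {
  list(
    MOIST = site_climate_params(
      site = "MOIST", latitude = 53.3,
      t_norm = c(-4, -3, 1, 7, 13, 16, 18, 17, 12, 7, 2, -2),
      p_norm = c(30, 25, 30, 35, 58, 72, 78, 66, 52, 42, 38, 35),
      t_sd = 0.8, p_disp = 0.30,
      drought_freq = 0.10, drought_severity = 0.30),
    DRY = site_climate_params(
      site = "DRY", latitude = 52.2,
      t_norm = c(-1, 0, 3, 8, 14, 17, 19, 18, 13, 8, 3, 0),
      p_norm = c(28, 24, 28, 30, 46, 56, 64, 54, 42, 32, 32, 30),
      t_sd = 0.9, p_disp = 0.35,
      drought_freq = 0.25, drought_severity = 0.45)
  )
}

#' Construct a validated monthly climate table
#'
#' @param df Data frame with columns `year`, `month`, `tmean`, `tmax`,
#'   `tmin`, `prec`.
#' @param site Site label.
#' @param latitude Latitude in decimal degrees.
#' @return A `monthly_climate` data frame (attributes `site`, `latitude`).
#' @export
monthly_climate <- function(df, site, latitude) {
  need <- c("year", "month", "tmean", "tmax", "tmin", "prec")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_arg("missing climate columns: %s",
                             paste(miss, collapse = ", "))
  if (any(df$month < 1 | df$month > 12)) {
    stop_arg("month out of range 1..12")
  }
  bad <- which(df$tmax < df$tmin)
  if (length(bad)) {
    stop_arg("tmax < tmin in rows: %s",
             paste(utils::head(bad, 10), collapse = ", "))
  }
  if (any(df$prec < 0)) stop_arg("negative precipitation")
  df <- df[order(df$year, df$month), need, drop = FALSE]
  rownames(df) <- NULL
  structure(df, site = site, latitude = latitude,
            class = c("monthly_climate", "data.frame"))
}

#' Years of a monthly climate table that have all 12 months
#' @param climate A `monthly_climate` table.
#' @return Integer vector of complete years.
#' @export
complete_years <- function(climate) {
  tab <- table(climate$year)
  as.integer(names(tab)[tab == 12L])
}

#' Simulate monthly climate for one site
#'
#' Draws `years` years of monthly Tmean/Tmax/Tmin/precipitation around the
#' site normals. A shared annual temperature anomaly plus independent monthly
#' noise perturbs temperature; precipitation follows a gamma distribution with
#' the monthly normal as mean and CV `p_disp`. Drought years (Bernoulli with
#' probability `drought_freq`) reduce May--August precipitation by
#' `drought_severity` and warm those months by 1.5 degrees C. The drought-year
#' flags are recorded in attribute `drought_years`.
#'
#' @param params A `site_climate_params` object.
#' @param years Number of years to simulate (>= 1).
#' @param seed Integer seed; identical `params` + `seed` reproduce identical
#'   output.
#' @param first_year Calendar year of the first simulated year.
#' @return A `monthly_climate` table with attribute `drought_years` (logical,
#'   one per year).
#' @export
simulate_site_climate <- function(params, years, seed, first_year = 1975L) {
  stopifnot(inherits(params, "site_climate_params"))
  if (!is.numeric(years) || length(years) != 1L || years < 1) {
    stop_arg("`years` must be a positive count")
  }
  years <- as.integer(years)
  with_seed(seed, {
    yr <- first_year + seq_len(years) - 1L
    out <- vector("list", years)
    drought <- logical(years)
    for (i in seq_len(years)) {
      ann <- if (params$t_sd > 0) stats::rnorm(1, 0, params$t_sd) else 0
      mon <- if (params$t_sd > 0) stats::rnorm(12, 0, params$t_sd / 2) else numeric(12)
      tmean <- params$t_norm + ann + mon
      if (params$p_disp > 0) {
        # gamma with mean p_norm and CV p_disp: shape = 1/CV^2, scale = mean/shape
        shape <- 1 / params$p_disp^2
        prec <- stats::rgamma(12, shape = shape, scale = params$p_norm / shape)
      } else {
        prec <- params$p_norm
      }
      drought[i] <- params$drought_freq > 0 &&
        stats::runif(1) < params$drought_freq
      if (drought[i]) {
        sm <- 5:8
        prec[sm] <- prec[sm] * (1 - params$drought_severity)
        tmean[sm] <- tmean[sm] + 1.5
      }
      out[[i]] <- data.frame(year = yr[i], month = 1:12, tmean = tmean,
                             tmax = tmean + params$diurnal_half,
                             tmin = tmean - params$diurnal_half,
                             prec = prec)
    }
    clim <- monthly_climate(do.call(rbind, out), params$site, params$latitude)
    attr(clim, "drought_years") <- stats::setNames(drought, yr)
    clim
  })
}
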