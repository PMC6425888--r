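#' Extraterrestrial radiation (FAO-56)
#'
#' Daily extraterrestrial radiation `Ra` from solar geometry: inverse relative
#' Earth--Sun distance, solar declination and sunset hour angle, evaluated at
#' a representative Julian day. For monthly use the representative day is the
#' FAO-56 mid-month day `J = floor(30.4 m - 15)`.
#'
#' @param latitude Latitude in decimal degrees, `|latitude| <= 66.5` (polar
#'   day/night is not handled).
#' @param month Month 1--12 (ignored when `day` is given).
#' @param day Optional Julian day overriding the mid-month convention.
#' @return Ra in MJ m-2 day-1.
#' @export
extraterrestrial_radiation <- function(latitude, month, day = NULL) {
  if (any(abs(latitude) > 66.5)) {
    stop_arg("latitude beyond +/-66.5 degrees is unsupported (polar day/night)")
  }
  j <- if (is.null(day)) floor(30.4 * month - 15) else day
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  dec <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(dec))))
  gsc <- 0.0820
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
}

#' Hargreaves reference evapotranspiration
#'
#' `PET = 0.408 x 0.0023 (Tmean + 17.8) sqrt(Tmax - Tmin) Ra`, in mm day-1;
#' 0.408 converts MJ m-2 day-1 into mm day-1. Negative values (possible at
#' very low temperature) are floored at 0 and counted in attribute `floored`.
#'
#' @param tmean,tmax,tmin Temperatures, degrees C (`tmax >= tmin`).
#' @param ra Extraterrestrial radiation, MJ m-2 day-1.
#' @return PET in mm day-1 with attribute `floored`.
#' @export
hargreaves_pet <- function(tmean, tmax, tmin, ra) {
  if (any(tmax < tmin)) stop_arg("tmax < tmin")
  pet <- 0.408 * 0.0023 * (tmean + 17.8) * sqrt(tmax - tmin) * ra
  fl <- pet < 0
  pet[fl] <- 0
  attr(pet, "floored") <- sum(fl)
  pet
}

#' Monthly potential evapotranspiration table
#'
#' Hargreaves PET per month of a climate table, converted from mm day-1 to
#' mm month-1 with the actual number of days in each (possibly leap) month.
#'
#' @param climate A `monthly_climate` table.
#' @return Data frame `year`, `month`, `pet` (mm month-1).
#' @export
monthly_pet <- function(climate) {
  ra <- extraterrestrial_radiation(attr(climate, "latitude"), climate$month)
  daily <- hargreaves_pet(climate$tmean, climate$tmax, climate$tmin, ra)
  data.frame(year = climate$year, month = climate$month,
             pet = as.numeric(daily) * days_in_month(climate$month, climate$year))
}

#' Monthly climatic water balance
#'
#' `CWB_m = P_m - PET_m` (mm month-1), PET by Hargreaves. Incomplete years
#' are excluded with a warning.
#'
#' @param climate A `monthly_climate` table.
#' @return Data frame `year`, `month`, `cwb` with attribute `site`.
#' @export
climatic_water_balance <- function(climate) {
  cy <- complete_years(climate)
  drop <- setdiff(unique(climate$year), cy)
  if (length(drop)) {
    warning(sprintf("excluding incomplete years: %s",
                    paste(drop, collapse = ", ")), call. = FALSE)
    climate <- climate[climate$year %in% cy, ]
  }
  pet <- monthly_pet(climate)
  structure(data.frame(year = climate$year, month = climate$month,
                       cwb = climate$prec - pet$pet),
            site = attr(climate, "site"))
}

# Unbiased probability-weighted moment of order r (Hosking/Landwehr).
pwm_unbiased <- function(x, r) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  mean(x * choose(i - 1, r)) / choose(n - 1, r)
}

# Three-parameter log-logistic fit by unbiased PWMs. Under the CDF
# F(x) = (1 + (alpha / (x - gamma))^beta)^-1 the textbook moment ratio
# returns the shape with inverted sign; |beta| keeps F increasing in x.
fit_loglogistic_pwm <- function(x) {
  b0 <- pwm_unbiased(x, 0)
  b1 <- pwm_unbiased(x, 1)
  b2 <- pwm_unbiased(x, 2)
  beta <- abs((2 * b1 - b0) / (6 * b1 - b0 - 6 * b2))
  g12 <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- abs((b0 - 2 * b1) * beta / g12)
  gam <- b0 - alpha * g12
  list(beta = beta, alpha = alpha, gamma = gam)
}

ploglogistic <- function(x, par) {
  p <- numeric(length(x))
  below <- x <= par$gamma
  p[below] <- 0
  p[!below] <- 1 / (1 + (par$alpha / (x[!below] - par$gamma))^par$beta)
  pmin(1 - 1e-8, pmax(1e-8, p))
}

#' Standardized precipitation--evapotranspiration index
#'
#' Monthly water balance `D = P - PET` (Hargreaves PET) is summed over
#' backward-looking `k`-month windows; for each calendar month a
#' three-parameter log-logistic distribution is fitted to the window sums by
#' unbiased probability-weighted moments over the full provided series
#' (the calibration period), and the fitted probabilities are mapped to
#' standard normal deviates. The first `k - 1` months are undefined.
#'
#' @param climate A `monthly_climate` table with >= 20 complete years.
#' @param k Aggregation scale in months (the analysis uses 3 and 6).
#' @return Data frame `year`, `month`, `spei` (NA where undefined), with
#'   attributes `scale` and `site`.
#' @export
spei <- function(climate, k) {
  stopifnot(k >= 1)
  cy <- complete_years(climate)
  if (length(cy) < 20) stop_arg("SPEI calibration needs >= 20 complete years")
  climate <- climate[climate$year %in% cy, ]
  climate <- climate[order(climate$year, climate$month), ]
  pet <- monthly_pet(climate)
  d <- climate$prec - pet$pet
  dk <- as.numeric(stats::filter(d, rep(1, k), sides = 1))
  z <- rep(NA_real_, length(dk))
  for (m in 1:12) {
    idx <- which(climate$month == m & !is.na(dk))
    if (length(idx) < 4) next
    if (stats::sd(dk[idx]) == 0) {
      stop_arg("degenerate fit: zero variance of %d-month sums in calendar month %d",
               k, m)
    }
    par <- fit_loglogistic_pwm(dk[idx])
    z[idx] <- stats::qnorm(ploglogistic(dk[idx], par))
  }
  structure(data.frame(year = climate$year, month = climate$month, spei = z),
            scale = k, site = attr(climate, "site"))
}

#' Annual aridity index
#'
#' A scalar aridity summary from the mean annual temperature and annual
#' precipitation sum of the complete years. The default is the de Martonne
#' index `P / (T + 10)` (mm / degrees C; larger = more humid); the formula in
#' force is recorded in attribute `formula` so downstream output is
#' self-describing.
#'
#' @param climate A `monthly_climate` table with >= 1 complete year.
#' @param formula Currently `"de-martonne"`.
#' @return Index value with attribute `formula`.
#' @export
aridity_index <- function(climate, formula = c("de-martonne")) {
  formula <- match.arg(formula)
  cy <- complete_years(climate)
  if (!length(cy)) stop_arg("no complete year")
  climate <- climate[climate$year %in% cy, ]
  t_ann <- mean(tapply(climate$tmean, climate$year, mean))
  p_ann <- mean(tapply(climate$prec, climate$year, sum))
  val <- switch(formula, "de-martonne" = p_ann / (t_ann + 10))
  structure(val, formula = formula)
}

#' The 19 bioclimatic variables from monthly normals
#'
#' Standard bioclim summaries (annual means, diurnality, seasonality,
#' extreme months and extreme three-month quarters) from 12-month normals of
#' mean/max/min temperature and precipitation. Quarters are all 12
#' wrap-around windows of 3 consecutive months (December--January wraps);
#' the wettest/driest/warmest/coldest window is selected per definition,
#' first window winning ties. bio4 is the standard deviation of monthly mean
#' temperature x 100; bio15 is the precipitation CV in percent
#' (`100 sd / mean`), flagged undefined (NA) for zero mean precipitation, as
#' is bio3 when the annual temperature range is zero.
#'
#' @param tmean,tmax,tmin,prec Numeric vectors of length 12 (degrees C, mm).
#' @return Named numeric vector `bio1` .. `bio19` (NA where undefined), with
#'   attribute `quarters` (the chosen window start months).
#' @export
bioclim_variables <- function(tmean, tmax, tmin, prec) {
  if (any(lengths(list(tmean, tmax, tmin, prec)) != 12L)) {
    stop_arg("all four monthly normal vectors must have 12 entries")
  }
  if (anyNA(c(tmean, tmax, tmin, prec))) stop_arg("missing month in normals")
  wrap <- function(x) x[((0:2 + rep(0:11, each = 3)) %% 12) + 1]
  qt <- colMeans(matrix(wrap(tmean), 3))   # mean T of window starting m
  qp <- colSums(matrix(wrap(prec), 3))     # P sum of window starting m
  wettest <- which.max(qp)
  driest <- which.min(qp)
  warmest <- which.max(qt)
  coldest <- which.min(qt)
  b <- numeric(19)
  b[1] <- mean(tmean)
  b[2] <- mean(tmax - tmin)
  b[5] <- max(tmax)
  b[6] <- min(tmin)
  b[7] <- b[5] - b[6]
  b[3] <- if (b[7] == 0) NA_real_ else b[2] / b[7] * 100
  b[4] <- stats::sd(tmean) * 100
  b[8] <- qt[wettest]
  b[9] <- qt[driest]
  b[10] <- qt[warmest]
  b[11] <- qt[coldest]
  b[12] <- sum(prec)
  b[13] <- max(prec)
  b[14] <- min(prec)
  b[15] <- if (mean(prec) == 0) NA_real_ else 100 * stats::sd(prec) / mean(prec)
  b[16] <- qp[wettest]
  b[17] <- qp[driest]
  b[18] <- qp[warmest]
  b[19] <- qp[coldest]
  structure(stats::setNames(b, paste0("bio", 1:19)),
            quarters = c(wettest = wettest, driest = driest,
                         warmest = warmest, coldest = coldest))
}

#' Bioclim vector from a climate table's monthly normals
#'
#' Averages the complete years of a `monthly_climate` table into 12-month
#' normals and applies [bioclim_variables()].
#'
#' @param climate A `monthly_climate` table.
#' @return Named numeric vector `bio1` .. `bio19`.
#' @export
bioclim_from_climate <- function(climate) {
  cy <- complete_years(climate)
  if (!length(cy)) stop_arg("no complete year")
  climate <- climate[climate$year %in% cy, ]
  agg <- function(v) as.numeric(tapply(v, climate$month, mean))
  bioclim_variables(agg(climate$tmean), agg(climate$tmax),
                    agg(climate$tmin), agg(climate$prec))
}
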