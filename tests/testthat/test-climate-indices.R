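test_that("extraterrestrial radiation reproduces the reference geometry", {
  # published worked example: 20 S in early September
  expect_equal(extraterrestrial_radiation(-20, 9, day = 246), 32.2,
               tolerance = 0.02)
  # equator: March (equinox month) carries the annual maximum
  ra_eq <- vapply(1:12, function(m) extraterrestrial_radiation(0, m),
                  numeric(1))
  expect_gte(ra_eq[3], max(ra_eq) * 0.995)
  # hemispheric symmetry up to the representative-day asymmetry
  for (phi in c(10, 35, 55)) {
    for (m in 1:6) {
      a <- extraterrestrial_radiation(phi, m)
      b <- extraterrestrial_radiation(-phi, (m + 5) %% 12 + 1)
      expect_equal(a, b, tolerance = 0.03 * max(a, b))
    }
  }
  expect_error(extraterrestrial_radiation(70, 6), "polar")
})

test_that("Hargreaves PET follows its closed form", {
  expect_equal(as.numeric(hargreaves_pet(15, 20, 20, 25)), 0)
  expect_equal(as.numeric(hargreaves_pet(-17.8, -10, -25, 10)), 0)
  expect_equal(as.numeric(hargreaves_pet(20, 25, 15, 30)),
               0.408 * 0.0023 * 37.8 * sqrt(10) * 30)
  expect_error(hargreaves_pet(10, 5, 8, 20), "tmax < tmin")
  # floored negative value is flagged
  v <- hargreaves_pet(-30, -25, -35, 10)
  expect_equal(as.numeric(v), 0)
  expect_equal(attr(v, "floored"), 1)
})

test_that("water balance is precipitation minus PET, month by month", {
  cl <- simulate_site_climate(default_sites()$DRY, 25, seed = 61)
  cwb <- climatic_water_balance(cl)
  pet <- monthly_pet(cl)
  expect_equal(cwb$cwb + pet$pet, cl$prec)
  # incomplete years are excluded with a warning
  cl2 <- cl[-5, ]
  attr(cl2, "site") <- attr(cl, "site")
  attr(cl2, "latitude") <- attr(cl, "latitude")
  expect_warning(cwb2 <- climatic_water_balance(cl2), "incomplete")
  expect_false(cl$year[5] %in% cwb2$year)
  # the drought-prone site has the lower growing-season water balance
  moist <- climatic_water_balance(simulate_site_climate(default_sites()$MOIST,
                                                        25, seed = 61))
  gs <- function(x) mean(x$cwb[x$month %in% 5:8])
  expect_lt(gs(cwb), gs(moist))
})

test_that("SPEI is standardized over the calibration period and monotone", {
  cl <- simulate_site_climate(default_sites()$MOIST, 50, seed = 71)
  for (k in c(3, 6)) {
    sk <- spei(cl, k)
    expect_true(all(is.na(sk$spei[seq_len(k - 1)])))
    for (m in 1:12) {
      z <- sk$spei[sk$month == m & !is.na(sk$spei)]
      expect_lt(abs(mean(z)), 0.05)
      expect_gt(stats::sd(z), 0.9)
      expect_lt(stats::sd(z), 1.1)
    }
  }
  # monotone in the water balance within a calendar month
  s3 <- spei(cl, 3)
  pet <- monthly_pet(cl)
  d <- cl$prec - pet$pet
  dk <- as.numeric(stats::filter(d, rep(1, 3), sides = 1))
  idx <- which(cl$month == 7)
  expect_equal(order(s3$spei[idx]), order(dk[idx]))
  # independent oracle: empirical-quantile (Gringorten) z-scores
  n <- length(idx)
  gring <- stats::qnorm((rank(dk[idx]) - 0.44) / (n + 0.12))
  expect_gt(stats::cor(gring, s3$spei[idx]), 0.98)
  expect_lt(max(abs(gring - s3$spei[idx])), 0.5)
})

test_that("SPEI is invariant to a location shift of the water balance", {
  cl <- simulate_site_climate(default_sites()$MOIST, 40, seed = 81)
  shifted <- cl
  shifted$prec <- shifted$prec + 40
  attr(shifted, "site") <- attr(cl, "site")
  attr(shifted, "latitude") <- attr(cl, "latitude")
  a <- spei(cl, 3)$spei
  b <- spei(shifted, 3)$spei
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("degenerate SPEI input names the offending month", {
  cl <- make_constant_climate(years = 1981:2005)
  expect_error(spei(cl, 3), "zero variance.*month \\d")
  expect_error(spei(make_constant_climate(years = 1981:1990), 3), ">= 20")
})

test_that("the aridity index is the documented de Martonne form", {
  cl <- make_constant_climate(tmean = 10, prec = 50)
  ai <- aridity_index(cl)
  expect_equal(as.numeric(ai), 600 / (10 + 10))
  expect_equal(attr(ai, "formula"), "de-martonne")
  wet <- make_constant_climate(tmean = 10, prec = 100)
  expect_gt(as.numeric(aridity_index(wet)), as.numeric(ai))
  drier <- make_constant_climate(tmean = 10, prec = 40)
  expect_lt(as.numeric(aridity_index(drier)), as.numeric(ai))
})

test_that("bioclim variables satisfy their identities", {
  # constancy degeneracy
  b <- bioclim_variables(rep(10, 12), rep(10, 12), rep(10, 12), rep(50, 12))
  expect_equal(as.numeric(b["bio1"]), 10)
  expect_equal(as.numeric(b["bio4"]), 0)
  expect_equal(as.numeric(b["bio7"]), 0)
  expect_true(is.na(b["bio3"]))
  expect_equal(as.numeric(b["bio12"]), 600)
  expect_equal(as.numeric(b["bio15"]), 0)
  expect_equal(as.numeric(b["bio16"]), 150)
  expect_equal(as.numeric(b["bio17"]), 150)
  # randomized identity checks against a brute-force quarter oracle
  for (seed in 1:100) {
    set.seed(seed)
    tmean <- stats::runif(12, -5, 20)
    half <- stats::runif(12, 1, 8)
    prec <- stats::runif(12, 0, 120)
    b <- bioclim_variables(tmean, tmean + half, tmean - half, prec)
    expect_equal(as.numeric(b["bio7"]), as.numeric(b["bio5"] - b["bio6"]))
    expect_equal(as.numeric(b["bio12"]), sum(prec))
    expect_gte(b[["bio5"]], b[["bio6"]])
    expect_gte(b[["bio13"]], b[["bio14"]])
    expect_gte(b[["bio16"]], b[["bio17"]])
    # brute force over the 12 wrap-around windows
    qsum <- vapply(1:12, function(m) sum(prec[((m - 1):(m + 1) %% 12) + 1]),
                   numeric(1))
    qmean <- vapply(1:12, function(m) mean(tmean[((m - 1):(m + 1) %% 12) + 1]),
                    numeric(1))
    expect_equal(as.numeric(b["bio16"]), max(qsum))
    expect_equal(as.numeric(b["bio17"]), min(qsum))
    expect_equal(as.numeric(b["bio10"]), max(qmean))
    expect_equal(as.numeric(b["bio11"]), min(qmean))
    expect_equal(as.numeric(b["bio8"]), qmean[which.max(qsum)])
    expect_equal(as.numeric(b["bio9"]), qmean[which.min(qsum)])
    expect_equal(as.numeric(b["bio18"]), qsum[which.max(qmean)])
    expect_equal(as.numeric(b["bio19"]), qsum[which.min(qmean)])
  }
  # a single wet month dominates bio13 and anchors bio16
  prec <- rep(10, 12)
  prec[7] <- 200
  b <- bioclim_variables(rep(10, 12), rep(14, 12), rep(6, 12), prec)
  expect_equal(as.numeric(b["bio13"]), 200)
  expect_equal(as.numeric(b["bio16"]), 220)
  expect_error(bioclim_variables(rep(1, 11), rep(1, 12), rep(1, 12), rep(1, 12)),
               "12")
})

test_that("PDSI is validated as an external input only", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(year = rep(2000:2001, each = 12), month = rep(1:12, 2),
                   pdsi = stats::rnorm(24))
  utils::write.csv(df, f, row.names = FALSE)
  back <- read_pdsi_csv(f)
  expect_equal(back$pdsi, df$pdsi)
  df$month[1] <- 0
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_pdsi_csv(f), "month")
})
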