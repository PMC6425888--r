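# Frequency response of the growth-curve smoother, measured by regressing the
# fitted curve on the probe sinusoid over the interior of the series.
measure_response <- function(period, n = 150, cutoff = 30) {
  t <- seq_len(n)
  x <- 2 + 0.5 * sin(2 * pi * t / period)
  f <- fit_growth_spline(x, cutoff)
  i <- t > n * 0.15 & t <= n * 0.85
  co <- stats::coef(stats::lm(f[i] ~ sin(2 * pi * t[i] / period) +
                                cos(2 * pi * t[i] / period)))
  sqrt(sum(co[2:3]^2)) / 0.5
}

test_that("growth curve passes trends and rejects year-to-year variability", {
  # linear ramp is in the penalty null space: tracked almost exactly
  x <- seq(1, 5, length.out = 100)
  f <- fit_growth_spline(x, 30)
  i <- 15:85
  expect_lt(max(abs(f[i] - x[i]) / x[i]), 0.02)
  # period-2 alternation around 2.0 is rejected
  x <- 2 + 0.2 * rep(c(1, -1), 50)
  f <- fit_growth_spline(x, 30)
  expect_lt(max(abs(f[10:90] - 2)), 0.04)
  expect_error(fit_growth_spline(rep(1, 5)), ">= 10")
  expect_error(fit_growth_spline(rep(0, 50)), "zero")
})

test_that("detrending by division behaves as a ratio index", {
  curve <- seq(3, 1, length.out = 20)
  expect_equal(detrend_to_rwi(curve, curve), rep(1, 20))
  expect_equal(detrend_to_rwi(2 * curve, curve), rep(2, 20))
  w <- curve
  w[7] <- 0   # locally absent ring is retained as index 0
  expect_equal(detrend_to_rwi(w, curve)[7], 0)
  bad <- curve
  bad[4] <- -0.1
  expect_error(detrend_to_rwi(w, bad, years = 1981:2000), "1984")
})

test_that("prewhitening removes first-order autocorrelation", {
  # white noise: phi ~ 0, output is essentially the recentered input
  set.seed(8)
  x <- stats::rnorm(100, 1, 0.1)
  out <- prewhiten_ar1(x)
  expect_length(out, 99)
  expect_equal(mean(out), 1)
  expect_lt(abs(attr(out, "phi")), 0.25)
  expect_gt(stats::cor(as.numeric(out), x[-1]), 0.95)
  # AR(1) with phi = 0.7: residual lag-1 autocorrelation near zero
  set.seed(9)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.7), 200)) + 1
  res <- prewhiten_ar1(ar)
  r1 <- stats::cor(res[-1], res[-length(res)])
  expect_lt(abs(r1), 0.1)
  expect_equal(attr(res, "phi"), 0.7, tolerance = 0.15)
  expect_length(prewhiten_ar1(stats::rnorm(40) + 10), 39)
  expect_error(prewhiten_ar1(rep(1, 40)), "constant")
})

test_that("biweight mean is robust with bounded influence", {
  expect_equal(tukey_biweight_mean(c(5, 5, 5)), 5)
  expect_equal(tukey_biweight_mean(c(1, 2, 3)), 2)
  est <- tukey_biweight_mean(c(1, 1, 1, 10))
  expect_equal(est, 1, tolerance = 0.05)
  expect_lt(est, 3.25)
  # bounded influence: sending one observation to infinity barely moves it
  set.seed(12)
  x <- stats::rnorm(30, 1, 0.1)
  base <- tukey_biweight_mean(x)
  for (out in c(1e3, 1e6, 1e9)) {
    expect_equal(tukey_biweight_mean(c(x, out)), base, tolerance = 0.02)
  }
  expect_error(tukey_biweight_mean(numeric(0)), "finite")
})

test_that("chronology building is a per-year robust mean with sample depth", {
  yrs <- 1981:2010
  one <- 1 + 0.1 * sin(seq_along(yrs))
  rwi <- as.data.frame(replicate(15, one))
  colnames(rwi) <- sprintf("T%02d", 1:15)
  rownames(rwi) <- yrs
  ch <- build_chronology(rwi, provenance = "P", site = "S")
  expect_equal(ch$value, one, ignore_attr = TRUE)
  expect_true(all(ch$depth == 15))
  # single series passes through
  ch1 <- build_chronology(rwi["T01"])
  expect_equal(ch1$value, one, ignore_attr = TRUE)
  expect_true(all(ch1$depth == 1))
  # one wild value in one year: robust mean stays near 1
  rwi2 <- as.data.frame(matrix(1, 30, 15))
  colnames(rwi2) <- colnames(rwi)
  rownames(rwi2) <- yrs
  rwi2[5, 15] <- 3
  ch2 <- build_chronology(rwi2)
  expect_lt(abs(ch2$value[5] - 1), abs(ch2$value[5] - mean(c(rep(1, 14), 3))))
  expect_error(build_chronology(rwi, series = "nope"), "no series")
})

test_that("Gleichlaeufigkeit counts sign agreement of year-to-year changes", {
  a <- c(1, 2, 1, 3)
  b <- c(2, 3, 2, 2)
  expect_equal(glk(a, b), (1 + 1 + 0.5) / 3)
  expect_equal(glk(a, b), glk(b, a))
  x <- c(1, 3, 2, 5, 4, 6)
  expect_equal(glk(x, x), 1)
  mirror <- x[1] + cumsum(c(0, -diff(x)))
  expect_equal(glk(x, mirror), 0)
  # invariance to positive affine rescaling
  for (seed in 1:10) {
    set.seed(seed)
    u <- stats::runif(20)
    v <- stats::runif(20)
    expect_equal(glk(u, v), glk(2.5 * u + 7, v))
    expect_equal(glk(u, v), glk(u, 0.1 * v - 3))
  }
  expect_error(glk(1, 2), ">= 2")
})

test_that("mean sensitivity follows its definition", {
  expect_equal(as.numeric(mean_sensitivity(rep(2, 10))), 0)
  expect_equal(as.numeric(mean_sensitivity(c(1, 3))), 1)
  expect_equal(as.numeric(mean_sensitivity(c(1, 3, 1))), 1)
  ms <- mean_sensitivity(c(1, -1, 2))
  expect_equal(attr(ms, "skipped"), 1)
  expect_equal(as.numeric(ms), abs(2 * 3 / 1))
  expect_error(mean_sensitivity(c(0, 0)), "zero")
})

test_that("rbar averages pairwise correlations over common periods", {
  yrs <- 1951:2150
  set.seed(14)
  base <- stats::rnorm(200)
  same <- as.data.frame(replicate(4, base + 1))
  rownames(same) <- yrs
  expect_equal(interseries_rbar(same), 1)
  # two series: rbar is that single Pearson r
  two <- data.frame(a = stats::rnorm(200), b = stats::rnorm(200))
  rownames(two) <- yrs
  expect_equal(interseries_rbar(two), stats::cor(two$a, two$b))
  # independent noise: rbar near zero
  noise <- as.data.frame(matrix(stats::rnorm(200 * 15), 200, 15))
  rownames(noise) <- yrs
  expect_lt(abs(interseries_rbar(noise)), 0.05)
  expect_error(interseries_rbar(two[1]), ">= 2 series")
})

test_that("chronology statistics summarise each provenance", {
  fx <- make_small_trial(seed = 51, marginality = 0.2, trees = 6, years = 35)
  rwi <- detrend_rwl(fx$trial$rwl)
  st <- chronology_stats(fx$trial$rwl, rwi, fx$trial$meta)
  expect_equal(nrow(st), 2)
  expect_true(all(st$n == 6))
  expect_true(all(st$glk >= 0 & st$glk <= 1))
  expect_true(all(st$ms >= 0))
  expect_true(all(st$rbar >= -1 & st$rbar <= 1))
  expect_true(all(st$trw > 0))
})

test_that("the null scenario shows no between-provenance structure", {
  # detrend/prewhiten on identical provenance parameters: between- and
  # within-provenance tree correlations are indistinguishable
  fx <- make_fixture_suite(7, n_provenances = 4, trees_per_provenance = 6,
                           years = 35)[["null"]]
  rwi <- detrend_rwl(fx$rwl)
  cc <- stats::cor(as.matrix(rwi), use = "pairwise.complete.obs")
  same <- outer(fx$meta$provenance, fx$meta$provenance, "==")
  diag(cc) <- NA
  tt <- stats::t.test(cc[same & upper.tri(cc)], cc[!same & upper.tri(cc)])
  expect_gt(tt$p.value, 0.01)
})
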