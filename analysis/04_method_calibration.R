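#!/usr/bin/env Rscript
# Calibration checks of the methodological building blocks: growth-curve
# frequency response, prewhitening, SPEI standardization, rank-sum and
# pairwise-PCGA error rates. Writes results/method_calibration.csv.

library(dendroprov)

dir.create("results", showWarnings = FALSE)
rows <- list()
note <- function(metric, value, target) {
  rows[[length(rows) + 1]] <<- data.frame(metric = metric, value = value,
                                          target = target)
  cat(sprintf("  %-32s %8.4f   (target %s)\n", metric, value, target))
}

cat("Growth-curve frequency response (150-year sinusoid probes):\n")
resp <- function(period) {
  t <- 1:150
  x <- 2 + 0.5 * sin(2 * pi * t / period)
  f <- fit_growth_spline(x, 30)
  i <- t > 22 & t <= 127
  co <- stats::coef(stats::lm(f[i] ~ sin(2 * pi * t[i] / period) +
                                cos(2 * pi * t[i] / period)))
  sqrt(sum(co[2:3]^2)) / 0.5
}
note("response_30y", resp(30), "0.5 +/- 0.05")
note("response_100y", resp(100), ">= 0.9")
note("response_5y", resp(5), "<= 0.1")

cat("Prewhitening (AR(1) phi = 0.7, n = 200, 100 draws):\n")
r1 <- vapply(1:100, function(k) {
  set.seed(k)
  res <- prewhiten_ar1(as.numeric(stats::arima.sim(list(ar = 0.7), 200)) + 5)
  stats::cor(res[-1], res[-length(res)])
}, numeric(1))
note("mean_abs_residual_lag1", mean(abs(r1)), "< 0.1")

cat("SPEI standardization (50 simulated years):\n")
clim <- simulate_site_climate(default_sites()$MOIST, 50, seed = 77)
s3 <- spei(clim, 3)
mm <- vapply(1:12, function(m) mean(s3$spei[s3$month == m & !is.na(s3$spei)]),
             numeric(1))
ss <- vapply(1:12, function(m) stats::sd(s3$spei[s3$month == m & !is.na(s3$spei)]),
             numeric(1))
note("spei3_max_abs_month_mean", max(abs(mm)), "< 0.05")
note("spei3_mean_month_sd", mean(ss), "0.9 .. 1.1")

cat("Rank-sum null calibration (1000 draws):\n")
set.seed(7)
note("ranksum_null_rejection",
     mean(replicate(1000, rank_sum_test(stats::rnorm(10),
                                        stats::rnorm(10))$p.value < 0.05)),
     "0.03 .. 0.07")

cat("Pairwise PCGA type-I error (null scenario, 200 seeds):\n")
site <- default_sites()$DRY
q <- default_provenances(2)[[1]]
null_provs <- list(provenance_params("P01", q$response),
                   provenance_params("P02", q$response))
ps <- vapply(1:200, function(k) {
  cl <- simulate_site_climate(site, 35, seed = 51000 + k)
  tr <- simulate_provenance_trial(cl, null_provs,
                                  trial_config(15, 35, marginality = 0.5,
                                               seed = 52000 + k))
  pairwise_pcga(detrend_rwl(tr$rwl), tr$meta, keep_gradients = FALSE)$p[1, 2]
}, numeric(1))
note("pcga_null_rejection", mean(ps < 0.05), "0.02 .. 0.09")

utils::write.csv(do.call(rbind, rows), "results/method_calibration.csv",
                 row.names = FALSE)
cat("Written to results/method_calibration.csv\n")
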