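test_that("a rank-one ensemble loads everything on PC1", {
  base <- sin(seq_len(30))
  x <- matrix(rep(base, 6), 30, 6,
              dimnames = list(NULL, sprintf("T%d", 1:6)))
  expect_warning(g <- pcga_gradient(x), "zero variance")
  expect_gt(g$var_explained[1], 99.999)
  expect_equal(length(unique(round(g$angle, 10))), 1)
  expect_setequal(g$rank, 1:6)
  expect_error(pcga_gradient(matrix(1, 30, 6)), "degenerate")
})

test_that("two orthogonal groups produce bimodal, separated angles", {
  set.seed(101)
  n <- 34
  s1 <- stats::rnorm(n)
  s2 <- stats::rnorm(n)
  x <- cbind(sapply(1:8, function(i) s1 + stats::rnorm(n, 0, 0.3)),
             sapply(1:8, function(i) s2 + stats::rnorm(n, 0, 0.3)))
  colnames(x) <- c(sprintf("A%d", 1:8), sprintf("B%d", 1:8))
  g <- pcga_gradient(x)
  within_a <- stats::sd(g$angle[1:8])
  within_b <- stats::sd(g$angle[9:16])
  sep <- abs(mean(g$angle[1:8]) - mean(g$angle[9:16]))
  expect_gt(sep, 5 * max(within_a, within_b))
  ts <- rank_sum_test(g$rank[1:8], g$rank[9:16])
  expect_lt(ts$p.value, 0.01)
  # PC1 orientation convention
  expect_gte(mean(g$loadings[, "PC1"]), 0)
  expect_gte(mean(pcga_gradient(-x)$loadings[, "PC1"]), 0)
})

test_that("gradient angles are invariant to tree column order", {
  set.seed(102)
  x <- matrix(stats::rnorm(30 * 8), 30, 8,
              dimnames = list(NULL, sprintf("T%d", 1:8)))
  x <- x + sin(seq_len(30))   # shared signal so PC1 sign is stable
  g1 <- pcga_gradient(x)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  g2 <- pcga_gradient(x[, perm])
  expect_equal(stats::setNames(g2$angle, g2$series)[g1$series],
               stats::setNames(g1$angle, g1$series), tolerance = 1e-10)
  expect_error(pcga_gradient(x[, 1:3]), ">= 4 trees")
  expect_error(pcga_gradient(x[1:5, ]), ">= 10")
  xna <- x
  xna[2, 3] <- NA
  expect_error(pcga_gradient(xna), "missing")
})

test_that("rank-sum test is exact without ties and calibrated under the null", {
  ts <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ts$p.value, 0.1)
  expect_match(ts$method, "exact")
  expect_equal(rank_sum_test(c(2, 7, 9), c(2, 7, 9))$p.value, 1)
  expect_warning(rank_sum_test(c(3, 3), c(3, 3, 3)), "identical")
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
  # agreement with the standard implementation, both regimes
  set.seed(103)
  for (i in 1:20) {
    a <- stats::rnorm(sample(3:6, 1))
    b <- stats::rnorm(sample(3:6, 1))
    ours <- rank_sum_test(a, b)$p.value
    ref <- stats::wilcox.test(a, b, exact = length(a) + length(b) <= 12,
                              correct = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
    a <- stats::rnorm(15)
    b <- stats::rnorm(18)
    expect_equal(rank_sum_test(a, b)$p.value,
                 stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # null calibration
  set.seed(104)
  rej <- mean(replicate(1000, {
    rank_sum_test(stats::rnorm(10), stats::rnorm(10))$p.value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("pairwise PCGA covers all pairs symmetrically", {
  fx <- make_fixture_suite(5, n_provenances = 5, trees_per_provenance = 5,
                           years = 30)[["divergent-mild"]]
  rwi <- detrend_rwl(fx$rwl)
  pg <- pairwise_pcga(rwi, fx$meta)
  expect_equal(sum(!is.na(pg$p[upper.tri(pg$p)])), choose(5, 2))
  expect_equal(pg$p, t(pg$p))
  expect_true(all(is.na(diag(pg$p))))
  expect_true(all(pg$p[!is.na(pg$p)] >= 0 & pg$p[!is.na(pg$p)] <= 1))
  expect_length(pg$gradients, choose(5, 2))
  # invariance to tree ordering
  perm <- sample(ncol(rwi))
  pg2 <- pairwise_pcga(rwi[, perm], fx$meta[match(colnames(rwi)[perm],
                                                  fx$meta$series), ])
  expect_equal(pg$p, pg2$p[rownames(pg$p), colnames(pg$p)])
  # long export covers the upper triangle
  lt <- pcga_long_table(pg)
  expect_equal(nrow(lt), choose(5, 2))
  expect_true(all(lt$tier[lt$p < 0.01] == "**"))
})

test_that("undersized provenances are excluded with missing rows", {
  fx <- make_fixture_suite(6, n_provenances = 4, trees_per_provenance = 5,
                           years = 30)[["divergent-mild"]]
  meta <- fx$meta
  drop <- meta$series[meta$provenance == "P02"][1:3]
  keep <- setdiff(colnames(fx$rwl), drop)
  rwi <- detrend_rwl(fx$rwl[, keep])
  expect_warning(pg <- pairwise_pcga(rwi, meta[meta$series %in% keep, ]),
                 "P02")
  expect_true(all(is.na(pg$p["P02", ])))
  expect_equal(sum(!is.na(pg$p[upper.tri(pg$p)])), choose(3, 2))
})

test_that("a single divergent provenance dominates the significant pairs", {
  set.seed(106)
  n <- 34
  shared <- stats::rnorm(n)
  odd <- stats::rnorm(n)
  cols <- list()
  meta <- list()
  for (p in 1:4) {
    sig <- if (p == 4) odd else shared
    for (tr in 1:8) {
      id <- sprintf("P%02d_%02d", p, tr)
      cols[[id]] <- 1 + 0.2 * sig + stats::rnorm(n, 0, 0.1)
      meta[[id]] <- data.frame(series = id, tree = tr,
                               provenance = sprintf("P%02d", p), site = "S")
    }
  }
  rwi <- as.data.frame(cols, check.names = FALSE)
  rownames(rwi) <- 1981:(1980 + n)
  pg <- pairwise_pcga(rwi, do.call(rbind, meta))
  sig <- pg$p < 0.05
  expect_true(all(sig["P04", c("P01", "P02", "P03")]))
  expect_false(any(sig[c("P01", "P02", "P03"), c("P01", "P02", "P03")],
                   na.rm = TRUE))
})

test_that("orthogonally responding provenances are detected with high power", {
  site <- default_sites()$DRY
  provs <- default_provenances(10)[c(1, 6)]   # orthogonal deviations
  rej <- vapply(1:10, function(s) {
    cl <- simulate_site_climate(site, 40, seed = 4000 + s)
    tr <- simulate_provenance_trial(cl, provs,
                                    trial_config(15, 40, marginality = 0.1,
                                                 seed = 5000 + s))
    pg <- pairwise_pcga(detrend_rwl(tr$rwl), tr$meta, keep_gradients = FALSE)
    pg$p[1, 2] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("the differentiation score is the significant-pair fraction", {
  fake <- function(p_off) {
    p <- matrix(p_off, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    diag(p) <- NA
    structure(list(p = p), class = "pairwise_pcga")
  }
  expect_equal(differentiation_score(fake(1)), 0)
  expect_equal(differentiation_score(fake(0.001)), 1)
  expect_error(differentiation_score(fake(NA_real_)), "no valid")
})
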