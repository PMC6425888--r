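#' Principal component gradient analysis of a tree ensemble
#'
#' PCA of the individual-tree index series over their common period, with each
#' tree centered on its own mean. Each tree's loadings on the first two
#' components are expressed in polar form; the polar angle orders the trees
#' along the growth-pattern gradient. PC1 is oriented so that its mean
#' loading is positive and PC2 so that its largest-magnitude loading is
#' positive (resolving the reflection ambiguity of polar coordinates in a
#' column-order-invariant way); ties in angle are broken by the stable
#' column order, so the gradient ranks are always a permutation of `1..n`.
#'
#' @param x Numeric matrix or data frame, years x trees, no missing cells,
#'   >= 10 years and >= 4 trees.
#' @return List of class `pcga_gradient`: `loadings` (trees x 2), `angle`
#'   (radians), `rank` (integer permutation), `var_explained` (percent, PC1
#'   and PC2), `series` (column names).
#' @export
pcga_gradient <- function(x) {
  m <- as.matrix(x)
  if (anyNA(m)) stop_arg("no missing cells allowed in the common period")
  if (ncol(m) < 4) stop_arg("need >= 4 trees")
  if (nrow(m) < 10) stop_arg("need >= 10 common years")
  mc <- sweep(m, 2, colMeans(m))
  sv <- La.svd(mc)
  ev <- sv$d^2
  tot <- sum(ev)
  if (tot == 0 || ev[1] / tot < 1e-12) {
    stop_arg("degenerate ensemble: no positive-variance component")
  }
  v1 <- sv$vt[1, ]
  if (mean(v1) < 0) v1 <- -v1
  if (length(ev) >= 2 && ev[2] / tot > 1e-12) {
    v2 <- sv$vt[2, ]
    # PC2 reflection fixed by the largest-magnitude loading, so angles are
    # invariant to tree column order
    if (v2[which.max(abs(v2))] < 0) v2 <- -v2
  } else {
    warning("second component has zero variance; all polar angles coincide",
            call. = FALSE)
    v2 <- rep(0, ncol(m))
  }
  angle <- atan2(v2, v1)
  rk <- integer(ncol(m))
  rk[order(angle, seq_along(angle))] <- seq_along(angle)
  structure(list(loadings = cbind(PC1 = v1, PC2 = v2),
                 angle = angle, rank = rk,
                 var_explained = ev[1:2] / tot * 100,
                 series = colnames(m)),
            class = "pcga_gradient")
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact p by full enumeration of assignments when the combined sample size
#' is at most 12 and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction. All observations identical
#' across both groups returns p = 1 with a warning.
#'
#' @param a,b Numeric samples (non-empty).
#' @return List: `statistic` (Mann--Whitney U of `a`), `p.value`, `method`.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop_arg("both groups must be non-empty")
  x <- c(a, b)
  m <- length(a)
  n <- length(b)
  N <- m + n
  if (length(unique(x)) == 1L) {
    warning("all observations identical; no shift to test", call. = FALSE)
    return(list(statistic = m * n / 2, p.value = 1, method = "degenerate"))
  }
  r <- rank(x)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(x) > 0L
  if (N <= 12 && !ties) {
    cmb <- utils::combn(N, m)
    us <- colSums(matrix(r[cmb], nrow = m)) - m * (m + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    list(statistic = u, p.value = p, method = "exact enumeration")
  } else {
    mu <- m * n / 2
    tt <- table(x)
    sigma2 <- (m * n / 12) * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    z <- u - mu
    z <- z - sign(z) * 0.5
    p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
    list(statistic = u, p.value = p,
         method = "normal approximation with tie and continuity correction")
  }
}

#' Pairwise PCGA over all provenance pairs at one site
#'
#' For every unordered pair of provenances, runs [pcga_gradient()] on only
#' those two provenances' trees (common complete period) and tests the
#' gradient ranks, split by provenance, with [rank_sum_test()]. Testing ranks
#' rather than raw angles makes the result invariant to monotone angle
#' transforms. Provenances with fewer than `min_trees` trees are excluded
#' with a warning and their matrix rows left missing.
#'
#' @param rwi Wide RWI data frame (prewhitened single-tree indices).
#' @param meta Metadata with `series`, `provenance` (and optionally `site`).
#' @param min_trees Minimum trees per provenance (default 4).
#' @param min_years Minimum common years per pair (default 10).
#' @param keep_gradients Store the per-pair `pcga_gradient` objects (set
#'   FALSE in large simulation loops).
#' @return List of class `pairwise_pcga`: `p` (symmetric provenance x
#'   provenance p-value matrix, diagonal NA), `tier` (character matrix:
#'   `""`, `"*"` p < 0.05, `"**"` p < 0.01), `gradients` (named list),
#'   `site`.
#' @export
pairwise_pcga <- function(rwi, meta, min_trees = 4, min_years = 10,
                          keep_gradients = TRUE) {
  provs <- unique(meta$provenance)
  if (length(provs) < 2) stop_arg("need >= 2 provenances")
  n_by <- vapply(provs, function(p) sum(meta$provenance == p), integer(1))
  small <- provs[n_by < min_trees]
  if (length(small)) {
    warning(sprintf("excluding provenances with < %d trees: %s", min_trees,
                    paste(small, collapse = ", ")), call. = FALSE)
  }
  keep <- setdiff(provs, small)
  p_mat <- matrix(NA_real_, length(provs), length(provs),
                  dimnames = list(provs, provs))
  grads <- list()
  if (length(keep) >= 2) {
    for (i in seq_along(keep)[-length(keep)]) {
      for (j in (i + 1):length(keep)) {
        pa <- keep[i]
        pb <- keep[j]
        ids_a <- meta$series[meta$provenance == pa]
        ids_b <- meta$series[meta$provenance == pb]
        sub <- as.matrix(rwi[, c(ids_a, ids_b), drop = FALSE])
        ok <- rowSums(is.na(sub)) == 0
        if (sum(ok) < min_years) {
          stop_arg("pair %s-%s has only %d complete common years (need %d)",
                   pa, pb, sum(ok), min_years)
        }
        g <- pcga_gradient(sub[ok, , drop = FALSE])
        in_a <- g$series %in% ids_a
        ts <- rank_sum_test(g$rank[in_a], g$rank[!in_a])
        p_mat[pa, pb] <- p_mat[pb, pa] <- ts$p.value
        if (keep_gradients) grads[[paste(pa, pb, sep = "-")]] <- g
      }
    }
  }
  tier <- matrix("", nrow(p_mat), ncol(p_mat), dimnames = dimnames(p_mat))
  tier[!is.na(p_mat) & p_mat < 0.05] <- "*"
  tier[!is.na(p_mat) & p_mat < 0.01] <- "**"
  structure(list(p = p_mat, tier = tier, gradients = grads,
                 site = if ("site" %in% names(meta)) meta$site[1] else NA_character_),
            class = "pairwise_pcga")
}

#' Between-provenance differentiation score
#'
#' The fraction of provenance pairs whose pairwise PCGA rank-sum test falls
#' below `alpha` -- the scalar on which sites are compared: high under
#' provenance-specific growth, low where a shared limiting factor
#' homogenizes growth patterns.
#'
#' @param result A `pairwise_pcga` object.
#' @param alpha Significance level (default 0.05).
#' @return Fraction in \[0, 1\].
#' @export
differentiation_score <- function(result, alpha = 0.05) {
  p <- result$p[upper.tri(result$p)]
  p <- p[!is.na(p)]
  if (!length(p)) stop_arg("no valid provenance pair")
  mean(p < alpha)
}

#' Export a pairwise PCGA p-value matrix in long form
#'
#' @param result A `pairwise_pcga` object.
#' @return Data frame `prov_a`, `prov_b`, `p`, `tier` (upper triangle).
#' @export
pcga_long_table <- function(result) {
  provs <- rownames(result$p)
  idx <- which(upper.tri(result$p), arr.ind = TRUE)
  data.frame(prov_a = provs[idx[, 1]], prov_b = provs[idx[, 2]],
             p = result$p[idx], tier = result$tier[idx],
             stringsAsFactors = FALSE)
}
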