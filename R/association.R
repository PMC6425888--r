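# The 20-month dendroclimatic window: previous-year March .. current-year
# October. Lag -1 marks previous-year months.
climate_window_months <- function() {
  data.frame(lag = c(rep(-1L, 10), rep(0L, 10)),
             month = c(3:12, 1:10),
             label = c(paste0("prev_", month.abb[3:12]),
                       paste0("curr_", month.abb[1:10])))
}

#' Climate--growth correlations over the dendroclimatic window
#'
#' Pearson correlation (with two-sided p) of a chronology with each monthly
#' climate covariate from previous-year March through current-year October --
#' 20 slots per variable. Months with undefined values (e.g. the spin-up of
#' an SPEI series) are excluded pairwise.
#'
#' @param chron A `chronology` (or data frame `year`, `value`).
#' @param climate_vars Named list of monthly series, each a data frame with
#'   columns `year`, `month` and one value column (its name is taken from the
#'   list name; any third column is used).
#' @param years Target-year range (integer vector); overlap with the
#'   chronology must be >= 20 years.
#' @return Data frame `variable`, `label`, `lag`, `month`, `n`, `r`, `p`,
#'   `tier` (`""`, `"*"` < 0.05, `"**"` < 0.01, `"***"` < 0.001).
#' @export
climate_growth_correlations <- function(chron, climate_vars, years) {
  win <- climate_window_months()
  years <- intersect(years, chron$year)
  if (length(years) < 20) stop_arg("chronology/climate overlap %d < 20 years",
                                   length(years))
  g <- chron$value[match(years, chron$year)]
  out <- list()
  for (v in names(climate_vars)) {
    cv <- climate_vars[[v]]
    valcol <- setdiff(names(cv), c("year", "month"))[1]
    key <- paste(cv$year, cv$month)
    for (k in seq_len(nrow(win))) {
      target <- cv[[valcol]][match(paste(years + win$lag[k], win$month[k]), key)]
      ok <- !is.na(target) & !is.na(g)
      if (sum(ok) >= 3) {
        ct <- stats::cor.test(g[ok], target[ok])
        r <- unname(ct$estimate)
        p <- ct$p.value
      } else {
        r <- NA_real_
        p <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        variable = v, label = win$label[k], lag = win$lag[k],
        month = win$month[k], n = sum(ok), r = r, p = p,
        tier = if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Agglomerative coefficient of a hierarchical clustering
#'
#' `1 - mean_i(h_first(i) / h_final)`, where `h_first(i)` is the height at
#' which object i first merges and `h_final` the height of the last merge.
#' Values near 1 indicate strong clustering structure.
#'
#' @param hc An `hclust` object.
#' @return Coefficient in \[0, 1\].
#' @export
agglomerative_coefficient <- function(hc) {
  n <- length(hc$height) + 1L
  first <- rep(NA_real_, n)
  for (j in seq_along(hc$height)) {
    for (obj in hc$merge[j, ]) {
      if (obj < 0 && is.na(first[-obj])) first[-obj] <- hc$height[j]
    }
  }
  1 - mean(first / max(hc$height))
}

#' Mojena stopping rule
#'
#' Scans the fusion heights in merge order and selects the partition just
#' before the first fusion whose height exceeds
#' `mean(heights) + constant * sd(heights)`. Returns 1 cluster when no fusion
#' exceeds the threshold.
#'
#' @param heights Fusion heights in merge order (from `hclust$height`).
#' @param constant Threshold constant (default 1.25, the value recommended in
#'   the follow-up literature on the rule).
#' @return Selected number of clusters.
#' @export
mojena_k <- function(heights, constant = 1.25) {
  if (length(heights) < 2) stop_arg("need >= 2 merges")
  thr <- mean(heights) + constant * stats::sd(heights)
  j <- which(heights > thr)[1]
  # n objects = length(heights) + 1; the partition just before merge j has
  # n - j + 1 clusters
  if (is.na(j)) 1L else length(heights) - j + 2L
}

#' Hierarchical clustering of provenance chronologies
#'
#' Euclidean distances between chronologies over their common period; single,
#' complete, UPGMA and Ward (minimum-variance on squared distances, heights
#' on the distance scale, i.e. `ward.D2`) linkages; the agglomerative
#' coefficient per method; the method with the highest coefficient is
#' selected and the Mojena rule applied to its tree.
#'
#' @param chron_mat Numeric matrix years x chronologies (colnames label the
#'   chronologies). Rows with any NA are dropped to the common period (with a
#'   warning); an empty common period is an error.
#' @param methods Linkage methods to compare.
#' @param mojena_constant Passed to [mojena_k()].
#' @return List of class `chronology_clustering`: `trees` (named list of
#'   `hclust`), `ac` (named coefficients), `selected` (method name), `k`,
#'   `membership` (cluster assignment at `k` for the selected tree).
#' @export
cluster_chronologies <- function(chron_mat,
                                 methods = c("single", "complete", "UPGMA", "Ward"),
                                 mojena_constant = 1.25) {
  m <- as.matrix(chron_mat)
  if (ncol(m) < 3) stop_arg("need >= 3 chronologies")
  ok <- rowSums(is.na(m)) == 0
  if (!any(ok)) stop_arg("chronologies share no common period")
  if (!all(ok)) {
    warning(sprintf("truncating to common period of %d years", sum(ok)),
            call. = FALSE)
    m <- m[ok, , drop = FALSE]
  }
  d <- stats::dist(t(m))
  linkage <- c(single = "single", complete = "complete",
               UPGMA = "average", Ward = "ward.D2")
  trees <- lapply(methods, function(mm) stats::hclust(d, method = linkage[[mm]]))
  names(trees) <- methods
  ac <- vapply(trees, agglomerative_coefficient, numeric(1))
  selected <- methods[which.max(ac)]
  k <- mojena_k(trees[[selected]]$height, mojena_constant)
  membership <- stats::cutree(trees[[selected]], k = k)
  structure(list(trees = trees, ac = ac, selected = selected, k = k,
                 membership = membership),
            class = "chronology_clustering")
}

#' Write a clustering tree as Newick
#'
#' Branch lengths derive from the merge heights (ultrametric tree).
#'
#' @param hc An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' PCA of bioclimatic profiles
#'
#' Principal component analysis of standardized bioclim vectors across
#' locations. Zero-variance variables are dropped with a warning. Eigenvalues
#' sum to the number of retained variables; the reported variance shares are
#' `eigenvalue / n_variables x 100`. Each component is oriented so that its
#' largest-magnitude variable correlation is positive, making the output
#' deterministic.
#'
#' @param mat Numeric matrix locations x variables (rownames = locations,
#'   colnames = variable names, no NA).
#' @param n_pc Number of components for the correlation table (default 3).
#' @return List of class `bioclim_pca`: `eigenvalues`, `variance_pct`,
#'   `correlations` (variables x `n_pc` Pearson correlations), `scores`,
#'   `dropped` (zero-variance variables).
#' @export
bioclim_pca <- function(mat, n_pc = 3) {
  m <- as.matrix(mat)
  if (nrow(m) < 3) stop_arg("need >= 3 locations")
  if (anyNA(m)) stop_arg("undefined bioclim entries; impute or drop first")
  v <- apply(m, 2, stats::var)
  dropped <- colnames(m)[v == 0]
  if (length(dropped)) {
    warning(sprintf("dropping zero-variance variables: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    m <- m[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  n_pc <- min(n_pc, ncol(pc$x))
  cors <- stats::cor(scale(m), pc$x[, seq_len(n_pc), drop = FALSE])
  for (k in seq_len(n_pc)) {
    if (cors[which.max(abs(cors[, k])), k] < 0) {
      cors[, k] <- -cors[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  structure(list(eigenvalues = eig,
                 variance_pct = eig / ncol(m) * 100,
                 correlations = cors,
                 scores = pc$x,
                 dropped = dropped),
            class = "bioclim_pca")
}
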