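#' Cropper values of an index series
#'
#' Standardizes each year within a moving window centered on it:
#' `C_t = (x_t - mean(window)) / sd(window)` with the sample (n-1) standard
#' deviation. The first and last `(window - 1)/2` years have no full centered
#' window and are undefined (NA), as are years whose window has zero
#' standard deviation (these are additionally listed in attribute
#' `zero_sd_years`).
#'
#' @param x Numeric index series (optionally named by year).
#' @param window Odd window length in years (default 5).
#' @return Numeric vector aligned with `x` (NA where undefined).
#' @export
cropper_values <- function(x, window = 5) {
  if (window %% 2 != 1 || window < 3) stop_arg("window must be odd and >= 3")
  n <- length(x)
  if (n < window) stop_arg("series length %d is below the window %d", n, window)
  h <- (window - 1L) / 2L
  out <- rep(NA_real_, n)
  zero_sd <- integer(0)
  for (t in (h + 1L):(n - h)) {
    win <- x[(t - h):(t + h)]
    s <- stats::sd(win)
    if (is.na(s) || s == 0) {
      zero_sd <- c(zero_sd, t)
    } else {
      out[t] <- (x[t] - mean(win)) / s
    }
  }
  names(out) <- names(x)
  if (length(zero_sd)) {
    attr(out, "zero_sd_years") <- if (!is.null(names(x))) {
      names(x)[zero_sd]
    } else {
      zero_sd
    }
  }
  out
}

#' Classify a Cropper value into a signed intensity class
#'
#' `|C| > 1.645` extreme, `> 1.28` strong, `> 1` weak, else none; the sign of
#' the class follows the sign of C. Encoded as an integer in `-3..3`
#' (0 = none, +/-1 weak, +/-2 strong, +/-3 extreme).
#'
#' @param c_values Numeric Cropper values (NA passes through).
#' @return Integer vector of signed class codes.
#' @export
classify_intensity <- function(c_values) {
  a <- abs(c_values)
  cls <- ifelse(a > 1.645, 3L, ifelse(a > 1.28, 2L, ifelse(a > 1, 1L, 0L)))
  out <- as.integer(sign(c_values) * cls)
  out[is.na(c_values)] <- NA_integer_
  out
}

intensity_labels <- c("extreme", "strong", "weak")

#' Pointer years of one provenance
#'
#' A year is assessable when at least `min_trees` trees have a defined
#' Cropper value. It is a pointer year of a given sign when at least
#' `series_threshold` of the assessable trees reach at least the weak class
#' of that sign; the pointer intensity is the highest class still reached by
#' that fraction of trees.
#'
#' @param class_codes Integer matrix years x trees of signed class codes
#'   (from [classify_intensity()]), rownames = years.
#' @param series_threshold Fraction of trees required (default 0.65).
#' @param min_trees Minimum assessable trees per year (default 5).
#' @param cropper Optional numeric matrix of the underlying Cropper values
#'   (same shape) used to report the per-year mean Cropper value.
#' @param provenance,site Labels stored on the table.
#' @return Data frame of class `pointer_table`: `year`, `n_trees`,
#'   `mean_cropper`, per-class tree fractions, `pointer` (signed intensity
#'   code, 0 = none), `assessable`.
#' @export
provenance_pointer_years <- function(class_codes, series_threshold = 0.65,
                                     min_trees = 5, cropper = NULL,
                                     provenance = NA_character_,
                                     site = NA_character_) {
  m <- as.matrix(class_codes)
  years <- as.integer(rownames(m))
  rows <- lapply(seq_len(nrow(m)), function(i) {
    cls <- m[i, ]
    cls <- cls[!is.na(cls)]
    mc <- if (!is.null(cropper)) mean(cropper[i, ], na.rm = TRUE) else NA_real_
    nd <- length(cls)
    assess <- nd >= min_trees
    fr <- vapply(c(-3L, -2L, -1L, 1L, 2L, 3L), function(k) {
      if (nd) mean(cls == k) else 0
    }, numeric(1))
    ptr <- 0L
    if (assess) {
      for (k in 3:1) {       # strongest class satisfied by the threshold
        if (mean(cls <= -k) >= series_threshold) {
          ptr <- -k
          break
        }
        if (mean(cls >= k) >= series_threshold) {
          ptr <- k
          break
        }
      }
    }
    data.frame(year = years[i], n_trees = nd, mean_cropper = mc,
               f_neg_extreme = fr[1], f_neg_strong = fr[2], f_neg_weak = fr[3],
               f_pos_weak = fr[4], f_pos_strong = fr[5], f_pos_extreme = fr[6],
               pointer = ptr, assessable = assess)
  })
  structure(do.call(rbind, rows), provenance = provenance, site = site,
            class = c("pointer_table", "data.frame"))
}

#' Single-tree pointer analysis of an RWI table
#'
#' Convenience wrapper: Cropper values and intensity classes per tree, then
#' [provenance_pointer_years()] per provenance of one site.
#'
#' @param rwi Wide RWI data frame.
#' @param meta Metadata with `series`, `provenance`, `site`.
#' @param window,series_threshold,min_trees Passed through.
#' @return Named list of `pointer_table`, one per provenance.
#' @export
pointer_year_analysis <- function(rwi, meta, window = 5,
                                  series_threshold = 0.65, min_trees = 5) {
  stopifnot(length(unique(meta$site)) == 1)
  provs <- unique(meta$provenance)
  out <- lapply(provs, function(p) {
    ids <- meta$series[meta$provenance == p]
    cc <- vapply(ids, function(id) {
      v <- rwi[[id]]
      cv <- rep(NA_real_, length(v))
      idx <- which(!is.na(v))
      if (length(idx) >= window) cv[idx] <- cropper_values(v[idx], window)
      cv
    }, numeric(nrow(rwi)))
    rownames(cc) <- rownames(rwi)
    codes <- apply(cc, 2, classify_intensity)
    dimnames(codes) <- dimnames(cc)
    provenance_pointer_years(codes, series_threshold, min_trees, cropper = cc,
                             provenance = p, site = meta$site[1])
  })
  stats::setNames(out, provs)
}

#' Common pointer years across provenances
#'
#' A year is a common pointer year (CPY) of a given sign when at least
#' `min_provenances` provenances flag a pointer year of that sign at the
#' same site.
#'
#' @param tables List of `pointer_table` for one site, sharing the year span.
#' @param min_provenances Required provenance count (default 6).
#' @return Data frame `year`, `n_pos`, `n_neg`, `cpy` (+1, -1 or 0; +1 and
#'   -1 can co-occur in principle and are then reported as two rows).
#' @export
common_pointer_years <- function(tables, min_provenances = 6) {
  sites <- unique(vapply(tables, attr, character(1), "site"))
  if (length(sites) != 1) stop_arg("pointer tables mix sites: %s",
                                   paste(sites, collapse = ", "))
  years <- tables[[1]]$year
  same <- all(vapply(tables, function(t) identical(t$year, years), logical(1)))
  if (!same) stop_arg("pointer tables do not share the year span")
  n_pos <- rowSums(vapply(tables, function(t) t$pointer > 0, logical(length(years))))
  n_neg <- rowSums(vapply(tables, function(t) t$pointer < 0, logical(length(years))))
  cpy <- integer(length(years))
  cpy[n_pos >= min_provenances] <- 1L
  cpy[n_neg >= min_provenances] <- -1L   # sign-wise; both reaching is impossible
  data.frame(year = years, n_pos = n_pos, n_neg = n_neg, cpy = cpy)
}

#' Plot-ready long pointer table
#'
#' @param tables Named list of `pointer_table` (one per provenance).
#' @return Data frame `site`, `provenance`, `year`, `sign`, `intensity`
#'   (only flagged years).
#' @export
pointer_long_table <- function(tables) {
  rows <- lapply(tables, function(t) {
    f <- t[t$pointer != 0, ]
    if (!nrow(f)) return(NULL)
    data.frame(site = attr(t, "site"), provenance = attr(t, "provenance"),
               year = f$year, sign = sign(f$pointer),
               intensity = intensity_labels[4 - abs(f$pointer)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(site = character(), provenance = character(),
                      year = integer(), sign = integer(),
                      intensity = character())
  }
  rownames(out) <- NULL
  out
}
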