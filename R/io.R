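# Tucson/RWL dialects. Values are stored as integers in units of the
# measurement precision; the end-of-series sentinel doubles as the dialect
# marker (999 for 0.01 mm data, -9999 for 0.001 mm data).
rwl_dialects <- list(
  "0.01"  = list(precision = 0.01,  sentinel = 999L),
  "0.001" = list(precision = 0.001, sentinel = -9999L)
)

#' Read a decadal Tucson/RWL ring-width file
#'
#' Parses the classic decadal layout: series id in columns 1--8, the first
#' year of the line in columns 9--12, then one integer value per year of that
#' decade. The end-of-series sentinel is consumed and series ids are
#' preserved verbatim.
#'
#' @param path File path.
#' @param dialect `"0.01"` (precision 0.01 mm, sentinel 999) or `"0.001"`
#'   (precision 0.001 mm, sentinel -9999).
#' @return Wide data frame (rownames = years, one column per series, widths
#'   in mm, NA outside each series span) with attribute `dialect`.
#' @export
read_rwl <- function(path, dialect = c("0.01", "0.001")) {
  dialect <- match.arg(dialect)
  d <- rwl_dialects[[dialect]]
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  lines <- readLines(path)
  series <- list()   # id -> list(first_year, widths)
  open_id <- NULL
  open_first <- NA_integer_
  open_vals <- integer(0)
  expect_year <- NA_integer_
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    id <- trimws(substr(line, 1, 8))
    year <- suppressWarnings(as.integer(substr(line, 9, 12)))
    toks <- strsplit(trimws(substr(line, 13, nchar(line))), "\\s+")[[1]]
    vals <- suppressWarnings(as.integer(toks))
    if (!nzchar(id) || is.na(year) || (length(toks) && anyNA(vals))) {
      stop_arg("malformed decade line %d in %s", ln, path)
    }
    if (is.null(open_id)) {
      open_id <- id
      open_first <- year
      expect_year <- year
    } else if (!identical(id, open_id)) {
      stop_arg("series '%s' ends at line %d without its end-of-series sentinel",
               open_id, ln - 1L)
    }
    if (year != expect_year) {
      if (year < expect_year) {
        stop_arg("overlapping years in series '%s' at line %d", id, ln)
      }
      stop_arg("gap in years of series '%s' at line %d (expected %d, found %d)",
               id, ln, expect_year, year)
    }
    closed <- FALSE
    for (v in vals) {
      if (v == d$sentinel) {
        if (!is.null(series[[open_id]])) {
          stop_arg("duplicate series id '%s' at line %d", open_id, ln)
        }
        series[[open_id]] <- list(first_year = open_first, widths = open_vals)
        open_id <- NULL
        open_vals <- integer(0)
        closed <- TRUE
        break
      }
      open_vals <- c(open_vals, v)
    }
    if (!closed) expect_year <- year + length(vals)
  }
  if (!is.null(open_id)) {
    stop_arg("file truncated: series '%s' has no end-of-series sentinel", open_id)
  }
  if (!length(series)) {
    out <- data.frame()
    attr(out, "dialect") <- dialect
    return(out)
  }
  yr_min <- min(vapply(series, `[[`, integer(1), "first_year"))
  yr_max <- max(vapply(series, function(s) {
    s$first_year + length(s$widths) - 1L
  }, integer(1)))
  years <- yr_min:yr_max
  m <- matrix(NA_real_, length(years), length(series),
              dimnames = list(years, names(series)))
  for (id in names(series)) {
    s <- series[[id]]
    rows <- s$first_year:(s$first_year + length(s$widths) - 1L) - yr_min + 1L
    m[rows, id] <- s$widths * d$precision
  }
  out <- as.data.frame(m, check.names = FALSE)
  attr(out, "dialect") <- dialect
  out
}

#' Write a ring-width table in decadal Tucson/RWL layout
#'
#' Inverse of [read_rwl()]: `read_rwl(write_rwl(x))` reproduces `x`, and a
#' second write of the re-read data is byte-identical. A series starting
#' mid-decade is written on a shortened first line per the Tucson
#' convention.
#'
#' @param rwl Wide ring-width data frame (rownames = years, mm).
#' @param path Output path.
#' @param dialect See [read_rwl()].
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rwl, path, dialect = c("0.01", "0.001")) {
  dialect <- match.arg(dialect)
  d <- rwl_dialects[[dialect]]
  con <- file(path, "wb")
  on.exit(close(con))
  if (!ncol(rwl)) return(invisible(path))
  years <- as.integer(rownames(rwl))
  for (id in colnames(rwl)) {
    if (nchar(id) > 8) stop_arg("series id '%s' exceeds 8 characters", id)
    v <- rwl[[id]]
    idx <- which(!is.na(v))
    if (!length(idx)) next
    if (any(diff(idx) != 1L)) {
      stop_arg("series '%s' has internal gaps; RWL requires consecutive years", id)
    }
    units <- v[idx] / d$precision
    iu <- round(units)
    if (any(abs(units - iu) > 1e-6)) {
      stop_arg("series '%s' has widths not representable at %s mm precision",
               id, dialect)
    }
    if (any(iu == d$sentinel) || any(iu > 99999) || any(iu < -999)) {
      stop_arg("series '%s' has a value outside the %s dialect field range",
               id, dialect)
    }
    seq_vals <- c(as.integer(iu), d$sentinel)
    yr <- years[idx[1]]
    pos <- 1L
    while (pos <= length(seq_vals)) {
      dec_end <- (yr %/% 10) * 10 + 9
      take <- min(dec_end - yr + 1L, length(seq_vals) - pos + 1L)
      vals <- seq_vals[pos:(pos + take - 1L)]
      writeLines(sprintf("%-8s%4d%s", id, yr,
                         paste(sprintf("%6d", vals), collapse = "")),
                 con)
      pos <- pos + take
      yr <- dec_end + 1L
    }
  }
  invisible(path)
}

#' Write / read a monthly climate CSV
#'
#' The site id and latitude travel in `#`-prefixed header comments, followed
#' by a plain CSV with columns `year,month,tmean,tmax,tmin,prec`.
#'
#' @param climate A `monthly_climate` table.
#' @param path File path.
#' @return `write_climate_csv`: `path` invisibly. `read_climate_csv`: a
#'   validated `monthly_climate` with attribute `incomplete_years` listing
#'   years lacking months (these are excluded from index calculations by the
#'   consumers, which call [complete_years()]).
#' @export
write_climate_csv <- function(climate, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# site: %s", attr(climate, "site")),
               sprintf("# latitude: %.6f", attr(climate, "latitude"))), con)
  utils::write.csv(as.data.frame(climate), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    ln <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (!length(ln)) stop_arg("climate CSV lacks '# %s:' header", key)
    trimws(sub(sprintf("^#\\s*%s:", key), "", ln[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  clim <- monthly_climate(df, site = get_field("site"),
                          latitude = as.numeric(get_field("latitude")))
  tab <- table(clim$year)
  attr(clim, "incomplete_years") <- as.integer(names(tab)[tab < 12L])
  clim
}

#' Read an externally supplied PDSI series
#'
#' The Palmer drought severity index is consumed, never computed: this loader
#' only validates a monthly CSV (`year,month,pdsi`).
#'
#' @param path File path.
#' @return Data frame `year`, `month`, `pdsi`.
#' @export
read_pdsi_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("year", "month", "pdsi")
  if (!all(need %in% names(df))) {
    stop_arg("PDSI CSV must have columns %s", paste(need, collapse = ", "))
  }
  if (any(df$month < 1 | df$month > 12)) stop_arg("month out of range 1..12")
  df[order(df$year, df$month), need]
}

#' Export the long-format single-tree index table
#'
#' One row per tree x year with the prewhitened index, the shape consumed by
#' external repeated-measures fits (e.g. a GEE over site, provenance and
#' year). Column order is fixed: `site, provenance, tree, year, rwi`.
#'
#' @param rwi Wide RWI data frame.
#' @param meta Metadata with `series`, `tree`, `provenance`, `site`.
#' @param path Optional CSV output path.
#' @return The long data frame (invisibly when `path` is given).
#' @export
export_long_table <- function(rwi, meta, path = NULL) {
  years <- as.integer(rownames(rwi))
  rows <- lapply(colnames(rwi), function(id) {
    v <- rwi[[id]]
    ok <- !is.na(v)
    mrow <- meta[meta$series == id, ]
    if (nrow(mrow) != 1) stop_arg("series '%s' missing from metadata", id)
    data.frame(site = mrow$site, provenance = mrow$provenance,
               tree = mrow$tree, year = years[ok], rwi = v[ok],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
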