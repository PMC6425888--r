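#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All stochastic entry points route through this so that a single integer seed
# reproduces a scenario bit-for-bit regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to stamp output files with a fingerprint of the configuration that
# produced them (no cryptographic intent).
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits (kept exact in doubles)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply, split so every product stays below 2^53
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  # h is a double holding an unsigned 32-bit value; print as two 16-bit halves
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

days_in_month <- function(month, year = 2001L) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- dm[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  d[month == 2L & leap] <- 29L
  d
}

month_abb <- function(m) month.abb[m]

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)
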