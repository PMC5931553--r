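# Internal helpers shared across modules.

#' Decay constant of 210Pb
#'
#' `log(2) / 22.3` per year, the standard constant used by the constant
#' rate of supply (CRS) dating literature (half-life 22.3 yr).
#'
#' @format A length-one numeric, units yr^-1.
#' @export
pb210_lambda <- log(2) / 22.3

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. `seed = NULL` leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopifnot_cols <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# FNV-1a 32-bit hash of a character scalar; used to stamp pipeline outputs
# with a config fingerprint without an external digest dependency.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep arithmetic in doubles
    h <- (h - (h %% 256)) + bitwXor(h %% 256, b)
    # 32-bit multiply by the FNV prime 16777619 = 2^24 + 403, piecewise so
    # intermediates stay below 2^53
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

doy_of <- function(dates) as.integer(format(dates, "%j"))
year_of <- function(dates) as.integer(format(dates, "%Y"))

days_in_year <- function(year) {
  ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366L, 365L)
}
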