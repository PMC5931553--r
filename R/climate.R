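# Sea-ice phenology from daily concentration series, stacked-station
# temperature reconstruction, melting-season length, and decadal trends.

#' Regional mean of a gridded daily sea-ice concentration product
#'
#' Averages daily sea-ice concentration (SIC, %) over the ocean cells of
#' a region. On an equal-area grid every cell carries the same area, so
#' the unweighted mean is the areal mean. Days where fewer than
#' `min_valid_frac` of the region's cells report are marked missing.
#'
#' @param grid long-format data.frame `date, cell_id, sic_percent`.
#' @param cells optional cell metadata `cell_id, lat, lon` and optionally
#'   `ocean` (logical); required when `region` is a lat/lon box.
#' @param region either a vector of cell ids, or a list with `lat` and
#'   `lon` range vectors (`c(min, max)`); `NULL` uses every (ocean) cell.
#' @param min_valid_frac minimum fraction of region cells with data for a
#'   day to be retained.
#' @return data.frame `date, sic_percent` (daily series, missing days NA).
#' @export
regional_mean_sic <- function(grid, cells = NULL, region = NULL,
                              min_valid_frac = 0.5) {
  stopifnot_cols(grid, c("date", "cell_id", "sic_percent"), "SIC grid")
  keep_ids <- unique(grid$cell_id)
  if (!is.null(cells)) {
    stopifnot_cols(cells, c("cell_id"), "cell table")
    if (!is.null(cells$ocean)) cells <- cells[cells$ocean, , drop = FALSE]
    keep_ids <- cells$cell_id
  }
  if (!is.null(region)) {
    if (is.list(region)) {
      if (is.null(cells)) stop("a lat/lon region needs a cell table")
      sel <- cells$lat >= region$lat[1] & cells$lat <= region$lat[2] &
        cells$lon >= region$lon[1] & cells$lon <= region$lon[2]
      keep_ids <- cells$cell_id[sel]
    } else {
      keep_ids <- intersect(keep_ids, region)
    }
  }
  if (length(keep_ids) == 0L) stop("region selects no grid cells")
  g <- grid[grid$cell_id %in% keep_ids, , drop = FALSE]
  if (nrow(g) == 0L) stop("region selects no grid cells with data")
  n_region <- length(keep_ids)
  dates <- sort(unique(g$date))
  valid <- !is.na(g$sic_percent)
  mean_by_date <- tapply(g$sic_percent[valid], factor(g$date[valid],
                                                      levels = dates), mean)
  n_by_date <- tapply(valid, factor(g$date, levels = dates), sum)
  out <- data.frame(date = dates,
                    sic_percent = as.numeric(mean_by_date))
  out$sic_percent[is.na(n_by_date) |
                    n_by_date < min_valid_frac * n_region] <- NA_real_
  out
}

#' Annual sea-ice phenology
#'
#' For one calendar year of a daily regional SIC series: the number of
#' ice-free days (SIC below `threshold_free`, the paper-style 55 %
#' cutoff), the number of high-ice days (SIC above `threshold_high`),
#' and melt/freeze onsets taken from the longest run of consecutive
#' sub-threshold days (melt onset = first day of that run, freeze onset =
#' first day after it). Missing days are excluded from all counts and
#' break runs; a year with fewer than `min_days` valid days is flagged
#' low-coverage. Results do not depend on the input row order.
#'
#' @param series data.frame `date, sic_percent`.
#' @param year calendar year to evaluate.
#' @param threshold_free ice-free threshold, % (days strictly below).
#' @param threshold_high high-ice threshold, % (days strictly above).
#' @param min_days coverage requirement for an unflagged year.
#' @return one-row data.frame: `year, ice_free_days, high_ice_days,
#'   melt_onset_doy, freeze_onset_doy, n_valid, coverage_fraction,
#'   low_coverage`.
#' @export
ice_phenology <- function(series, year, threshold_free = 55,
                          threshold_high = 75, min_days = 300) {
  stopifnot_cols(series, c("date", "sic_percent"), "SIC series")
  series <- series[order(series$date), , drop = FALSE]
  sel <- year_of(series$date) == year
  diy <- days_in_year(year)
  # project onto the full calendar year so missing days are explicit
  v <- rep(NA_real_, diy)
  v[doy_of(series$date[sel])] <- series$sic_percent[sel]
  n_valid <- sum(!is.na(v))
  free <- !is.na(v) & v < threshold_free
  high <- !is.na(v) & v > threshold_high
  melt <- freeze <- NA_integer_
  if (any(free)) {
    runs <- rle(free)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    longest <- which(runs$values)[which.max(runs$lengths[runs$values])]
    melt <- starts[longest]
    freeze <- ends[longest] + 1L
  }
  data.frame(
    year = year,
    ice_free_days = sum(free),
    high_ice_days = sum(high),
    melt_onset_doy = melt,
    freeze_onset_doy = freeze,
    n_valid = n_valid,
    coverage_fraction = n_valid / diy,
    low_coverage = n_valid < min_days
  )
}

#' Period-mean sea-ice phenology
#'
#' Computes [ice_phenology()] for each year of a period and averages the
#' per-year metrics over qualifying (non-low-coverage) years.
#'
#' @param series data.frame `date, sic_percent`.
#' @param years vector of calendar years.
#' @param ... passed to [ice_phenology()].
#' @return list with `mean` (one-row data.frame of period means),
#'   `table` (per-year phenology) and `excluded_years`.
#' @export
period_phenology <- function(series, years, ...) {
  tab <- do.call(rbind, lapply(years, function(y)
    ice_phenology(series, y, ...)))
  ok <- !tab$low_coverage
  if (!any(ok)) stop("no qualifying years (all low-coverage)")
  qual <- tab[ok, , drop = FALSE]
  list(
    mean = data.frame(
      ice_free_days = mean(qual$ice_free_days),
      high_ice_days = mean(qual$high_ice_days),
      melt_onset_doy = mean(qual$melt_onset_doy, na.rm = TRUE),
      freeze_onset_doy = mean(qual$freeze_onset_doy, na.rm = TRUE),
      n_years = sum(ok)
    ),
    table = tab,
    excluded_years = tab$year[!ok]
  )
}

#' Stack station temperature series into a blended record
#'
#' Per day, averages the daily mean and daily maximum temperatures over
#' all stations reporting that day (mean and max handled separately);
#' days with fewer than `min_stations` reporting are marked missing.
#'
#' @param stations long-format data.frame `date, station, tmean_c, tmax_c`.
#' @param min_stations minimum stations required per day.
#' @return data.frame `date, tmean_c, tmax_c, n_stations`.
#' @export
stack_stations <- function(stations, min_stations = 2) {
  stopifnot_cols(stations, c("date", "station", "tmean_c", "tmax_c"),
                 "station table")
  if (nrow(stations) == 0L) stop("empty station table")
  dates <- sort(unique(stations$date))
  f <- factor(stations$date, levels = dates)
  day_mean <- function(v) {
    m <- tapply(v, f, mean, na.rm = TRUE)
    n <- tapply(!is.na(v), f, sum)
    m[is.na(n) | n < min_stations] <- NA_real_
    as.numeric(m)
  }
  n_rep <- as.integer(tapply(!is.na(stations$tmean_c), f, sum))
  out <- data.frame(date = dates,
                    tmean_c = day_mean(stations$tmean_c),
                    tmax_c = day_mean(stations$tmax_c),
                    n_stations = ifelse(is.na(n_rep), 0L, n_rep))
  out
}

#' Shift a blended record to the core site
#'
#' Applies a constant signed offset to every daily temperature — the
#' difference in annual mean temperature between the blended station
#' record and the core site (default -1.6 degrees C: the site is colder).
#' The offset and its uncertainty are recorded as attributes.
#'
#' @param blended data.frame with `tmean_c` and/or `tmax_c` columns.
#' @param offset signed offset, degrees C.
#' @param offset_sigma uncertainty of the offset, degrees C.
#' @return the shifted data.frame, with attributes `offset_c` and
#'   `offset_sigma_c`.
#' @export
site_temperature <- function(blended, offset = -1.6, offset_sigma = 0.5) {
  if (!is_scalar_number(offset)) stop("offset must be a finite number")
  for (col in intersect(c("tmean_c", "tmax_c"), names(blended))) {
    blended[[col]] <- blended[[col]] + offset
  }
  attr(blended, "offset_c") <- offset
  attr(blended, "offset_sigma_c") <- offset_sigma
  blended
}

#' Melting-season length
#'
#' The annual number of days whose daily maximum temperature exceeds the
#' melting point (0 degrees C). Missing days are excluded; coverage is
#' reported alongside.
#'
#' @param series data.frame `date, tmax_c`.
#' @param years calendar years to evaluate; default every year present.
#' @return data.frame `year, melt_days, n_valid, coverage_fraction`.
#' @export
melting_season_length <- function(series, years = NULL) {
  stopifnot_cols(series, c("date", "tmax_c"), "temperature series")
  yr <- year_of(series$date)
  years <- years %||% sort(unique(yr))
  do.call(rbind, lapply(years, function(y) {
    v <- series$tmax_c[yr == y]
    data.frame(year = y,
               melt_days = sum(v > 0, na.rm = TRUE),
               n_valid = sum(!is.na(v)),
               coverage_fraction = sum(!is.na(v)) / days_in_year(y))
  }))
}

#' Decadal linear trend of an annual series
#'
#' Ordinary least squares of an annual value on calendar year, reported
#' per decade: `slope_per_decade = 10 * slope`, with the slope's standard
#' error scaled likewise, the regression R^2, and a two-sided t-test
#' p-value on n - 2 degrees of freedom.
#'
#' @param x data.frame with columns `year` and `value`, or a numeric
#'   vector of years (then supply `values`).
#' @param values annual values when `x` is a year vector.
#' @param min_years minimum number of years required.
#' @return An object of class `trend_estimate`: list with
#'   `slope_per_decade, slope_se, r_squared, p_value, n_years, intercept`.
#' @export
linear_trend <- function(x, values = NULL, min_years = 10) {
  if (is.data.frame(x)) {
    stopifnot_cols(x, c("year", "value"), "annual series")
    years <- x$year; values <- x$value
  } else {
    years <- x
  }
  ok <- !is.na(years) & !is.na(values)
  years <- years[ok]; values <- values[ok]
  if (length(years) < min_years)
    stop(sprintf("need at least %d years for a trend", min_years))
  if (stats::var(values) == 0)
    stop("constant series: trend variance undefined")
  fit <- stats::lm(values ~ years)
  s <- summary(fit)
  structure(list(
    slope_per_decade = 10 * unname(stats::coef(fit)[2]),
    slope_se = 10 * s$coefficients[2, 2],
    r_squared = s$r.squared,
    p_value = s$coefficients[2, 4],
    n_years = length(years),
    intercept = unname(stats::coef(fit)[1])
  ), class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf(
    "Trend: %.3g +/- %.2g per decade over %d years (R^2 = %.2f, p = %.2g)\n",
    x$slope_per_decade, x$slope_se, x$n_years, x$r_squared, x$p_value))
  invisible(x)
}
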