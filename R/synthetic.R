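# Synthetic-data generators. Every input class of the pipeline can be
# emulated with known ground truth, so chronology, zonation and climate
# stages are testable by parameter recovery rather than by downloads.

#' Describe a synthetic sedimentation and fallout history
#'
#' A scenario prescribes a piecewise-constant mass accumulation history, a
#' constant atmospheric flux of unsupported 210Pb (the CRS premise), a
#' supported 210Pb level equal to the in-situ 226Ra activity, and a 137Cs
#' fallout pulse centred on the atmospheric bomb-testing maximum.
#'
#' @param epochs data.frame with columns `start_year`, `end_year` (calendar
#'   years AD) and `mar` (dry-mass accumulation rate, g cm^-2 yr^-1).
#'   Epochs must be contiguous and ordered oldest first; the last
#'   `end_year` is the core collection year. The default rises from
#'   0.006 to 0.05 g cm^-2 yr^-1 over 1900-2015, i.e. from 0.03 to
#'   0.25 cm/yr at the default bulk density.
#' @param pb_flux constant supply of unsupported 210Pb, Bq cm^-2 yr^-1.
#' @param supported_activity 226Ra-supported 210Pb level, Bq/kg.
#' @param cs_pulse_year calendar year of the 137Cs fallout maximum.
#' @param cs_pulse_magnitude peak 137Cs activity, Bq/kg.
#' @param cs_pulse_sigma width (standard deviation, yr) of the Gaussian
#'   fallout pulse in deposition age; 2 yr produces the broad maximum seen
#'   in real profiles rather than a single-slice spike.
#' @param noise_cv fractional coefficient of variation of the multiplicative
#'   lognormal measurement noise applied to all activities.
#' @param bulk_density dry bulk density, g cm^-3, assumed constant (the
#'   generator exposes dry mass per slice directly; no compaction model).
#' @param core_area_cm2 cross-sectional area of the core barrel.
#' @param seed integer seed making the generated profile reproducible.
#' @return An object of class `sediment_scenario`.
#' @seealso [gen_core()]
#' @export
sediment_scenario <- function(epochs = data.frame(
                                start_year = c(1900, 1950, 1980, 2000),
                                end_year   = c(1950, 1980, 2000, 2015),
                                mar        = c(0.006, 0.012, 0.024, 0.05)),
                              pb_flux = 0.005,
                              supported_activity = 25,
                              cs_pulse_year = 1963,
                              cs_pulse_magnitude = 300,
                              cs_pulse_sigma = 2,
                              noise_cv = 0.05,
                              bulk_density = 0.2,
                              core_area_cm2 = 1,
                              seed = 1L) {
  stopifnot_cols(epochs, c("start_year", "end_year", "mar"), "epochs")
  if (nrow(epochs) < 1L) stop("at least one epoch is required")
  if (any(epochs$end_year <= epochs$start_year))
    stop("each epoch must have end_year > start_year")
  if (nrow(epochs) > 1L &&
      any(abs(epochs$start_year[-1] - epochs$end_year[-nrow(epochs)]) > 1e-9))
    stop("epochs must be contiguous and ordered oldest first")
  if (any(epochs$mar <= 0)) stop("all mass accumulation rates must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (pb_flux <= 0 || bulk_density <= 0 || core_area_cm2 <= 0)
    stop("pb_flux, bulk_density and core_area_cm2 must be > 0")
  structure(list(
    epochs = epochs, pb_flux = pb_flux,
    supported_activity = supported_activity,
    cs_pulse_year = cs_pulse_year,
    cs_pulse_magnitude = cs_pulse_magnitude,
    cs_pulse_sigma = cs_pulse_sigma,
    noise_cv = noise_cv, bulk_density = bulk_density,
    core_area_cm2 = core_area_cm2, seed = seed,
    collection_year = epochs$end_year[nrow(epochs)]
  ), class = "sediment_scenario")
}

# Piecewise-linear depth <-> age maps for a scenario. Depth is measured
# downward from the sediment-water interface at collection time.
scenario_geometry <- function(scenario) {
  ep <- scenario$epochs
  n <- nrow(ep)
  v <- ep$mar / scenario$bulk_density           # cm/yr, oldest first
  thick <- v * (ep$end_year - ep$start_year)    # cm per epoch
  # cumulative depth of each epoch top, newest (shallowest) first
  ord <- n:1
  depth_top <- cumsum(c(0, thick[ord]))[seq_len(n)]   # top of epoch ord[i]
  list(
    # age in years before collection at depth z (vectorised)
    age_below_surface = function(z) {
      t_out <- numeric(length(z))
      for (i in seq_len(n)) {
        j <- ord[i]
        lo <- depth_top[i]; hi <- depth_top[i] + thick[j]
        sel <- z >= lo & (z < hi | (i == n & z <= hi + 1e-9))
        t_out[sel] <- (scenario$collection_year - ep$end_year[j]) +
          (z[sel] - lo) / v[j]
      }
      bad <- z < 0 | z > sum(thick) + 1e-9
      t_out[bad] <- NA_real_
      t_out
    },
    total_depth = sum(thick),
    linear_rate = function(z) {
      r <- numeric(length(z))
      for (i in seq_len(n)) {
        j <- ord[i]
        lo <- depth_top[i]; hi <- depth_top[i] + thick[j]
        sel <- z >= lo & (z < hi | (i == n & z <= hi + 1e-9))
        r[sel] <- v[j]
      }
      r
    }
  )
}

#' Generate a synthetic radiometric core profile
#'
#' Slices the scenario's sediment column into 1 cm intervals (the field
#' protocol) and computes, per slice, the mass-averaged unsupported 210Pb
#' activity implied by constant flux and exponential decay, the supported
#' (226Ra) level, and a Gaussian 137Cs fallout pulse. Multiplicative
#' lognormal noise with coefficient of variation `scenario$noise_cv` is
#' applied to each activity; reported measurement sigmas equal the
#' noise-free activity times `noise_cv`.
#'
#' @param scenario a [sediment_scenario()].
#' @return A list with elements:
#'   \describe{
#'     \item{profile}{data.frame, one row per 1 cm slice, with columns
#'       `depth_top_cm, depth_bottom_cm, dry_mass_g, pb210_bq_kg, pb210_sd,
#'       ra226_bq_kg, ra226_sd, cs137_bq_kg, cs137_sd`.}
#'     \item{true_age}{function mapping depth (cm) to true calendar age AD.}
#'     \item{true_excess}{function mapping depth to the noise-free
#'       unsupported 210Pb point activity, Bq/kg.}
#'     \item{scenario}{the input scenario.}
#'   }
#' @export
gen_core <- function(scenario) {
  stopifnot(inherits(scenario, "sediment_scenario"))
  geom <- scenario_geometry(scenario)
  n_slices <- floor(geom$total_depth + 1e-9)
  if (n_slices < 2L)
    stop("scenario spans fewer than 2 one-cm slices; extend the epochs")
  lambda <- pb210_lambda
  rho <- scenario$bulk_density
  top <- 0:(n_slices - 1L)
  bot <- top + 1
  t_top <- geom$age_below_surface(top)
  t_bot <- geom$age_below_surface(bot)
  t_mid <- geom$age_below_surface(top + 0.5)
  # Exact mass-averaged excess activity over each slice: integrating the
  # flux history over the slice's deposition window and dividing by the
  # slice dry mass per unit area (rho * 1 cm). Units: Bq/kg.
  excess_true <- 1000 * scenario$pb_flux / (lambda * rho) *
    (exp(-lambda * t_top) - exp(-lambda * t_bot))
  cs_true <- scenario$cs_pulse_magnitude *
    exp(-((scenario$collection_year - t_mid) - scenario$cs_pulse_year)^2 /
          (2 * scenario$cs_pulse_sigma^2))
  ra_true <- rep(scenario$supported_activity, n_slices)
  pb_total_true <- excess_true + ra_true
  cv <- scenario$noise_cv
  noisy <- function(x) {
    if (cv == 0) return(x)
    sdlog <- sqrt(log(1 + cv^2))
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  profile <- with_seed(scenario$seed, {
    data.frame(
      depth_top_cm = top, depth_bottom_cm = bot,
      dry_mass_g = rho * scenario$core_area_cm2 * 1,
      pb210_bq_kg = noisy(pb_total_true), pb210_sd = cv * pb_total_true,
      ra226_bq_kg = noisy(ra_true), ra226_sd = cv * ra_true,
      cs137_bq_kg = noisy(cs_true), cs137_sd = cv * pmax(cs_true, 1e-6)
    )
  })
  list(
    profile = profile,
    true_age = function(depth) {
      scenario$collection_year - geom$age_below_surface(depth)
    },
    true_excess = function(depth) {
      t <- geom$age_below_surface(depth)
      1000 * scenario$pb_flux /
        (geom$linear_rate(depth) * rho) * exp(-lambda * t)
    },
    scenario = scenario
  )
}

#' Describe a synthetic zoned assemblage
#'
#' @param n_samples number of stratigraphic samples (shallowest first).
#' @param boundaries integer sample indices; a boundary at `b` places the
#'   zone break between samples `b` and `b + 1`. Must be strictly
#'   increasing and inside `(0, n_samples)`.
#' @param zone_compositions matrix, one row per zone (length(boundaries)+1
#'   rows), each row a taxon proportion vector summing to 1.
#' @param concentration_parameter Dirichlet dispersion; `Inf` means every
#'   sample has exactly its zone's composition (no compositional noise).
#' @param counts_per_sample total individuals counted per sample.
#' @param marker_added exotic-marker particles added per sample.
#' @param dry_mass sample dry mass, g.
#' @param true_concentration true total microfossil concentration, per g;
#'   the expected number of markers counted alongside
#'   `counts_per_sample` individuals is implied by this concentration.
#' @param group counting group label (`"diatom"`, `"pediastrum"`, `"pollen"`).
#' @param seed integer seed.
#' @return An object of class `zone_scenario`.
#' @export
zone_scenario <- function(n_samples,
                          boundaries,
                          zone_compositions,
                          concentration_parameter = 100,
                          counts_per_sample = 300,
                          marker_added = 2136,
                          dry_mass = 0.5,
                          true_concentration = 5000,
                          group = "diatom",
                          seed = 1L) {
  zone_compositions <- as.matrix(zone_compositions)
  if (length(boundaries) > 0) {
    if (any(diff(boundaries) <= 0))
      stop("boundaries must be strictly increasing")
    if (any(boundaries <= 0 | boundaries >= n_samples))
      stop("boundaries must lie strictly inside (0, n_samples)")
  }
  if (nrow(zone_compositions) != length(boundaries) + 1L)
    stop("need exactly length(boundaries) + 1 zone composition rows")
  if (any(abs(rowSums(zone_compositions) - 1) > 1e-8))
    stop("each zone composition must sum to 1")
  structure(list(
    n_samples = as.integer(n_samples), boundaries = as.integer(boundaries),
    zone_compositions = zone_compositions,
    concentration_parameter = concentration_parameter,
    counts_per_sample = as.integer(counts_per_sample),
    marker_added = marker_added, dry_mass = dry_mass,
    true_concentration = true_concentration, group = group, seed = seed
  ), class = "zone_scenario")
}

#' Generate a synthetic marker-spiked count table
#'
#' Each sample's taxon counts are a Dirichlet-multinomial draw around its
#' zone's composition. The number of exotic-marker particles counted is a
#' Poisson draw whose mean makes the spike-based concentration estimator
#' centred on `scenario$true_concentration`.
#'
#' @param scenario a [zone_scenario()].
#' @return A long-format count table data.frame with columns
#'   `depth_cm, group, taxon, count, marker_counted, marker_added,
#'   dry_mass_g`, one row per (sample, taxon); sample depths are
#'   1, 2, ... `n_samples` cm, shallowest first. The true zone id per
#'   sample is attached as attribute `"zone"`.
#' @export
gen_assemblage <- function(scenario) {
  stopifnot(inherits(scenario, "zone_scenario"))
  n <- scenario$n_samples
  comp <- scenario$zone_compositions
  k <- ncol(comp)
  taxa <- colnames(comp) %||% sprintf("taxon_%02d", seq_len(k))
  zone_of <- findInterval(seq_len(n) - 1L, scenario$boundaries) + 1L
  with_seed(scenario$seed, {
    rows <- vector("list", n)
    # expected markers counted per `counts_per_sample` individuals
    m_mean <- scenario$counts_per_sample * scenario$marker_added /
      (scenario$dry_mass * scenario$true_concentration)
    for (i in seq_len(n)) {
      base_p <- comp[zone_of[i], ]
      p <- if (is.finite(scenario$concentration_parameter)) {
        g <- stats::rgamma(k, shape = base_p * scenario$concentration_parameter)
        if (sum(g) == 0) base_p else g / sum(g)
      } else base_p
      cnt <- as.integer(stats::rmultinom(1, scenario$counts_per_sample, p))
      m <- max(1L, stats::rpois(1, m_mean))
      rows[[i]] <- data.frame(
        depth_cm = i, group = scenario$group, taxon = taxa, count = cnt,
        marker_counted = m, marker_added = scenario$marker_added,
        dry_mass_g = scenario$dry_mass
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "zone") <- zone_of
    out
  })
}

#' Describe a synthetic sea-ice and station-temperature climate
#'
#' Daily sea-ice concentration (SIC) follows a seasonal plateau-ramp cycle:
#' full winter cover, an open-water season, and cosine ramps whose
#' mid-threshold crossings define the melt and freeze onsets analytically.
#' The melt onset shifts earlier and the freeze onset later by the stated
#' days per decade. Station temperature follows a seasonal cosine plus a
#' linear warming trend plus AR(1) noise, with per-station offsets.
#'
#' @param years calendar years covered by the daily series.
#' @param sic_melt_doy,sic_freeze_doy melt/freeze onset day-of-year in the
#'   reference year `sic_ref_year` (threshold-crossing days of the
#'   noise-free cycle).
#' @param sic_trend length-2 numeric `c(melt_earlier, freeze_later)` in
#'   days per decade (both positive values lengthen the open season).
#' @param sic_ref_year year at which the reference onsets apply.
#' @param sic_high,sic_low plateau SIC values (%); their midpoint is the
#'   concentration at the nominal onset day, so the default 100/10 puts
#'   the analytic crossing exactly at the 55 % threshold.
#' @param sic_ramp_days full length of each cosine ramp, days.
#' @param sic_noise_sd additive Gaussian noise on daily SIC (%), clipped
#'   to `[0, 100]`.
#' @param temp_mean annual-mean temperature of the blended station
#'   climatology at the series start, degrees C.
#' @param temp_amplitude seasonal half-range, degrees C.
#' @param temp_peak_doy warmest day of year.
#' @param temp_trend warming trend, degrees C per decade.
#' @param ar1_coeff lag-1 autocorrelation of the daily noise, in `[0, 1)`.
#' @param noise_sd innovation standard deviation of the AR(1) noise,
#'   degrees C.
#' @param n_stations number of stations.
#' @param station_offsets per-station additive offsets, degrees C.
#' @param tmax_offset daily maximum minus daily mean, degrees C.
#' @param seed integer seed.
#' @return An object of class `climate_scenario`.
#' @export
climate_scenario <- function(years = 1960:2015,
                             sic_melt_doy = 170, sic_freeze_doy = 270,
                             sic_trend = c(20, 19),
                             sic_ref_year = 1992.5,
                             sic_high = 100, sic_low = 10,
                             sic_ramp_days = 60,
                             sic_noise_sd = 2,
                             temp_mean = -5.6, temp_amplitude = 11,
                             temp_peak_doy = 201,
                             temp_trend = 0.7,
                             ar1_coeff = 0.8, noise_sd = 2,
                             n_stations = 4,
                             station_offsets = NULL,
                             tmax_offset = 3.5,
                             seed = 1L) {
  if (length(years) < 1L) stop("year range must be non-empty")
  if (ar1_coeff < 0 || ar1_coeff >= 1) stop("ar1_coeff must be in [0, 1)")
  if (length(sic_trend) == 1L) sic_trend <- rep(sic_trend, 2)
  if (is.null(station_offsets)) {
    station_offsets <- if (n_stations == 1L) 0 else
      seq(-0.35, 0.35, length.out = n_stations)
  }
  if (length(station_offsets) != n_stations)
    stop("station_offsets must have length n_stations")
  structure(list(
    years = years, sic_melt_doy = sic_melt_doy,
    sic_freeze_doy = sic_freeze_doy, sic_trend = sic_trend,
    sic_ref_year = sic_ref_year, sic_high = sic_high, sic_low = sic_low,
    sic_ramp_days = sic_ramp_days, sic_noise_sd = sic_noise_sd,
    temp_mean = temp_mean, temp_amplitude = temp_amplitude,
    temp_peak_doy = temp_peak_doy, temp_trend = temp_trend,
    ar1_coeff = ar1_coeff, noise_sd = noise_sd,
    n_stations = n_stations, station_offsets = station_offsets,
    tmax_offset = tmax_offset, seed = seed
  ), class = "climate_scenario")
}

# Noise-free SIC cycle value for day-of-year d in year y (vectorised in d).
sic_cycle_value <- function(scenario, year, doy) {
  melt <- scenario$sic_melt_doy -
    scenario$sic_trend[1] / 10 * (year - scenario$sic_ref_year)
  freeze <- scenario$sic_freeze_doy +
    scenario$sic_trend[2] / 10 * (year - scenario$sic_ref_year)
  R <- scenario$sic_ramp_days
  hi <- scenario$sic_high; lo <- scenario$sic_low
  mid <- (hi + lo) / 2; half <- (hi - lo) / 2
  v <- rep(hi, length(doy))
  in_melt <- doy >= melt - R / 2 & doy < melt + R / 2
  v[in_melt] <- mid + half * cos(pi * (doy[in_melt] - (melt - R / 2)) / R)
  open <- doy >= melt + R / 2 & doy < freeze - R / 2
  v[open] <- lo
  in_frz <- doy >= freeze - R / 2 & doy < freeze + R / 2
  v[in_frz] <- mid - half * cos(pi * (doy[in_frz] - (freeze - R / 2)) / R)
  v
}

#' Generate synthetic daily sea-ice and station-temperature series
#'
#' @param scenario a [climate_scenario()].
#' @return A list with elements:
#'   \describe{
#'     \item{sic}{data.frame `date, sic_percent` (daily regional-mean SIC).}
#'     \item{stations}{data.frame `date, station, tmean_c, tmax_c`.}
#'     \item{truth}{list with the imposed melt/freeze onsets per year
#'       (`melt_doy`, `freeze_doy`, noise-free), the imposed trends, and
#'       the noise-free annual mean temperature per year.}
#'   }
#' @export
gen_daily_climate <- function(scenario) {
  stopifnot(inherits(scenario, "climate_scenario"))
  years <- scenario$years
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  yr <- year_of(dates); doy <- doy_of(dates)
  with_seed(scenario$seed, {
    sic_clean <- numeric(length(dates))
    for (y in unique(yr)) {
      sel <- yr == y
      sic_clean[sel] <- sic_cycle_value(scenario, y, doy[sel])
    }
    sic <- sic_clean
    if (scenario$sic_noise_sd > 0) {
      sic <- sic + stats::rnorm(length(sic), 0, scenario$sic_noise_sd)
    }
    sic <- pmin(100, pmax(0, sic))
    y0 <- min(years)
    seasonal <- scenario$temp_mean + scenario$temp_trend / 10 * (yr - y0) +
      scenario$temp_amplitude *
        cos(2 * pi * (doy - scenario$temp_peak_doy) / 365.25)
    stations <- vector("list", scenario$n_stations)
    for (s in seq_len(scenario$n_stations)) {
      noise <- if (scenario$noise_sd > 0) {
        as.numeric(stats::arima.sim(
          list(ar = if (scenario$ar1_coeff > 0) scenario$ar1_coeff else NULL),
          n = length(dates), sd = scenario$noise_sd))
      } else numeric(length(dates))
      tmean <- seasonal + scenario$station_offsets[s] + noise
      stations[[s]] <- data.frame(
        date = dates, station = sprintf("station_%02d", s),
        tmean_c = tmean, tmax_c = tmean + scenario$tmax_offset)
    }
    truth_years <- sort(unique(yr))
    list(
      sic = data.frame(date = dates, sic_percent = sic),
      stations = do.call(rbind, stations),
      truth = list(
        melt_doy = scenario$sic_melt_doy -
          scenario$sic_trend[1] / 10 * (truth_years - scenario$sic_ref_year),
        freeze_doy = scenario$sic_freeze_doy +
          scenario$sic_trend[2] / 10 * (truth_years - scenario$sic_ref_year),
        years = truth_years,
        melt_trend_d_per_decade = -scenario$sic_trend[1],
        freeze_trend_d_per_decade = scenario$sic_trend[2],
        temp_trend_c_per_decade = scenario$temp_trend,
        annual_mean_clean = vapply(truth_years, function(y) {
          sel <- yr == y
          mean(scenario$temp_mean + scenario$temp_trend / 10 * (y - y0) +
                 scenario$temp_amplitude *
                   cos(2 * pi * (doy[sel] - scenario$temp_peak_doy) / 365.25))
        }, numeric(1))
      )
    )
  })
}
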