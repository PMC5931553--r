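# Sea-ice phenology, station stacking, melting season, decadal trends.

daily_series <- function(year, values) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  data.frame(date = dates, sic_percent = rep_len(values, length(dates)))
}

test_that("regional mean SIC averages ocean cells and respects coverage", {
  dates <- rep(as.Date("2000-06-01") + 0:1, each = 4)
  grid <- data.frame(date = dates, cell_id = rep(1:4, 2),
                     sic_percent = c(rep(80, 4), 100, 100, 0, 0))
  out <- regional_mean_sic(grid)
  expect_equal(out$sic_percent, c(80, 50))
  # half the cells missing on day 2 with min_valid_frac 0.75: masked
  grid$sic_percent[c(7, 8)] <- NA
  out2 <- regional_mean_sic(grid, min_valid_frac = 0.75)
  expect_true(is.na(out2$sic_percent[2]))
  # region restricted by cell ids
  out3 <- regional_mean_sic(grid, region = 1:2)
  expect_equal(out3$sic_percent, c(80, 100))
  cells <- data.frame(cell_id = 1:4, lat = c(77, 77, 78, 78),
                      lon = c(20, 21, 20, 21))
  out4 <- regional_mean_sic(grid, cells = cells,
                            region = list(lat = c(76.5, 77.5),
                                          lon = c(19, 22)))
  expect_equal(out4$sic_percent[1], 80)
  expect_error(regional_mean_sic(grid, region = 99), "no grid cells")
})

test_that("phenology counts for constant series hit the degenerate limits", {
  full <- ice_phenology(daily_series(2001, 100), 2001)
  expect_equal(full$ice_free_days, 0)
  expect_equal(full$high_ice_days, 365)
  expect_true(is.na(full$melt_onset_doy))
  open <- ice_phenology(daily_series(2001, 0), 2001)
  expect_equal(open$ice_free_days, 365)
  expect_equal(open$melt_onset_doy, 1)
  leap <- ice_phenology(daily_series(2000, 0), 2000)
  expect_equal(leap$ice_free_days, 366)
})

test_that("phenology matches the analytic crossing window of the generator", {
  sc <- climate_scenario(years = 1990:1999, sic_noise_sd = 0,
                         sic_trend = c(10, 10))
  clim <- gen_daily_climate(sc)
  for (y in c(1990, 1995, 1999)) {
    truth_i <- which(clim$truth$years == y)
    expect_window <- clim$truth$freeze_doy[truth_i] -
      clim$truth$melt_doy[truth_i]
    ph <- ice_phenology(clim$sic, y)
    expect_lt(abs(ph$ice_free_days - expect_window), 1.5)
    expect_lt(abs(ph$melt_onset_doy - clim$truth$melt_doy[truth_i]), 1.5)
    expect_lt(abs(ph$freeze_onset_doy - clim$truth$freeze_doy[truth_i]), 1.5)
  }
})

test_that("phenology bookkeeping: counts partition the year, order-invariant", {
  set.seed(6)
  s <- daily_series(2002, NA)
  s$sic_percent <- runif(nrow(s), 0, 100)
  s$sic_percent[sample(nrow(s), 30)] <- NA
  ph <- ice_phenology(s, 2002)
  n_above <- sum(s$sic_percent >= 55, na.rm = TRUE)
  expect_equal(ph$ice_free_days + n_above + sum(is.na(s$sic_percent)), 365)
  expect_true(ph$low_coverage == (ph$n_valid < 300))
  shuffled <- s[sample(nrow(s)), ]
  expect_equal(ice_phenology(shuffled, 2002), ph)
})

test_that("period phenology averages qualifying years and excludes sparse ones", {
  s1 <- daily_series(2001, 0); s2 <- daily_series(2002, 0)
  s2$sic_percent[1:200] <- 100
  both <- rbind(s1, s2)
  pp <- period_phenology(both, 2001:2002)
  expect_equal(pp$mean$ice_free_days, (365 + 165) / 2)
  sparse <- s2[1:100, ]
  pp2 <- period_phenology(rbind(s1, sparse), 2001:2002)
  expect_equal(pp2$excluded_years, 2002)
  expect_equal(pp2$mean$ice_free_days, 365)
  expect_error(period_phenology(sparse, 2002), "no qualifying years")
})

test_that("imposed melt/freeze shifts are recovered in period means and trends", {
  sc <- climate_scenario(years = 1985:2014, sic_trend = c(10, 10),
                         sic_noise_sd = 0)
  clim <- gen_daily_climate(sc)
  early <- period_phenology(clim$sic, 1985:1994)$mean$ice_free_days
  late <- period_phenology(clim$sic, 2005:2014)$mean$ice_free_days
  # 20 d/decade total widening over 2 decades between window centres
  expect_lt(abs((late - early) - 40), 2)
  tab <- period_phenology(clim$sic, 1985:2014)$table
  tr_melt <- suppressWarnings(linear_trend(tab$year, tab$melt_onset_doy))
  tr_freeze <- suppressWarnings(linear_trend(tab$year, tab$freeze_onset_doy))
  expect_lt(abs(tr_melt$slope_per_decade + 10), 2 * tr_melt$slope_se + 0.5)
  expect_lt(abs(tr_freeze$slope_per_decade - 10), 2 * tr_freeze$slope_se + 0.5)
})

test_that("station stacking averages per day and enforces min_stations", {
  dates <- as.Date("2000-01-01") + 0:2
  st <- rbind(
    data.frame(date = dates, station = "a", tmean_c = c(1, 2, 3),
               tmax_c = c(3, 4, 5)),
    data.frame(date = dates, station = "b", tmean_c = c(3, NA, 5),
               tmax_c = c(5, NA, 7)))
  out <- stack_stations(st)
  expect_equal(out$tmean_c, c(2, NA, 4))
  expect_equal(out$tmax_c, c(4, NA, 6))
  # identical stations: output equals input
  st2 <- rbind(
    data.frame(date = dates, station = "a", tmean_c = 1:3, tmax_c = 4:6),
    data.frame(date = dates, station = "b", tmean_c = 1:3, tmax_c = 4:6))
  out2 <- stack_stations(st2)
  expect_equal(out2$tmean_c, c(1, 2, 3))
  expect_error(stack_stations(st[0, ]), "empty")
})

test_that("dropping one of several identical-climatology stations barely moves annual means", {
  sc <- climate_scenario(years = 2000:2003, n_stations = 5,
                         station_offsets = rep(0, 5), noise_sd = 1,
                         ar1_coeff = 0, temp_trend = 0, sic_noise_sd = 0,
                         seed = 12)
  clim <- gen_daily_climate(sc)
  all5 <- stack_stations(clim$stations)
  four <- stack_stations(
    clim$stations[clim$stations$station != "station_05", ])
  yr <- format(all5$date, "%Y")
  d <- abs(tapply(all5$tmean_c, yr, mean) - tapply(four$tmean_c, yr, mean))
  expect_lt(max(d), 1 / sqrt(20))
})

test_that("site offset shifts every day and the annual mean by the offset", {
  dates <- as.Date("2000-01-01") + 0:364
  blended <- data.frame(date = dates, tmean_c = rnorm(365, 3),
                        tmax_c = rnorm(365, 6))
  site <- site_temperature(blended, offset = -1.6)
  expect_equal(site$tmean_c, blended$tmean_c - 1.6)
  expect_equal(mean(site$tmean_c), mean(blended$tmean_c) - 1.6)
  expect_equal(attr(site, "offset_c"), -1.6)
  ident <- site_temperature(blended, offset = 0)
  expect_equal(ident$tmean_c, blended$tmean_c)
  expect_equal(site_temperature(
    data.frame(date = dates[1], tmean_c = 3, tmax_c = 3.0),
    offset = -1.6)$tmax_c, 1.4)
})

test_that("melting season counts days above freezing, with analytic sinusoid check", {
  dates <- seq(as.Date("2003-01-01"), as.Date("2003-12-31"), by = "day")
  cold <- data.frame(date = dates, tmax_c = -5)
  expect_equal(melting_season_length(cold)$melt_days, 0)
  warm <- data.frame(date = dates, tmax_c = 5)
  expect_equal(melting_season_length(warm)$melt_days, 365)
  doy <- as.integer(format(dates, "%j"))
  amp <- 8; mean_t <- -3; peak <- 200
  sinus <- data.frame(date = dates,
                      tmax_c = mean_t + amp * cos(2 * pi * (doy - peak) / 365.25))
  # analytic above-zero window: |doy - peak| < (365.25/2pi) acos(-mean/amp)
  half <- 365.25 / (2 * pi) * acos(-mean_t / amp)
  expect_lt(abs(melting_season_length(sinus)$melt_days - 2 * half), 1.5)
})

test_that("linear trend matches the closed-form OLS slope and calibrates its test", {
  years <- 1960:2015
  vals <- 2 * years + 3
  tr <- suppressWarnings(linear_trend(years, vals))
  expect_equal(tr$slope_per_decade, 20)
  expect_equal(tr$r_squared, 1)
  set.seed(13)
  for (i in 1:5) {
    y <- rnorm(30)
    x <- 1981:2010
    tr2 <- linear_trend(x, y)
    beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(tr2$slope_per_decade, 10 * beta, tolerance = 1e-10)
  }
  expect_error(linear_trend(2001:2005, rnorm(5)), "at least 10")
  expect_error(linear_trend(1991:2010, rep(1, 20)), "constant")
})

test_that("trend type-I error sits near the nominal 5% on white noise", {
  set.seed(14)
  p <- replicate(400, linear_trend(1960:2015, rnorm(56))$p_value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.035)
})
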