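# Synthetic-data generators: ground-truth consistency and reproducibility.

test_that("gen_core slices at 1 cm, halves excess after one half-life, and is reproducible", {
  core <- gen_core(constant_rate_scenario())
  p <- core$profile
  expect_true(all(p$depth_bottom_cm - p$depth_top_cm == 1))
  # depth where the true age below surface is exactly one half-life
  v <- 0.04 / 0.2                          # cm/yr
  z_half <- 22.3 * v
  surface_excess <- core$true_excess(0)
  expect_equal(core$true_excess(z_half), surface_excess / 2, tolerance = 1e-9)
  # slice-averaged activities decay exactly with the age offset between
  # slice tops (one slice = 5 yr here): C_k / C_1 = exp(-lambda * 5(k-1))
  excess <- p$pb210_bq_kg - p$ra226_bq_kg
  expect_equal(excess[5] / excess[1], exp(-pb210_lambda * 20),
               tolerance = 1e-9)
  core2 <- gen_core(constant_rate_scenario())
  expect_identical(core$profile, core2$profile)
  core3 <- gen_core(constant_rate_scenario(noise_cv = 0.1, seed = 5))
  core4 <- gen_core(constant_rate_scenario(noise_cv = 0.1, seed = 6))
  expect_false(identical(core3$profile, core4$profile))
})

test_that("gen_core true ages match the closed-form epoch-integration oracle", {
  sc <- two_epoch_scenario()
  core <- gen_core(sc)
  z <- seq(0, nrow(core$profile), by = 0.25)
  expect_equal(core$true_age(z),
               oracle_age_at_depth(sc$epochs, sc$bulk_density, z),
               tolerance = 1e-9)
})

test_that("gen_core places the 137Cs maximum in the slice deposited in the pulse year", {
  core <- gen_core(sediment_scenario(noise_cv = 0))   # paper-mimicking default
  p <- core$profile
  k <- which.max(p$cs137_bq_kg)
  mid_ages <- core$true_age((p$depth_top_cm + p$depth_bottom_cm) / 2)
  expect_equal(k, which.min(abs(mid_ages - 1963)))
})

test_that("gen_core rejects degenerate scenarios", {
  expect_error(gen_core(sediment_scenario(
    epochs = data.frame(start_year = 2014, end_year = 2015, mar = 0.04))),
    "fewer than 2")
  expect_error(sediment_scenario(
    epochs = data.frame(start_year = 1900, end_year = 2015, mar = -1)),
    "rates")
  expect_error(sediment_scenario(noise_cv = -0.1), "noise_cv")
})

test_that("gen_assemblage totals, homogeneous limit and zone recovery behave", {
  sc <- two_zone_scenario(counts = 300)
  tab <- gen_assemblage(sc)
  totals <- tapply(tab$count, tab$depth_cm, sum)
  expect_true(all(totals == 300))
  # dispersion -> Inf, no boundaries: identical expected proportions
  sc0 <- zone_scenario(n_samples = 6, boundaries = integer(0),
                       zone_compositions = matrix(c(0.5, 0.3, 0.2), 1),
                       concentration_parameter = Inf,
                       counts_per_sample = 1e5, seed = 2)
  tab0 <- gen_assemblage(sc0)
  prop <- relative_abundance(tab0, min_total = 1)$proportions
  expect_lt(max(abs(sweep(prop, 2, colMeans(prop)))), 0.01)
  expect_error(zone_scenario(n_samples = 10, boundaries = c(5, 3),
                             zone_compositions = random_proportions(3, 4)),
               "increasing")
  expect_error(zone_scenario(n_samples = 10, boundaries = 5,
                             zone_compositions = random_proportions(3, 4)),
               "composition")
})

test_that("gen_assemblage proportions converge to zone compositions as counts grow", {
  comp <- rbind(c(0.6, 0.25, 0.1, 0.05))
  sc <- zone_scenario(n_samples = 8, boundaries = integer(0),
                      zone_compositions = comp,
                      concentration_parameter = Inf,
                      counts_per_sample = 1e5, seed = 3)
  prop <- relative_abundance(gen_assemblage(sc), min_total = 1)$proportions
  expect_lt(max(abs(sweep(prop, 2, comp[1, ]))), 0.02)
})

test_that("gen_daily_climate: stationary phenology, deterministic limit, trend truth", {
  sc <- climate_scenario(years = 2000:2004, sic_trend = c(0, 0),
                         sic_noise_sd = 0, noise_sd = 0, ar1_coeff = 0,
                         temp_trend = 0)
  clim <- gen_daily_climate(sc)
  ph <- do.call(rbind, lapply(2000:2004, function(y)
    ice_phenology(clim$sic, y)))
  expect_true(all(ph$ice_free_days == ph$ice_free_days[1]))
  expect_true(all(ph$melt_onset_doy == ph$melt_onset_doy[1]))
  # ar1 = 0, noise 0: annual means equal the noise-free cycle means
  st <- clim$stations[clim$stations$station == "station_01", ]
  ann <- tapply(st$tmean_c, format(st$date, "%Y"), mean)
  expect_equal(as.numeric(ann),
               clim$truth$annual_mean_clean + sc$station_offsets[1],
               tolerance = 1e-9)
  # reproducibility
  clim2 <- gen_daily_climate(sc)
  expect_identical(clim$sic, clim2$sic)
  expect_error(climate_scenario(years = integer(0)), "non-empty")
  expect_error(climate_scenario(ar1_coeff = 1), "ar1")
})

test_that("imposed warming trend is recovered within its 95% CI", {
  sc <- climate_scenario(years = 1960:2015, temp_trend = 0.7,
                         noise_sd = 0.5, ar1_coeff = 0.3, sic_noise_sd = 0,
                         seed = 11)
  clim <- gen_daily_climate(sc)
  blended <- stack_stations(clim$stations)
  yr <- as.integer(format(blended$date, "%Y"))
  ann <- data.frame(year = sort(unique(yr)),
                    value = as.numeric(tapply(blended$tmean_c, yr, mean)))
  tr <- linear_trend(ann)
  expect_lt(abs(tr$slope_per_decade - 0.7), 1.96 * tr$slope_se)
})
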