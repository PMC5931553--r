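# Excess 210Pb arithmetic, CRS ages, 137Cs peak, bomb 14C calibration.

flat_profile <- function(n = 5, excess = 100, supported = 50, mass = 0.2,
                         sd_pb = 0, sd_ra = 0) {
  data.frame(
    depth_top_cm = 0:(n - 1), depth_bottom_cm = 1:n, dry_mass_g = mass,
    pb210_bq_kg = excess + supported, pb210_sd = sd_pb,
    ra226_bq_kg = supported, ra226_sd = sd_ra,
    cs137_bq_kg = 0, cs137_sd = 0)
}

test_that("excess activity subtracts supported level with quadrature sigmas", {
  p <- flat_profile(n = 3, excess = 100, supported = 50, sd_pb = 4, sd_ra = 3)
  ex <- excess_pb210(p, tail_correction = FALSE)
  expect_equal(ex$data$excess_bq_kg, rep(100, 3))
  expect_equal(ex$data$excess_sd, rep(5, 3))      # sqrt(16 + 9)
})

test_that("constant excess and equal masses give a linearly declining inventory", {
  n <- 6
  ex <- excess_pb210(flat_profile(n = n), tail_correction = FALSE)
  inv <- ex$data$inventory_below_top
  expect_equal(inv / inv[1], (n:1) / n, tolerance = 1e-12)
  expect_true(all(diff(inv) < 0))
  expect_equal(inv[1], ex$total_inventory)
})

test_that("negative excess is clamped with a warning and flagged", {
  p <- flat_profile(n = 4)
  p$pb210_bq_kg[3] <- 30                            # below supported 50
  expect_warning(ex <- excess_pb210(p), "clamped")
  expect_equal(ex$data$excess_bq_kg[3], 0)
  expect_true(ex$data$clamped[3])
  expect_true(all(ex$data$inventory_below_top >= 0))
})

test_that("unmeasured slices are interpolated on the mass scale", {
  core <- gen_core(constant_rate_scenario())
  p <- core$profile
  full <- excess_pb210(p)
  gappy <- p
  unmeasured <- seq(2, nrow(p) - 1, by = 2)
  gappy$pb210_bq_kg[unmeasured] <- NA
  gappy$ra226_bq_kg[unmeasured] <- NA
  ex <- excess_pb210(gappy)
  expect_true(all(ex$data$interpolated[unmeasured]))
  expect_equal(ex$data$excess_bq_kg, full$data$excess_bq_kg,
               tolerance = 0.02)
  expect_error(excess_pb210(p[1:2, ]), "3 slices")
})

test_that("zero-noise generator inventories match the analytic flux integral", {
  sc <- two_epoch_scenario()
  core <- gen_core(sc)
  ex <- excess_pb210(core$profile)
  lambda <- pb210_lambda
  t_top <- 2015 - core$true_age(ex$data$depth_top_cm)
  analytic <- sc$pb_flux / lambda * exp(-lambda * t_top)
  expect_equal(ex$data$inventory_below_top, analytic, tolerance = 0.01)
})

test_that("CRS dates the half-inventory horizon to exactly one half-life", {
  # profile engineered so the interpolated inventory halves at 2.8 cm
  ex <- excess_pb210(flat_profile(n = 5), tail_correction = FALSE)
  # total = 5 units; find the depth where log-interpolated A = A0/2
  a0 <- ex$total_inventory
  age <- crs_age_at(ex, 2.5, collection_year = 2015)
  # A(midpoint of slice 3) = sqrt(3*2)/5 of A0, not the half yet; solve:
  target <- uniroot(function(z)
    crs_age_at(ex, z, 2015) - (2015 - 22.3), c(2, 3.5))$root
  expect_equal(crs_age_at(ex, target, 2015), 2015 - 22.3, tolerance = 1e-6)
  # and the slice-table route: A(mid slice 3) known in closed form
  crs <- crs_ages(ex, collection_year = 2015, n_monte_carlo = 0)
  expect_equal(2015 - crs$age[3],
               log(5 / sqrt(6)) / pb210_lambda, tolerance = 1e-9)
})

test_that("surface dates to zero age and A0/2 to one half-life through the equation", {
  ex <- excess_pb210(flat_profile(n = 5), tail_correction = FALSE)
  expect_equal(crs_age_at(ex, 0, 2015), 2015, tolerance = 1e-9)
})

test_that("CRS is invariant to uniform rescaling of all activities", {
  core <- gen_core(constant_rate_scenario())
  p <- core$profile
  p2 <- p
  p2$pb210_bq_kg <- p$ra226_bq_kg + 3 * (p$pb210_bq_kg - p$ra226_bq_kg)
  a1 <- crs_ages(excess_pb210(p), 2015, n_monte_carlo = 0)
  a2 <- crs_ages(excess_pb210(p2), 2015, n_monte_carlo = 0)
  expect_equal(a1$age, a2$age, tolerance = 1e-9)
})

test_that("zero-noise CRS recovers true ages to within a year over the last century", {
  for (make in list(constant_rate_scenario, two_epoch_scenario)) {
    core <- gen_core(make())
    crs <- crs_ages(excess_pb210(core$profile), 2015, n_monte_carlo = 0)
    err <- abs(crs$age - core$true_age(crs$depth))
    expect_lt(max(err[crs$age >= 1915]), 1)
  }
})

test_that("Monte-Carlo age sigma is zero without measurement error and scales with it", {
  core <- gen_core(constant_rate_scenario())
  ex0 <- excess_pb210(core$profile)
  crs0 <- crs_ages(ex0, 2015, n_monte_carlo = 100, seed = 4)
  expect_equal(max(crs0$age_sigma), 0)
  noisy <- function(cv, seed) {
    c1 <- gen_core(constant_rate_scenario(noise_cv = cv, seed = 3))
    crs_ages(excess_pb210(c1$profile), 2015, n_monte_carlo = 300, seed = seed)
  }
  s_small <- noisy(0.005, 5)
  s_big <- noisy(0.02, 5)
  expect_gt(median(s_big$age_sigma) / median(s_small$age_sigma), 2)
})

test_that("CRS parameter recovery holds over random noisy scenarios", {
  set.seed(42)
  errs <- replicate(20, {
    mar_old <- runif(1, 0.01, 0.03)
    sc <- sediment_scenario(
      epochs = data.frame(start_year = c(1880, 1970),
                          end_year = c(1970, 2015),
                          mar = c(mar_old, runif(1, 0.03, 0.08))),
      pb_flux = runif(1, 0.003, 0.01),
      noise_cv = 0.05, seed = sample.int(1e6, 1))
    core <- gen_core(sc)
    crs <- crs_ages(excess_pb210(core$profile), 2015, n_monte_carlo = 0)
    true <- core$true_age(crs$depth)
    keep <- true >= 1950
    median(abs(crs$age - true)[keep])
  })
  expect_lt(median(errs), 5)
})

test_that("137Cs peak detection returns the shallower maximum, window and flags", {
  core <- gen_core(sediment_scenario(noise_cv = 0))
  peak <- detect_cs137_peak(core$profile)
  expect_equal(core$true_age(peak$depth), 1963, tolerance = 3)
  expect_true(peak$interior_peak)
  expect_equal(peak$age, 1962.5)
  expect_true(peak$window[1] < peak$depth && peak$window[2] > peak$depth)
  # monotone-decreasing profile: boundary maximum, flagged
  p <- flat_profile(n = 5)
  p$cs137_bq_kg <- c(50, 40, 30, 20, 10)
  m <- detect_cs137_peak(p)
  expect_equal(m$depth, 0.5)
  expect_false(m$interior_peak)
  # ties break toward the shallower slice
  p$cs137_bq_kg <- c(10, 50, 50, 20, 10)
  expect_equal(detect_cs137_peak(p)$depth, 1.5)
  p$cs137_bq_kg <- 0
  expect_error(detect_cs137_peak(p), "no bomb signal")
})

test_that("bomb 14C calibration reports rising- and falling-limb windows", {
  # symmetric triangular curve peaking in 1964
  years <- 1955:1980
  curve <- data.frame(year_ad = years,
                      f14c_percent = 200 - 6 * abs(years - 1964),
                      f14c_sd = 0.5)
  sample <- list(f14c_percent = 152, f14c_sigma = 0.5)
  iv <- calibrate_bomb_14c(sample, curve)
  expect_equal(nrow(iv), 2)
  # brute-force oracle over the year grid
  tol <- 1 * sqrt(0.5^2 + 0.5^2)
  hit <- years[abs(152 - curve$f14c_percent) <= tol]
  expect_equal(iv$start_year[1], min(hit))
  expect_equal(iv$end_year[2], max(hit))
  # symmetric about the peak
  expect_equal(1964 - iv$end_year[1], iv$start_year[2] - 1964)
  # strictly monotone curve, sample exactly on it, tiny sigma: one interval
  mono <- data.frame(year_ad = 1950:1970,
                     f14c_percent = 100 + 2 * (1950:1970 - 1950),
                     f14c_sd = 1e-9)
  iv2 <- calibrate_bomb_14c(list(f14c_percent = 120, f14c_sigma = 1e-9), mono)
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$start_year, 1960)
  expect_equal(iv2$end_year, 1960)
  expect_error(calibrate_bomb_14c(list(f14c_percent = 90, f14c_sigma = 1),
                                  curve), "post-bomb")
  expect_error(calibrate_bomb_14c(list(f14c_percent = 500, f14c_sigma = 1),
                                  curve), "envelope")
})
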