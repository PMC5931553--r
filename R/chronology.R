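# Radiometric chronology: unsupported 210Pb profile and inventories,
# constant-rate-of-supply (CRS) ages, 137Cs bomb-peak detection, and
# post-bomb radiocarbon calibration.

validate_isotope_profile <- function(profile) {
  stopifnot_cols(profile,
                 c("depth_top_cm", "depth_bottom_cm", "dry_mass_g",
                   "pb210_bq_kg", "pb210_sd", "ra226_bq_kg", "ra226_sd"),
                 "isotope profile")
  if (is.unsorted(profile$depth_top_cm, strictly = TRUE))
    stop("slices must be sorted shallow to deep")
  if (any(profile$depth_bottom_cm <= profile$depth_top_cm))
    stop("each slice needs depth_bottom_cm > depth_top_cm")
  if (any(profile$depth_top_cm[-1] <
          profile$depth_bottom_cm[-nrow(profile)] - 1e-9))
    stop("depth intervals overlap")
  if (any(profile$dry_mass_g <= 0, na.rm = TRUE) ||
      anyNA(profile$dry_mass_g))
    stop("dry masses must all be present and positive")
  invisible(profile)
}

#' Unsupported 210Pb profile and inventories
#'
#' Computes per-slice unsupported (excess) 210Pb as total 210Pb minus the
#' per-slice 226Ra-supported level, with sigmas propagated in quadrature,
#' then integrates the excess inventory from each depth to the core
#' bottom on a mass-depth scale. Negative excess values are clamped to
#' zero (flagged and warned). Slices with unmeasured 210Pb are filled by
#' linear interpolation of excess activity on cumulative dry mass, so a
#' ~5 cm measurement resolution still yields a full inventory profile.
#' The inventory below the deepest slice is estimated by exponential
#' extrapolation of the deepest three positive excess activities against
#' cumulative mass; CRS ages are sensitive to this missing deep tail.
#'
#' @param profile isotope profile data.frame (see [gen_core()] for the
#'   column layout); 210Pb and 226Ra must be present for at least 3 slices.
#' @param core_area_cm2 core cross-sectional area. It cancels from CRS
#'   ages provided mass-depth units are consistent; inventories are
#'   carried per cm^2.
#' @param tail_correction logical; estimate inventory below the deepest
#'   slice (default `TRUE`).
#' @return An object of class `excess_pb` with a `data` data.frame
#'   (`depth_top_cm, depth_bottom_cm, depth_mid_cm, excess_bq_kg,
#'   excess_sd, clamped, interpolated, mass_depth_g_cm2,
#'   inventory_below_top, inventory_below_mid` — inventories in Bq cm^-2,
#'   `mass_depth_g_cm2` the cumulative dry mass above the slice base),
#'   plus `total_inventory`, `tail_inventory` and `core_area_cm2`.
#' @export
excess_pb210 <- function(profile, core_area_cm2 = 1, tail_correction = TRUE) {
  validate_isotope_profile(profile)
  measured <- !is.na(profile$pb210_bq_kg) & !is.na(profile$ra226_bq_kg)
  if (sum(measured) < 3L)
    stop("need total 210Pb and 226Ra on at least 3 slices")
  n <- nrow(profile)
  excess <- profile$pb210_bq_kg - profile$ra226_bq_kg
  excess_sd <- sqrt(ifelse(is.na(profile$pb210_sd), 0, profile$pb210_sd)^2 +
                    ifelse(is.na(profile$ra226_sd), 0, profile$ra226_sd)^2)
  clamped <- !is.na(excess) & excess < 0
  if (any(clamped)) {
    warning(sprintf("%d slice(s) had negative excess 210Pb; clamped to 0",
                    sum(clamped)))
    excess[clamped] <- 0
  }
  mu <- profile$dry_mass_g / core_area_cm2        # g cm^-2 per slice
  mass_bottom <- cumsum(mu)                       # above slice base
  mass_mid <- mass_bottom - mu / 2
  interpolated <- !measured
  if (any(interpolated)) {
    ok <- which(measured)
    excess[interpolated] <- stats::approx(mass_mid[ok], excess[ok],
                                          xout = mass_mid[interpolated],
                                          rule = 2)$y
    excess_sd[interpolated] <- stats::approx(mass_mid[ok], excess_sd[ok],
                                             xout = mass_mid[interpolated],
                                             rule = 2)$y
  }
  slice_inv <- excess / 1000 * mu                 # Bq cm^-2 per slice
  tail_inv <- 0
  if (tail_correction) {
    pos <- which(excess > 0)
    deep <- utils::tail(pos, 3)
    if (length(deep) == 3L && excess[deep[3]] > 0) {
      fit <- stats::lm(log(excess[deep]) ~ mass_mid[deep])
      beta <- -unname(stats::coef(fit)[2])
      if (is.finite(beta) && beta > 0) {
        c_bottom <- exp(unname(stats::coef(fit)[1]) -
                        beta * mass_bottom[n])
        tail_inv <- c_bottom / 1000 / beta
      }
    }
  }
  inv_below_top <- rev(cumsum(rev(slice_inv))) + tail_inv
  # within a slice the inventory decays ~exponentially on the mass scale,
  # so the midpoint (half the slice mass) takes the geometric mean of the
  # boundary inventories; exact under constant accumulation
  inv_below_mid <- sqrt(inv_below_top * (inv_below_top - slice_inv))
  structure(list(
    data = data.frame(
      depth_top_cm = profile$depth_top_cm,
      depth_bottom_cm = profile$depth_bottom_cm,
      depth_mid_cm = (profile$depth_top_cm + profile$depth_bottom_cm) / 2,
      dry_mass_g = profile$dry_mass_g,
      excess_bq_kg = excess, excess_sd = excess_sd,
      clamped = clamped, interpolated = interpolated,
      mass_depth_g_cm2 = mass_bottom,
      inventory_below_top = inv_below_top,
      inventory_below_mid = inv_below_mid
    ),
    total_inventory = inv_below_top[1],
    tail_inventory = tail_inv,
    core_area_cm2 = core_area_cm2,
    tail_correction = tail_correction
  ), class = "excess_pb")
}

# Recompute inventories for a perturbed excess vector (Monte-Carlo path);
# mirrors the integration in excess_pb210().
inventories_from_excess <- function(excess, mu, tail_correction) {
  n <- length(excess)
  mass_bottom <- cumsum(mu)
  mass_mid <- mass_bottom - mu / 2
  slice_inv <- excess / 1000 * mu
  tail_inv <- 0
  if (tail_correction) {
    pos <- which(excess > 0)
    deep <- utils::tail(pos, 3)
    if (length(deep) == 3L) {
      fit <- stats::lm.fit(cbind(1, mass_mid[deep]), log(excess[deep]))
      beta <- -fit$coefficients[2]
      if (is.finite(beta) && beta > 0) {
        tail_inv <- exp(fit$coefficients[1] - beta * mass_bottom[n]) /
          1000 / beta
      }
    }
  }
  inv_top <- rev(cumsum(rev(slice_inv))) + tail_inv
  list(top = inv_top, mid = sqrt(inv_top * (inv_top - slice_inv)))
}

#' CRS (constant rate of supply) 210Pb ages
#'
#' Under constant supply of unsupported 210Pb, the age below the surface
#' at a horizon `z` is `t(z) = log(A0 / A(z)) / lambda`, where `A(z)` is
#' the excess inventory below `z` and `A0` the whole-core inventory.
#' Ages are evaluated at slice midpoints. Age uncertainty comes from
#' Monte-Carlo perturbation of the slice activities by their sigmas, with
#' inventories (including the deep-tail extrapolation) re-derived in every
#' replicate. Horizons retaining no more than `min_inventory_frac` of the
#' total inventory are flagged unreliable and excluded from the returned
#' tie points (the CRS age diverges as `A(z)` approaches 0).
#'
#' @param excess an [excess_pb210()] result.
#' @param collection_year calendar year of core collection.
#' @param decay_constant 210Pb decay constant, yr^-1.
#' @param n_monte_carlo number of Monte-Carlo replicates.
#' @param seed seed for the Monte-Carlo draws.
#' @param min_inventory_frac reliability cutoff on `A(z) / A0`.
#' @return data.frame of tie points (`depth, age, age_sigma, source,
#'   reliable`), ages in calendar years AD, `source = "crs"`; unreliable
#'   horizons carried with `reliable = FALSE`.
#' @export
crs_ages <- function(excess, collection_year,
                     decay_constant = pb210_lambda,
                     n_monte_carlo = 1000, seed = 1L,
                     min_inventory_frac = 0.05) {
  stopifnot(inherits(excess, "excess_pb"))
  d <- excess$data
  a0 <- excess$total_inventory
  if (!is.finite(a0) || a0 <= 0) stop("total excess 210Pb inventory must be > 0")
  a_mid <- d$inventory_below_mid
  if (all(a_mid <= 0))
    stop("excess inventory vanishes everywhere; CRS ages undefined")
  t_below <- ifelse(a_mid > 0, log(a0 / a_mid) / decay_constant, NA_real_)
  reliable <- a_mid > min_inventory_frac * a0
  age_sigma <- rep(0, nrow(d))
  mu <- d$dry_mass_g / excess$core_area_cm2
  if (any(d$excess_sd > 0) && n_monte_carlo > 0) {
    ages_mc <- with_seed(seed, {
      sims <- matrix(NA_real_, n_monte_carlo, nrow(d))
      for (r in seq_len(n_monte_carlo)) {
        pert <- pmax(0, stats::rnorm(nrow(d), d$excess_bq_kg, d$excess_sd))
        inv <- inventories_from_excess(pert, mu, excess$tail_correction)
        ok <- inv$mid > 0
        sims[r, ok] <- log(inv$top[1] / inv$mid[ok]) / decay_constant
      }
      sims
    })
    age_sigma <- apply(ages_mc, 2, stats::sd, na.rm = TRUE)
  }
  out <- data.frame(
    depth = d$depth_mid_cm,
    age = collection_year - t_below,
    age_sigma = age_sigma,
    source = "crs",
    reliable = reliable
  )
  structure(out[out$reliable, , drop = FALSE],
            excluded = out[!out$reliable, , drop = FALSE])
}

#' CRS age at an arbitrary horizon
#'
#' Interpolates the excess inventory at any depth inside the measured
#' profile — log-linearly on the cumulative-mass scale, matching the
#' near-exponential decay of inventory with mass depth — and applies the
#' CRS age equation. A horizon where the interpolated inventory vanishes
#' is an error (the age is undefined there; no extrapolation is done).
#'
#' @param excess an [excess_pb210()] result.
#' @param depth depths (cm), inside the measured profile.
#' @param collection_year calendar year of core collection.
#' @param decay_constant 210Pb decay constant, yr^-1.
#' @return calendar ages, years AD.
#' @export
crs_age_at <- function(excess, depth, collection_year,
                       decay_constant = pb210_lambda) {
  stopifnot(inherits(excess, "excess_pb"))
  d <- excess$data
  n <- nrow(d)
  knots_depth <- c(d$depth_top_cm, d$depth_bottom_cm[n])
  knots_mass <- c(0, d$mass_depth_g_cm2)
  knots_inv <- c(d$inventory_below_top,
                 excess$tail_inventory)
  if (any(depth < knots_depth[1] - 1e-9 | depth > knots_depth[n + 1] + 1e-9))
    stop("depth outside the measured profile")
  mass <- stats::approx(knots_depth, knots_mass, xout = depth)$y
  seg <- pmin(pmax(findInterval(mass, knots_mass), 1L), n)
  frac <- (mass - knots_mass[seg]) /
    (knots_mass[seg + 1L] - knots_mass[seg])
  lo <- knots_inv[seg]; hi <- knots_inv[seg + 1L]
  # log-linear between positive knots; linear into a zero-inventory base
  a <- ifelse(hi > 0, exp((1 - frac) * log(pmax(lo, 1e-300)) +
                            frac * log(pmax(hi, 1e-300))),
              lo * (1 - frac))
  if (any(a <= 0))
    stop("excess inventory vanishes at a requested horizon: ",
         "CRS age undefined there")
  collection_year - log(excess$total_inventory / a) / decay_constant
}

#' Locate the 137Cs bomb-fallout maximum
#'
#' The activity maximum of 137Cs is assumed to mark the 1962-1963 peak of
#' atmospheric nuclear-weapons testing, giving an independent tie point at
#' 1962.5 AD (sigma 1 yr). Ties are broken toward the shallower slice. The
#' contiguous depth window where activity stays at or above half the
#' maximum is reported alongside; a maximum sitting on the shallowest or
#' deepest measured slice is flagged as having no interior peak.
#'
#' @param profile isotope profile data.frame with `cs137_bq_kg` measured
#'   on at least 3 slices.
#' @return list with `depth` (slice midpoint, cm), `age` (1962.5),
#'   `age_sigma` (1), `source` (`"cs_peak"`), `window` (c(top, bottom)
#'   depth of the half-maximum run, cm), `interior_peak` (logical) and
#'   `peak_activity` (Bq/kg).
#' @export
detect_cs137_peak <- function(profile) {
  stopifnot_cols(profile, c("depth_top_cm", "depth_bottom_cm", "cs137_bq_kg"),
                 "isotope profile")
  ok <- which(!is.na(profile$cs137_bq_kg))
  if (length(ok) < 3L) stop("137Cs must be measured on at least 3 slices")
  act <- profile$cs137_bq_kg[ok]
  if (max(act) <= 0) stop("all 137Cs activities are zero: no bomb signal")
  imax <- ok[which.max(act)]                 # first maximum = shallower tie
  half <- profile$cs137_bq_kg[imax] / 2
  above <- !is.na(profile$cs137_bq_kg) & profile$cs137_bq_kg >= half
  lo <- imax; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- imax; while (hi < nrow(profile) && above[hi + 1L]) hi <- hi + 1L
  list(
    depth = (profile$depth_top_cm[imax] + profile$depth_bottom_cm[imax]) / 2,
    age = 1962.5, age_sigma = 1, source = "cs_peak",
    window = c(profile$depth_top_cm[lo], profile$depth_bottom_cm[hi]),
    interior_peak = imax != ok[1] && imax != ok[length(ok)],
    peak_activity = profile$cs137_bq_kg[imax]
  )
}

#' Calibrate a post-bomb radiocarbon measurement
#'
#' Matches a fraction-modern measurement (F14C, in percent of the modern
#' standard) against a post-bomb atmospheric calibration curve. Because
#' the bomb curve rises to its mid-1960s peak and then falls, a sample
#' below the peak generally intersects the curve twice; every maximal run
#' of years where the measurement lies within `k` combined standard
#' deviations of the curve is reported, so both the rising-limb and
#' falling-limb candidate windows appear.
#'
#' @param sample list with `f14c_percent` (> 100, i.e. post-bomb),
#'   `f14c_sigma`, and optionally `delta13c` and `depth`.
#' @param curve data.frame `year_ad, f14c_percent, f14c_sd` covering the
#'   post-1950 bomb era.
#' @param k envelope half-width in combined standard deviations.
#' @return data.frame of intervals `start_year, end_year`, earliest first.
#' @export
calibrate_bomb_14c <- function(sample, curve, k = 1) {
  stopifnot_cols(curve, c("year_ad", "f14c_percent", "f14c_sd"),
                 "calibration curve")
  if (!is_scalar_number(sample$f14c_percent) || sample$f14c_percent <= 100)
    stop("sample F14C must exceed 100% (post-bomb)")
  if (max(curve$year_ad) < 1955)
    stop("calibration curve does not cover the post-1950 bomb era")
  curve <- curve[order(curve$year_ad), ]
  tol <- k * sqrt(sample$f14c_sigma^2 + curve$f14c_sd^2)
  inside <- abs(sample$f14c_percent - curve$f14c_percent) <= tol
  if (!any(inside))
    stop("sample never intersects the calibration-curve envelope")
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  data.frame(
    start_year = curve$year_ad[starts[keep]],
    end_year = curve$year_ad[ends[keep]]
  )
}
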