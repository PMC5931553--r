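# Pipeline orchestration: configured, logged, reproducible runs of
# chronology -> proxies -> zonation -> sea ice -> temperature, writing
# CSV outputs plus a machine-readable JSON summary.

pipeline_defaults <- function() {
  list(
    collection_year = 2015,
    core_area_cm2 = 1,
    max_depth = NULL,
    n_monte_carlo = 1000,
    seed = 1L,
    threshold_free = 55,
    threshold_high = 75,
    min_sic_days = 300,
    site_offset = -1.6,
    site_offset_sigma = 0.5,
    min_stations = 2,
    exclude_stations = character(0),
    exclude_taxa = character(0),
    zonation_group = "diatom",
    zonation_max_splits = NULL,
    zonation_transform = "none",
    c14_sample = NULL,
    sic_periods = list(c(1988, 1997), c(2010, 2014)),
    outdir = "paleolimr_out"
  )
}

#' Build or load a pipeline configuration
#'
#' A configuration is a named list of input paths and stage parameters;
#' unspecified keys take the documented defaults (55 % / 75 % sea-ice
#' thresholds, -1.6 +/- 0.5 degrees C site offset, 1000 Monte-Carlo
#' replicates, seed 1). `pipeline_config()` builds one in code;
#' `load_config()` reads the same keys from a YAML file.
#'
#' @param ... configuration keys overriding the defaults. Input paths:
#'   `isotope_csv`, `counts_csv`, `loi_csv`, `sic_csv`, `stations_csv`,
#'   `c14_curve_csv` (with `c14_sample`, a list with `f14c_percent`,
#'   `f14c_sigma`, `depth`).
#' @param path YAML file path (for `load_config`).
#' @return a named configuration list with class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- utils::modifyList(pipeline_defaults(), list(...))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  fnv1a32(paste(deparse(config[order(names(config))]), collapse = ""))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_stage_info <- function(config, stage, outdir, extra = list()) {
  info <- c(list(stage = stage, config_hash = config_hash(config)), extra)
  jsonlite::write_json(info, file.path(outdir, paste0(stage, "_info.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

ensure_outdir <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  config$outdir
}

#' Run the chronology stage
#'
#' Reads the isotope table, derives the unsupported 210Pb profile and
#' inventories, computes CRS ages with Monte-Carlo uncertainties, locates
#' the 137Cs bomb peak, optionally calibrates a post-bomb radiocarbon
#' date (adopting the falling-limb window when two candidates exist, as
#' the 137Cs constraint requires), fits the quadratic age-depth model and
#' writes the excess-Pb table, tie points, age model and sedimentation
#' rates to the output directory.
#'
#' @param config a [pipeline_config()] with at least `isotope_csv` set.
#' @return (invisibly) a list with `model`, `excess`, `tie_points`,
#'   `cs_peak` and `rates`.
#' @export
run_chronology <- function(config) {
  outdir <- ensure_outdir(config)
  profile <- read_isotope_csv(config$isotope_csv)
  excess <- excess_pb210(profile, core_area_cm2 = config$core_area_cm2)
  if (any(excess$data$clamped))
    stage_log("chronology", "clamped %d negative excess slice(s)",
              sum(excess$data$clamped))
  crs <- crs_ages(excess, collection_year = config$collection_year,
                  n_monte_carlo = config$n_monte_carlo, seed = config$seed)
  excluded <- attr(crs, "excluded")
  if (!is.null(excluded) && nrow(excluded) > 0)
    stage_log("chronology", "excluded %d unreliable deep CRS horizon(s)",
              nrow(excluded))
  cs <- detect_cs137_peak(profile)
  stage_log("chronology", "137Cs maximum at %.1f cm (window %.1f-%.1f cm)",
            cs$depth, cs$window[1], cs$window[2])
  ties <- rbind(
    crs[, c("depth", "age", "age_sigma", "source")],
    data.frame(depth = cs$depth, age = cs$age, age_sigma = cs$age_sigma,
               source = cs$source))
  if (!is.null(config$c14_curve_csv) && !is.null(config$c14_sample)) {
    curve <- read_calibration_csv(config$c14_curve_csv)
    iv <- calibrate_bomb_14c(config$c14_sample, curve)
    chosen <- iv[nrow(iv), ]    # falling limb: consistent with the Cs peak
    stage_log("chronology", "14C windows: %s; adopting %d-%d",
              paste(sprintf("%d-%d", iv$start_year, iv$end_year),
                    collapse = ", "),
              chosen$start_year, chosen$end_year)
    ties <- rbind(ties, data.frame(
      depth = config$c14_sample$depth,
      age = (chosen$start_year + chosen$end_year) / 2,
      age_sigma = max(1, (chosen$end_year - chosen$start_year) / 2),
      source = "c14_bomb"))
  }
  model <- fit_age_depth(ties, collection_year = config$collection_year,
                         max_depth = config$max_depth %||%
                           max(profile$depth_bottom_cm))
  grid <- seq(0, model$depth_range[2], by = 1)
  rates <- data.frame(depth_cm = grid,
                      rate_cm_yr = sedimentation_rate(model, grid))
  utils::write.csv(excess$data, file.path(outdir, "excess_pb.csv"),
                   row.names = FALSE)
  utils::write.csv(ties, file.path(outdir, "tie_points.csv"),
                   row.names = FALSE)
  write_age_model_csv(model, file.path(outdir, "age_model.csv"))
  utils::write.csv(rates, file.path(outdir, "sedimentation_rates.csv"),
                   row.names = FALSE)
  write_stage_info(config, "chronology", outdir, list(
    coefficients = as.list(model$coefficients),
    cs_peak_depth_cm = cs$depth,
    total_inventory_bq_cm2 = excess$total_inventory))
  invisible(list(model = model, excess = excess, tie_points = ties,
                 cs_peak = cs, rates = rates))
}

#' Run the proxy-quantification stage
#'
#' Reads the count table (and optional LOI table), computes marker-spike
#' concentrations per counting group, relative abundances, LOI, and
#' places every sample on the age model when one is supplied.
#'
#' @param config a [pipeline_config()] with `counts_csv` (and optionally
#'   `loi_csv`) set.
#' @param model optional `age_depth` model for age assignment.
#' @return (invisibly) list with `concentrations`, `abundances` (one
#'   `assemblage_matrix` per group), `loi`.
#' @export
run_proxies <- function(config, model = NULL) {
  outdir <- ensure_outdir(config)
  counts <- read_counts_csv(config$counts_csv)
  conc <- marker_concentration(counts)
  groups <- unique(counts$group)
  abundances <- list()
  for (g in groups) {
    gc <- counts[counts$group == g, , drop = FALSE]
    excl <- if (g == "pollen") config$exclude_taxa else NULL
    am <- relative_abundance(gc, exclude_taxa = excl)
    if (!is.null(model)) am$ages <- assign_ages(model, am$depth_cm)
    abundances[[g]] <- am
    wide <- data.frame(depth_cm = am$depth_cm,
                       age_ad = am$ages %||% rep(NA_real_, length(am$depth_cm)))
    wide <- cbind(wide, as.data.frame(am$proportions))
    utils::write.csv(wide, file.path(outdir, sprintf("abundance_%s.csv", g)),
                     row.names = FALSE)
    stage_log("proxies", "%s: %d samples, %d taxa, %d low-count",
              g, nrow(am$proportions), ncol(am$proportions),
              sum(am$low_count))
  }
  if (!is.null(model)) conc$age_ad <- assign_ages(model, conc$depth_cm)
  utils::write.csv(conc, file.path(outdir, "concentrations.csv"),
                   row.names = FALSE)
  loi <- NULL
  if (!is.null(config$loi_csv)) {
    loi <- loi550(read_loi_csv(config$loi_csv))
    if (!is.null(model)) loi$age_ad <- assign_ages(model, loi$depth_cm)
    utils::write.csv(loi, file.path(outdir, "loi.csv"), row.names = FALSE)
  }
  write_stage_info(config, "proxies", outdir)
  invisible(list(concentrations = conc, abundances = abundances, loi = loi))
}

#' Run the zonation stage
#'
#' Applies significance-screened information-content zonation to the
#' configured counting group's assemblage matrix.
#'
#' @param config a [pipeline_config()].
#' @param abundances result of [run_proxies()] (`abundances` element), or
#'   `NULL` to read `counts_csv` afresh.
#' @param model optional `age_depth` model for boundary ages.
#' @return (invisibly) the `zonation` result.
#' @export
run_zones <- function(config, abundances = NULL, model = NULL) {
  outdir <- ensure_outdir(config)
  g <- config$zonation_group
  am <- if (!is.null(abundances)) abundances[[g]] else {
    counts <- read_counts_csv(config$counts_csv)
    relative_abundance(counts[counts$group == g, , drop = FALSE])
  }
  if (is.null(am)) stop("no assemblage for zonation group ", g)
  if (is.null(am$ages) && !is.null(model))
    am$ages <- assign_ages(model, am$depth_cm)
  transform <- switch(config$zonation_transform,
                      none = NULL, sqrt = sqrt,
                      stop("unknown zonation_transform: ",
                           config$zonation_transform))
  zones <- recursive_zonation(am, max_splits = config$zonation_max_splits,
                              transform = transform)
  stage_log("zones", "%d significant boundary/ies of %d candidate split(s)",
            zones$n_significant, nrow(zones$splits))
  write_zones_csv(zones, file.path(outdir, "zones.csv"))
  write_stage_info(config, "zones", outdir,
                   list(n_significant = zones$n_significant))
  invisible(zones)
}

#' Run the sea-ice stage
#'
#' Reads the daily sea-ice table (a regional series, or a long grid with
#' a `cell_id` column which is first averaged over the region), computes
#' annual phenology, period means and decadal trends of the ice-free
#' season and of the melt/freeze onsets.
#'
#' @param config a [pipeline_config()] with `sic_csv` set.
#' @return (invisibly) list with `phenology` (per-year), `periods`,
#'   `trends`.
#' @export
run_seaice <- function(config) {
  outdir <- ensure_outdir(config)
  sic <- utils::read.csv(config$sic_csv, stringsAsFactors = FALSE)
  sic$date <- as.Date(sic$date)
  if ("cell_id" %in% names(sic)) {
    sic <- regional_mean_sic(sic, region = config$sic_region)
  }
  stopifnot_cols(sic, c("date", "sic_percent"), "sea-ice table")
  years <- sort(unique(year_of(sic$date)))
  pheno <- period_phenology(sic, years,
                            threshold_free = config$threshold_free,
                            threshold_high = config$threshold_high,
                            min_days = config$min_sic_days)
  tab <- pheno$table[!pheno$table$low_coverage, , drop = FALSE]
  trends <- list(
    ice_free_days = linear_trend(tab$year, tab$ice_free_days),
    melt_onset = linear_trend(tab$year, tab$melt_onset_doy),
    freeze_onset = linear_trend(tab$year, tab$freeze_onset_doy))
  periods <- do.call(rbind, lapply(config$sic_periods, function(p) {
    m <- period_phenology(sic, p[1]:p[2],
                          threshold_free = config$threshold_free,
                          threshold_high = config$threshold_high,
                          min_days = config$min_sic_days)$mean
    cbind(data.frame(start = p[1], end = p[2]), m)
  }))
  for (nm in names(trends)) {
    t <- trends[[nm]]
    stage_log("seaice", "%s trend: %.1f +/- %.1f d/decade (R^2=%.2f)",
              nm, t$slope_per_decade, t$slope_se, t$r_squared)
  }
  utils::write.csv(pheno$table, file.path(outdir, "sea_ice_phenology.csv"),
                   row.names = FALSE)
  utils::write.csv(periods, file.path(outdir, "sea_ice_periods.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(metric = names(trends),
               slope_per_decade = vapply(trends, `[[`, 0, "slope_per_decade"),
               slope_se = vapply(trends, `[[`, 0, "slope_se"),
               r_squared = vapply(trends, `[[`, 0, "r_squared"),
               p_value = vapply(trends, `[[`, 0, "p_value")),
    file.path(outdir, "sea_ice_trends.csv"), row.names = FALSE)
  write_stage_info(config, "seaice", outdir)
  invisible(list(phenology = pheno$table, periods = periods,
                 trends = trends))
}

#' Run the temperature stage
#'
#' Stacks the configured stations into a blended daily record, shifts it
#' to the core site by the configured offset, and derives annual mean
#' temperature, melting-season length and their decadal trends.
#'
#' @param config a [pipeline_config()] with `stations_csv` set.
#' @return (invisibly) list with `site_annual`, `melt_season`, `trends`.
#' @export
run_temperature <- function(config) {
  outdir <- ensure_outdir(config)
  stations <- read_station_csv(config$stations_csv)
  stations <- stations[!(stations$station %in% config$exclude_stations), ]
  if (nrow(stations) == 0L) stop("no stations left after exclusion")
  blended <- stack_stations(stations, min_stations = config$min_stations)
  site <- site_temperature(blended, offset = config$site_offset,
                           offset_sigma = config$site_offset_sigma)
  yr <- year_of(site$date)
  annual <- data.frame(
    year = sort(unique(yr)),
    tmean_c = as.numeric(tapply(site$tmean_c, yr, mean, na.rm = TRUE)))
  melt <- melting_season_length(site)
  trends <- list(
    temperature = linear_trend(annual$year, annual$tmean_c),
    melt_season = linear_trend(melt$year, melt$melt_days))
  stage_log("temperature",
            "warming %.2f +/- %.2f C/decade; melt season %+.1f +/- %.1f d/decade",
            trends$temperature$slope_per_decade, trends$temperature$slope_se,
            trends$melt_season$slope_per_decade, trends$melt_season$slope_se)
  utils::write.csv(annual, file.path(outdir, "site_annual_temperature.csv"),
                   row.names = FALSE)
  utils::write.csv(melt, file.path(outdir, "melt_season.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(metric = names(trends),
               slope_per_decade = vapply(trends, `[[`, 0, "slope_per_decade"),
               slope_se = vapply(trends, `[[`, 0, "slope_se"),
               r_squared = vapply(trends, `[[`, 0, "r_squared"),
               p_value = vapply(trends, `[[`, 0, "p_value")),
    file.path(outdir, "temperature_trends.csv"), row.names = FALSE)
  write_stage_info(config, "temperature", outdir)
  invisible(list(site_annual = annual, melt_season = melt, trends = trends))
}

#' Run the full pipeline
#'
#' Executes chronology, proxies, zonation, sea ice and temperature in
#' order (each stage only if its inputs are configured), aborting with a
#' stage-tagged error on failure, and writes `summary.json` with the
#' headline numbers (age-model coefficients, zone-boundary ages, period
#' phenology means, decadal trends) plus `stratigraphy.csv`, a
#' diagram-ready table of age against the proxies and zone membership.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of stage results plus `summary`.
#' @export
run_all <- function(config) {
  outdir <- ensure_outdir(config)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] stage failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  chron <- proxies <- zones <- seaice <- temperature <- NULL
  if (!is.null(config$isotope_csv))
    chron <- run_stage("chronology", run_chronology(config))
  if (!is.null(config$counts_csv))
    proxies <- run_stage("proxies", run_proxies(config, model = chron$model))
  if (!is.null(proxies))
    zones <- run_stage("zones",
                       run_zones(config, proxies$abundances, chron$model))
  if (!is.null(config$sic_csv))
    seaice <- run_stage("seaice", run_seaice(config))
  if (!is.null(config$stations_csv))
    temperature <- run_stage("temperature", run_temperature(config))
  summary <- list(
    config_hash = config_hash(config),
    chronology = if (!is.null(chron)) list(
      coefficients = as.list(chron$model$coefficients),
      surface_age_ad = predict(chron$model, 0),
      base_age_ad = predict(chron$model, chron$model$depth_range[2]),
      cs_peak_depth_cm = chron$cs_peak$depth),
    zonation = if (!is.null(zones)) list(
      n_significant = zones$n_significant,
      boundary_ages_ad = zones$splits$boundary_age_ad[
        seq_len(zones$n_significant)],
      boundary_depths_cm = zones$splits$boundary_depth_cm[
        seq_len(zones$n_significant)]),
    sea_ice = if (!is.null(seaice)) list(
      period_ice_free_days = stats::setNames(
        as.list(seaice$periods$ice_free_days),
        sprintf("%d-%d", seaice$periods$start, seaice$periods$end)),
      trends_d_per_decade = lapply(seaice$trends, `[[`, "slope_per_decade")),
    temperature = if (!is.null(temperature)) list(
      warming_c_per_decade = temperature$trends$temperature$slope_per_decade,
      melt_season_d_per_decade =
        temperature$trends$melt_season$slope_per_decade)
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(proxies) && !is.null(chron)) {
    conc <- proxies$concentrations
    strat <- data.frame(depth_cm = conc$depth_cm, group = conc$group,
                        age_ad = conc$age_ad %||% NA_real_,
                        concentration_per_g = conc$concentration_per_g)
    if (!is.null(zones) && zones$n_significant > 0) {
      bounds <- sort(zones$splits$boundary_depth_cm[
        seq_len(zones$n_significant)])
      strat$zone <- findInterval(strat$depth_cm, bounds) + 1L
    } else strat$zone <- 1L
    if (!is.null(proxies$loi)) {
      strat <- merge(strat,
                     proxies$loi[, c("depth_cm", "loi_percent")],
                     by = "depth_cm", all.x = TRUE)
    }
    utils::write.csv(strat[order(strat$depth_cm), ],
                     file.path(outdir, "stratigraphy.csv"),
                     row.names = FALSE)
  }
  invisible(list(chronology = chron, proxies = proxies, zones = zones,
                 sea_ice = seaice, temperature = temperature,
                 summary = summary))
}
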