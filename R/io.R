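# CSV dialects shared by the pipeline and the synthetic generators, so
# synthetic outputs are drop-in fixtures. Empty cells mean "not measured".

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s (%s) is missing column(s): %s",
                 what, path, paste(missing, collapse = ", ")))
  df
}

#' Read / write the per-slice isotope table
#'
#' Columns: `depth_top_cm, depth_bottom_cm, dry_mass_g, pb210_bq_kg,
#' pb210_sd, ra226_bq_kg, ra226_sd, cs137_bq_kg, cs137_sd`; empty cells
#' mark unmeasured slices.
#'
#' @param path file path.
#' @param profile isotope profile data.frame (for writing).
#' @return the profile data.frame (reading), or `path` invisibly.
#' @export
read_isotope_csv <- function(path) {
  df <- read_checked_csv(path, c("depth_top_cm", "depth_bottom_cm",
                                 "dry_mass_g", "pb210_bq_kg", "pb210_sd",
                                 "ra226_bq_kg", "ra226_sd"),
                         "isotope table")
  validate_isotope_profile(df)
  df
}

#' @rdname read_isotope_csv
#' @export
write_isotope_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a post-bomb radiocarbon calibration curve
#'
#' Columns: `year_ad, f14c_percent, f14c_sd`.
#' @param path file path.
#' @return data.frame.
#' @export
read_calibration_csv <- function(path) {
  read_checked_csv(path, c("year_ad", "f14c_percent", "f14c_sd"),
                   "calibration curve")
}

#' Read / write the long-format microfossil count table
#'
#' Columns: `depth_cm, group, taxon, count` plus the per-sample sidecar
#' columns `marker_counted, marker_added, dry_mass_g`.
#'
#' @param path file path.
#' @param counts count table data.frame (for writing).
#' @return the count table (reading), or `path` invisibly.
#' @export
read_counts_csv <- function(path) {
  df <- read_checked_csv(path, c("depth_cm", "group", "taxon", "count",
                                 "marker_counted", "marker_added",
                                 "dry_mass_g"),
                         "count table")
  validate_count_table(df)
  df
}

#' @rdname read_counts_csv
#' @export
write_counts_csv <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read the loss-on-ignition table (`depth_cm, dry_g, ashed_g`)
#' @param path file path.
#' @return data.frame.
#' @export
read_loi_csv <- function(path) {
  read_checked_csv(path, c("depth_cm", "dry_g", "ashed_g"), "LOI table")
}

#' Read / write daily station temperature series
#'
#' Columns: `date, station, tmean_c, tmax_c` (ISO dates).
#' @param path file path.
#' @param stations station table (for writing).
#' @return the station table with `date` parsed (reading), or `path`.
#' @export
read_station_csv <- function(path) {
  df <- read_checked_csv(path, c("date", "station", "tmean_c", "tmax_c"),
                         "station table")
  df$date <- as.Date(df$date)
  df
}

#' @rdname read_station_csv
#' @export
write_station_csv <- function(stations, path) {
  utils::write.csv(stations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a daily sea-ice concentration series or long grid
#'
#' A series has columns `date, sic_percent`; a long grid additionally has
#' `cell_id` between them.
#' @param path file path.
#' @param sic series or grid data.frame (for writing).
#' @return data.frame with `date` parsed (reading), or `path`.
#' @export
read_sic_csv <- function(path) {
  df <- read_checked_csv(path, c("date", "sic_percent"), "sea-ice table")
  df$date <- as.Date(df$date)
  df
}

#' @rdname read_sic_csv
#' @export
write_sic_csv <- function(sic, path) {
  utils::write.csv(sic, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the age-model output table (`depth_cm, age_ad, age_sd, source`)
#' @param model an `age_depth` model.
#' @param path file path.
#' @param step depth step of the evaluation grid, cm.
#' @return `path`, invisibly.
#' @export
write_age_model_csv <- function(model, path, step = 1) {
  grid <- seq(model$depth_range[1], model$depth_range[2], by = step)
  df <- data.frame(depth_cm = grid,
                   age_ad = predict(model, grid),
                   age_sd = NA_real_,
                   source = "model")
  tie <- data.frame(depth_cm = model$fit_points$depth,
                    age_ad = model$fit_points$age,
                    age_sd = model$fit_points$age_sigma,
                    source = model$fit_points$source)
  utils::write.csv(rbind(tie, df), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the zonation table
#'
#' Columns: `rank, boundary_depth_cm, boundary_age_ad, reduction,
#' broken_stick, significant`.
#' @param zones a `zonation` result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_zones_csv <- function(zones, path) {
  s <- zones$splits
  utils::write.csv(
    data.frame(rank = s$rank, boundary_depth_cm = s$boundary_depth_cm,
               boundary_age_ad = s$boundary_age_ad, reduction = s$reduction,
               broken_stick = s$broken_stick, significant = s$significant),
    path, row.names = FALSE, na = "")
  invisible(path)
}
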