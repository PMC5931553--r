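# Proxy quantification: exotic-marker (spike) concentrations, relative
# abundances under a sum rule, and loss-on-ignition organic content.

validate_count_table <- function(counts) {
  stopifnot_cols(counts,
                 c("depth_cm", "group", "taxon", "count",
                   "marker_counted", "marker_added", "dry_mass_g"),
                 "count table")
  if (any(counts$count < 0) || any(counts$count != floor(counts$count)))
    stop("taxon counts must be non-negative integers")
  if (any(counts$marker_added <= 0)) stop("marker_added must be positive")
  if (any(counts$dry_mass_g <= 0)) stop("dry_mass_g must be positive")
  invisible(counts)
}

#' Marker-spike microfossil concentrations
#'
#' A known quantity of exotic marker particles (Lycopodium spores for
#' pollen/Pediastrum, microspheres for diatoms) is added to each sample
#' before counting; the concentration of a taxon (or of the whole group)
#' follows from the ratio of its count to the number of markers
#' encountered: `conc = (count / marker_counted) * marker_added /
#' dry_mass`. The reported sigma carries Poisson counting error on both
#' counts, propagated by the delta method
#' (`sigma / conc = sqrt(1/count + 1/marker_counted)`); weighing error is
#' ignored since counts dominate at the tens-to-hundreds per slide typical
#' of these analyses.
#'
#' @param counts long-format count table (see [gen_assemblage()] for the
#'   column layout).
#' @param by_taxon if `FALSE` (default) return one group-total
#'   concentration per sample; if `TRUE`, one row per (sample, taxon).
#' @return data.frame with `depth_cm`, `group` (and `taxon` when
#'   `by_taxon`), `count`, `concentration_per_g` and `concentration_sd`.
#' @examples
#' s <- data.frame(depth_cm = 1, group = "pollen", taxon = "Salix",
#'                 count = 20L, marker_counted = 100, marker_added = 2136,
#'                 dry_mass_g = 0.5)
#' marker_concentration(s)  # 854.4 grains per gram
#' @export
marker_concentration <- function(counts, by_taxon = FALSE) {
  validate_count_table(counts)
  if (any(counts$marker_counted == 0))
    stop("marker_counted is 0 for some sample(s): concentration undefined")
  key <- if (by_taxon) {
    interaction(counts$depth_cm, counts$group, counts$taxon, drop = TRUE)
  } else {
    interaction(counts$depth_cm, counts$group, drop = TRUE)
  }
  agg <- function(v, f = sum) as.numeric(tapply(v, key, f))
  first <- function(v) tapply(v, key, function(x) x[1])
  n <- agg(counts$count)
  m <- as.numeric(first(counts$marker_counted))
  added <- as.numeric(first(counts$marker_added))
  mass <- as.numeric(first(counts$dry_mass_g))
  conc <- (n / m) * added / mass
  rel_var <- ifelse(n > 0, 1 / n, 0) + 1 / m
  out <- data.frame(
    depth_cm = as.numeric(first(counts$depth_cm)),
    group = as.character(first(counts$group)),
    count = n,
    concentration_per_g = conc,
    concentration_sd = conc * sqrt(rel_var)
  )
  if (by_taxon) out$taxon <- as.character(first(counts$taxon))
  ord <- order(out$depth_cm)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative abundances under a sum rule
#'
#' Converts a long-format count table into a row-stochastic assemblage
#' matrix (samples x taxa, shallowest sample first). The sum rule selects
#' which taxa enter the percentage base: e.g. pollen percentages exclude
#' aquatic taxa, while Pediastrum and diatom percentages use the full
#' identified sum. Samples whose included total falls below
#' `min_total` (default 50) are flagged low-count but retained.
#'
#' @param counts long-format count table.
#' @param exclude_taxa character vector of taxa excluded from the sum
#'   (and from the matrix), e.g. aquatic pollen types.
#' @param min_total reporting threshold for the per-sample sum.
#' @param ages optional calendar ages (years AD), one per sample in depth
#'   order.
#' @return An object of class `assemblage_matrix`: list with
#'   `proportions` (matrix, rows sum to 1), `depth_cm`, `ages`,
#'   `total_counts` and `low_count`.
#' @export
relative_abundance <- function(counts, exclude_taxa = NULL, min_total = 50,
                               ages = NULL) {
  validate_count_table(counts)
  counts <- counts[!(counts$taxon %in% exclude_taxa), , drop = FALSE]
  if (nrow(counts) == 0L) stop("no taxa left after exclusion")
  depths <- sort(unique(counts$depth_cm))
  taxa <- sort(unique(counts$taxon))
  mat <- matrix(0, length(depths), length(taxa),
                dimnames = list(NULL, taxa))
  mat[cbind(match(counts$depth_cm, depths),
            match(counts$taxon, taxa))] <- counts$count
  totals <- rowSums(mat)
  if (any(totals == 0))
    stop(sprintf("sample(s) at depth %s have zero included counts",
                 paste(depths[totals == 0], collapse = ", ")))
  if (!is.null(ages) && length(ages) != length(depths))
    stop("ages must have one value per sample")
  structure(list(
    proportions = mat / totals,
    depth_cm = depths,
    ages = ages,
    total_counts = totals,
    low_count = totals < min_total
  ), class = "assemblage_matrix")
}

#' @export
print.assemblage_matrix <- function(x, ...) {
  cat(sprintf("Assemblage matrix: %d samples x %d taxa (%.1f-%.1f cm)\n",
              nrow(x$proportions), ncol(x$proportions),
              min(x$depth_cm), max(x$depth_cm)))
  if (any(x$low_count))
    cat(sprintf("  %d low-count sample(s) below the reporting threshold\n",
                sum(x$low_count)))
  invisible(x)
}

#' Loss-on-ignition organic content
#'
#' Weight-percent organic matter from the mass lost between drying
#' (105 degrees C, overnight) and ashing (550 degrees C, 4 h):
#' `LOI = 100 * (dry - ashed) / dry`.
#'
#' @param records data.frame with columns `depth_cm`, `dry_g`, `ashed_g`.
#' @return the input data.frame with an added `loi_percent` column.
#' @examples
#' loi550(data.frame(depth_cm = 1, dry_g = 1.0, ashed_g = 0.6))  # 40%
#' @export
loi550 <- function(records) {
  stopifnot_cols(records, c("depth_cm", "dry_g", "ashed_g"), "LOI table")
  if (any(records$dry_g <= 0))
    stop("dry weights must be positive")
  if (any(records$ashed_g > records$dry_g))
    stop("ashed weight exceeds dry weight: weighing error")
  if (any(records$ashed_g < 0)) stop("ashed weights must be non-negative")
  records$loi_percent <- 100 * (records$dry_g - records$ashed_g) / records$dry_g
  records
}
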