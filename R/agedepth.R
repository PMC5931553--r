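# Second-order polynomial age-depth model fitted through chronological
# tie points (CRS ages, the 137Cs peak, a bomb-calibrated 14C date and
# the sediment-water interface).

#' Fit a quadratic age-depth model through tie points
#'
#' Fits `age(d) = a d^2 + b d + c` (calendar years AD, depth in cm) by
#' weighted least squares through the supplied tie points, with weights
#' `1 / sigma^2` where a positive age sigma is given and unit weight
#' otherwise. Unless a surface tie point is already present, one is added
#' at the sediment-water interface (0 cm, the collection year,
#' sigma 0.5 yr). The fitted polynomial must be strictly decreasing in
#' depth (checked on a 0.1 cm grid over `depth_range`); non-monotonicity
#' signals incompatible tie points and is an error.
#'
#' @param points data.frame of tie points with columns `depth`, `age`
#'   (years AD), `age_sigma` (yr) and `source`; at least 3 points.
#' @param collection_year calendar year of core collection, used for the
#'   surface tie point and the surface-age check.
#' @param max_depth upper end of the model's validity range, cm; defaults
#'   to the deepest tie point. Evaluation beyond it is an error.
#' @param add_surface add the surface tie point if none is present.
#' @param surface_sigma age sigma assigned to the surface tie point, yr.
#' @return An object of class `age_depth`: list with `coefficients`
#'   (named `c`, `b`, `a` for the constant, linear and quadratic terms),
#'   `fit_points`, `depth_range`, `collection_year` and the underlying
#'   `lm` fit.
#' @seealso [predict.age_depth()], [sedimentation_rate()], [assign_ages()]
#' @examples
#' pts <- data.frame(depth = c(25.5, 29.5), age = c(1973, 1962.5),
#'                   age_sigma = c(2, 1), source = c("c14_bomb", "cs_peak"))
#' m <- fit_age_depth(pts, collection_year = 2015, max_depth = 47)
#' predict(m, depth = 47)
#' @export
fit_age_depth <- function(points, collection_year, max_depth = NULL,
                          add_surface = TRUE, surface_sigma = 0.5) {
  stopifnot_cols(points, c("depth", "age"), "tie points")
  if (is.null(points$age_sigma)) points$age_sigma <- 0
  if (is.null(points$source)) points$source <- "user"
  pts <- points[, c("depth", "age", "age_sigma", "source")]
  if (add_surface && !any(pts$source == "surface")) {
    pts <- rbind(data.frame(depth = 0, age = collection_year,
                            age_sigma = surface_sigma, source = "surface"),
                 pts)
  }
  if (nrow(pts) < 3L) stop("need at least 3 tie points (incl. surface)")
  if (any(pts$age > collection_year + 1e-6))
    stop("tie-point ages cannot postdate the collection year")
  w <- ifelse(pts$age_sigma > 0, 1 / pts$age_sigma^2, 1)
  fit <- stats::lm(age ~ depth + I(depth^2), data = pts, weights = w)
  cf <- stats::coef(fit)
  coefficients <- c(c = unname(cf[1]), b = unname(cf[2]), a = unname(cf[3]))
  depth_range <- c(0, max_depth %||% max(pts$depth))
  grid <- seq(depth_range[1], depth_range[2], by = 0.1)
  ages <- coefficients["a"] * grid^2 + coefficients["b"] * grid +
    coefficients["c"]
  if (any(diff(ages) >= 0))
    stop("fitted age-depth polynomial is not strictly decreasing over ",
         sprintf("[0, %.1f] cm: tie points are incompatible", depth_range[2]))
  obj <- structure(list(
    coefficients = coefficients,
    fit_points = pts,
    depth_range = depth_range,
    collection_year = collection_year,
    lm = fit
  ), class = "age_depth")
  surf <- predict(obj, 0)
  if (any(pts$source == "surface") && abs(surf - collection_year) > 1)
    warning(sprintf(
      "modelled surface age %.1f differs from collection year %d by > 1 yr",
      surf, collection_year))
  obj
}

#' @export
print.age_depth <- function(x, ...) {
  cf <- x$coefficients
  cat("Quadratic age-depth model\n")
  cat(sprintf("  age(d) = %.6g %+.6g d %+.6g d^2   [years AD, d in cm]\n",
              cf["c"], cf["b"], cf["a"]))
  cat(sprintf("  %d tie points (%s), valid over 0-%.1f cm\n",
              nrow(x$fit_points),
              paste(unique(x$fit_points$source), collapse = ", "),
              x$depth_range[2]))
  cat(sprintf("  surface age %.1f AD, base age %.1f AD\n",
              predict(x, x$depth_range[1]), predict(x, x$depth_range[2])))
  invisible(x)
}

#' @export
summary.age_depth <- function(object, ...) {
  res <- residuals(object)
  cat("Quadratic age-depth model\n\nCoefficients:\n")
  print(object$coefficients)
  cat("\nTie points:\n")
  print(cbind(object$fit_points,
              fitted = round(predict(object, object$fit_points$depth), 1),
              residual = round(res, 2)), row.names = FALSE)
  cat(sprintf("\nWeighted RMS residual: %.2f yr\n",
              sqrt(stats::weighted.mean(
                res^2, ifelse(object$fit_points$age_sigma > 0,
                              1 / object$fit_points$age_sigma^2, 1)))))
  cat(sprintf("Sedimentation rate: %.3f cm/yr at surface, %.3f cm/yr at %.1f cm\n",
              sedimentation_rate(object, object$depth_range[1]),
              sedimentation_rate(object, object$depth_range[2]),
              object$depth_range[2]))
  invisible(object)
}

#' @export
coef.age_depth <- function(object, ...) object$coefficients

#' Evaluate an age-depth model
#'
#' @param object an [fit_age_depth()] model.
#' @param depth depths (cm) at which to evaluate; must lie within the
#'   model's `depth_range` (no extrapolation).
#' @param ... unused.
#' @return calendar ages, years AD, strictly decreasing with depth.
#' @export
predict.age_depth <- function(object, depth, ...) {
  if (any(depth < object$depth_range[1] - 1e-9 |
          depth > object$depth_range[2] + 1e-9))
    stop(sprintf("depth outside the model's validity range [0, %.1f] cm",
                 object$depth_range[2]))
  cf <- object$coefficients
  unname(cf["a"] * depth^2 + cf["b"] * depth + cf["c"])
}

#' @export
residuals.age_depth <- function(object, ...) {
  object$fit_points$age - predict(object, object$fit_points$depth)
}

#' @export
plot.age_depth <- function(x, ...) {
  pts <- x$fit_points
  grid <- seq(x$depth_range[1], x$depth_range[2], length.out = 200)
  plot(predict(x, grid), grid, type = "l", ylim = rev(range(grid)),
       xlab = "Age (years AD)", ylab = "Depth (cm)",
       main = "Age-depth model", ...)
  graphics::points(pts$age, pts$depth, pch = 19,
                   col = as.integer(factor(pts$source)) + 1)
  graphics::segments(pts$age - pts$age_sigma, pts$depth,
                     pts$age + pts$age_sigma, pts$depth)
  graphics::legend("bottomleft", legend = levels(factor(pts$source)),
                   pch = 19, col = seq_along(levels(factor(pts$source))) + 1,
                   bty = "n")
  invisible(x)
}

#' Sedimentation rate implied by an age-depth model
#'
#' The linear sedimentation rate at depth `d` is the reciprocal of the
#' age gradient: `rate = -1 / (2 a d + b)` cm/yr, positive for any valid
#' (strictly decreasing) model.
#'
#' @param model an [fit_age_depth()] model.
#' @param depth depths (cm) within the model's validity range.
#' @return sedimentation rates, cm/yr.
#' @export
sedimentation_rate <- function(model, depth) {
  stopifnot(inherits(model, "age_depth"))
  if (any(depth < model$depth_range[1] - 1e-9 |
          depth > model$depth_range[2] + 1e-9))
    stop("depth outside the model's validity range")
  cf <- model$coefficients
  deriv <- 2 * cf["a"] * depth + cf["b"]
  if (any(abs(deriv) < 1e-12))
    stop("age gradient vanishes at a requested depth")
  unname(-1 / deriv)
}

#' Place proxy sample depths on an age model
#'
#' Vectorised evaluation of the age-depth polynomial at proxy sample
#' depths; a thin convenience wrapper around [predict.age_depth()].
#'
#' @param model an [fit_age_depth()] model.
#' @param depths depths (cm) within the model's validity range.
#' @return calendar ages, years AD.
#' @export
assign_ages <- function(model, depths) {
  stopifnot(inherits(model, "age_depth"))
  predict(model, depths)
}
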