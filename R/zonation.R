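# Stratigraphic zonation by optimal splitting on information content,
# with broken-stick significance screening. The information measure is
# the within-block Kullback-Leibler deviance of each sample against the
# block-mean composition (nats), following the information-content
# zonation tradition for stratigraphic assemblage sequences.

as_proportion_matrix <- function(x) {
  p <- if (inherits(x, "assemblage_matrix")) x$proportions else as.matrix(x)
  if (any(p < 0)) stop("proportions must be non-negative")
  rs <- rowSums(p)
  if (any(rs <= 0)) stop("every sample needs a positive total")
  if (any(abs(rs - 1) > 1e-6)) p <- p / rs
  p
}

#' Information content of a contiguous sample block
#'
#' `I = sum_ij p_ij log(p_ij / q_j)` over the block's samples, with `q_j`
#' the block-mean proportion of taxon `j`; zero proportions contribute
#' nothing. `I >= 0`, with equality iff all samples in the block are
#' compositionally identical.
#'
#' @param block matrix of row-stochastic sample proportions (or an
#'   `assemblage_matrix`).
#' @return information content in nats.
#' @export
zone_information <- function(block) {
  p <- as_proportion_matrix(block)
  if (nrow(p) == 0L) stop("block must be non-empty")
  q <- colMeans(p)
  pos <- p > 0            # q_j = 0 implies p_ij = 0 for all i: term is 0
  sum(p[pos] * log(p[pos] / rep(q, each = nrow(p))[pos]))
}

#' Best single split of a sample block
#'
#' Exhaustively evaluates every between-sample cut of a contiguous block
#' and returns the cut maximising the information reduction
#' `I(block) - I(left) - I(right)`; ties break toward the shallower cut.
#'
#' @param block matrix of row-stochastic sample proportions.
#' @return list with `position` (the cut lies after this row index),
#'   `reduction` (nats) and `reductions` (all candidate cuts).
#' @export
optimal_split <- function(block) {
  p <- as_proportion_matrix(block)
  n <- nrow(p)
  if (n < 2L) stop("block must contain at least 2 samples")
  total <- zone_information(p)
  red <- vapply(seq_len(n - 1L), function(cut) {
    total - zone_information(p[seq_len(cut), , drop = FALSE]) -
      zone_information(p[(cut + 1L):n, , drop = FALSE])
  }, numeric(1))
  best <- which.max(red)    # first maximum = shallower cut on ties
  list(position = best, reduction = red[best], reductions = red)
}

#' Broken-stick expected proportions
#'
#' Expected ordered piece sizes when a unit stick is broken at random
#' into `n_pieces`: `b_k = (1/n) * sum_{j=k}^{n} 1/j`. Used as the null
#' expectation for the proportional information reduction of the k-th
#' zonation split.
#'
#' @param n_pieces number of pieces (here, number of samples).
#' @param k piece rank(s); default all of `1:n_pieces`.
#' @return expected proportion(s), decreasing in `k` and summing to 1
#'   over all ranks.
#' @examples
#' broken_stick_expectation(3)  # 11/18, 5/18, 2/18
#' @export
broken_stick_expectation <- function(n_pieces, k = seq_len(n_pieces)) {
  if (any(k < 1 | k > n_pieces)) stop("k out of range 1..n_pieces")
  all_b <- rev(cumsum(1 / rev(seq_len(n_pieces)))) / n_pieces
  all_b[k]
}

#' Significance-screened recursive zonation
#'
#' Greedy recursive binary splitting: at each step the cut with the
#' largest attainable information reduction across all current blocks is
#' applied (each block searched exhaustively), until `max_splits` cuts
#' have been placed or no cut reduces information. Split `k` is deemed
#' significant while its proportional reduction
#' `reduction_k / I(whole sequence)` exceeds the broken-stick expectation
#' for rank `k` with the number of samples as the number of stick pieces;
#' `n_significant` is the longest prefix of splits that are all
#' significant.
#'
#' @param x an `assemblage_matrix` (carrying depths and optionally ages)
#'   or a plain row-stochastic matrix, samples ordered shallow to deep.
#' @param max_splits maximum number of cuts; default `n - 1`.
#' @param transform optional function applied to the proportion rows
#'   before the information computation (e.g. `sqrt`); rows are
#'   renormalised afterwards. Untransformed proportions are the default.
#' @return An object of class `zonation`: list with `splits` (data.frame
#'   `rank, position, boundary_depth_cm, boundary_age_ad, reduction,
#'   proportion, broken_stick, significant`; the cut at `position` falls
#'   between samples `position` and `position + 1`, boundary depth/age are
#'   midpoints of the bracketing samples), `n_significant`,
#'   `information` (whole-sequence I) and `n_samples`.
#' @export
recursive_zonation <- function(x, max_splits = NULL, transform = NULL) {
  p <- as_proportion_matrix(x)
  n <- nrow(p)
  if (n < 3L) stop("zonation needs at least 3 samples")
  if (!is.null(transform)) {
    p <- t(apply(p, 1L, transform))
    p <- p / rowSums(p)
  }
  max_splits <- max_splits %||% (n - 1L)
  total_info <- zone_information(p)
  blocks <- list(c(1L, n))
  splits <- integer(0)
  reductions <- numeric(0)
  while (length(splits) < max_splits) {
    best <- NULL
    for (b in blocks) {
      if (b[2] - b[1] < 1L) next
      s <- optimal_split(p[b[1]:b[2], , drop = FALSE])
      if (is.null(best) || s$reduction > best$reduction + 1e-15) {
        best <- list(block = b, position = b[1] - 1L + s$position,
                     reduction = s$reduction)
      }
    }
    if (is.null(best) || best$reduction <= 1e-12) break
    splits <- c(splits, best$position)
    reductions <- c(reductions, best$reduction)
    blocks <- c(Filter(function(b) !identical(b, best$block), blocks),
                list(c(best$block[1], best$position)),
                list(c(best$position + 1L, best$block[2])))
  }
  k <- length(splits)
  depths <- if (inherits(x, "assemblage_matrix")) x$depth_cm else seq_len(n)
  ages <- if (inherits(x, "assemblage_matrix")) x$ages else NULL
  prop <- if (total_info > 0) reductions / total_info else rep(0, k)
  bstick <- if (k > 0) broken_stick_expectation(n, seq_len(k)) else numeric(0)
  significant <- prop > bstick
  n_significant <- if (k == 0) 0L else {
    run <- cumprod(significant)
    as.integer(sum(run))
  }
  splits_df <- data.frame(
    rank = seq_len(k),
    position = splits,
    boundary_depth_cm = if (k > 0)
      (depths[splits] + depths[splits + 1L]) / 2 else numeric(0),
    boundary_age_ad = if (!is.null(ages) && k > 0)
      (ages[splits] + ages[splits + 1L]) / 2 else rep(NA_real_, k),
    reduction = reductions,
    proportion = prop,
    broken_stick = bstick,
    significant = significant
  )
  structure(list(
    splits = splits_df,
    n_significant = n_significant,
    information = total_info,
    n_samples = n
  ), class = "zonation")
}

#' @export
print.zonation <- function(x, ...) {
  cat(sprintf(
    "Stratigraphic zonation: %d samples, total information %.3f nats\n",
    x$n_samples, x$information))
  cat(sprintf("  %d significant split(s) under the broken-stick null\n",
              x$n_significant))
  if (nrow(x$splits) > 0) {
    print(format(x$splits, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.zonation <- function(object, ...) {
  print(object)
  sig <- object$splits[object$splits$significant &
                         object$splits$rank <= object$n_significant, ]
  if (nrow(sig) > 0) {
    cat("\nZone boundaries (significant, shallow to deep):\n")
    ord <- order(sig$boundary_depth_cm)
    for (i in ord) {
      cat(sprintf("  %.2f cm%s\n", sig$boundary_depth_cm[i],
                  if (!is.na(sig$boundary_age_ad[i]))
                    sprintf(" (~%.0f AD)", sig$boundary_age_ad[i]) else ""))
    }
  }
  invisible(object)
}

#' @export
plot.zonation <- function(x, ...) {
  s <- x$splits
  if (nrow(s) == 0) {
    plot.new(); graphics::title("No splits"); return(invisible(x))
  }
  plot(s$rank, s$proportion, type = "h", lwd = 3,
       xlab = "Split rank", ylab = "Proportional information reduction",
       main = "Zonation splits vs broken-stick null", ...)
  graphics::lines(s$rank, s$broken_stick, type = "b", pch = 1, lty = 2)
  graphics::legend("topright", legend = c("observed", "broken stick"),
                   lty = c(1, 2), lwd = c(3, 1), bty = "n")
  invisible(x)
}
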