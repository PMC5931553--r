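# Shared fixtures, built in code.

# Single-epoch, noise-free core: CRS recovery should be near-exact.
constant_rate_scenario <- function(noise_cv = 0, seed = 1L) {
  sediment_scenario(
    epochs = data.frame(start_year = 1915, end_year = 2015, mar = 0.04),
    noise_cv = noise_cv, seed = seed)
}

# Two epochs with a long, slow old stage (closed-form t(z) oracle below).
two_epoch_scenario <- function(noise_cv = 0, seed = 1L) {
  sediment_scenario(
    epochs = data.frame(start_year = c(1880, 1970),
                        end_year = c(1970, 2015),
                        mar = c(0.01, 0.04)),
    noise_cv = noise_cv, seed = seed)
}

# Independent closed-form age oracle for a piecewise-constant rate
# history: integrates depth accumulated since deposition, epoch by epoch.
oracle_age_at_depth <- function(epochs, bulk_density, depth) {
  v <- epochs$mar / bulk_density
  dur <- epochs$end_year - epochs$start_year
  thick <- rev(v * dur)              # newest first
  v_new <- rev(v)
  end_new <- rev(epochs$end_year)
  vapply(depth, function(z) {
    for (i in seq_along(thick)) {
      top <- sum(thick[seq_len(i - 1)])
      if (z <= top + thick[i] + 1e-9) {
        return(end_new[i] - (z - top) / v_new[i])
      }
    }
    NA_real_
  }, numeric(1))
}

# Strong two-zone assemblage scenario with disjoint dominant taxa over a
# realistic assemblage richness (12 taxa, as on a typical diatom count
# sheet; with very few taxa the broken-stick screen is anticonservative).
two_zone_compositions <- function() {
  k <- 12
  z1 <- rep(0.035, k); z1[1] <- 0.40; z1[2] <- 0.25
  z2 <- rep(0.035, k); z2[k] <- 0.40; z2[k - 1] <- 0.25
  rbind(z1, z2)
}

two_zone_scenario <- function(n_samples = 20, boundary = 10, seed = 1L,
                              counts = 300) {
  zone_scenario(
    n_samples = n_samples, boundaries = boundary,
    zone_compositions = two_zone_compositions(),
    concentration_parameter = 200, counts_per_sample = counts,
    seed = seed)
}

# Rank-abundance style single-zone composition (homogeneous null).
homogeneous_composition <- function(k = 12) {
  p <- 0.7^(seq_len(k))
  matrix(p / sum(p), 1)
}

# Exhaustive best-first zonation oracle: same information measure, naive
# implementation, used to cross-check the recursive splitter.
oracle_information <- function(p) {
  q <- colMeans(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / q[j])
  }
  s
}

oracle_best_split <- function(p) {
  n <- nrow(p)
  red <- sapply(seq_len(n - 1), function(cut)
    oracle_information(p) -
      oracle_information(p[seq_len(cut), , drop = FALSE]) -
      oracle_information(p[(cut + 1):n, , drop = FALSE]))
  list(position = which.max(red), reduction = max(red))
}

oracle_greedy_zonation <- function(p, max_splits) {
  blocks <- list(c(1, nrow(p)))
  out <- list()
  while (length(out) < max_splits) {
    cand <- lapply(blocks, function(b) {
      if (b[2] - b[1] < 1) return(NULL)
      s <- oracle_best_split(p[b[1]:b[2], , drop = FALSE])
      list(block = b, position = b[1] - 1 + s$position,
           reduction = s$reduction)
    })
    cand <- Filter(Negate(is.null), cand)
    if (length(cand) == 0) break
    best <- cand[[which.max(vapply(cand, `[[`, 0, "reduction"))]]
    if (best$reduction <= 1e-12) break
    out[[length(out) + 1]] <- best
    blocks <- c(Filter(function(b) !identical(b, best$block), blocks),
                list(c(best$block[1], best$position)),
                list(c(best$position + 1, best$block[2])))
  }
  out
}

# Row-stochastic random matrix
random_proportions <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}
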