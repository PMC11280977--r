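# Independent brute-force oracles used across the test files. These are
# deliberately naive re-derivations from first principles and must stay
# independent of the package implementation they check.

# One-way ANOVA ICC(1,1) from explicit sums of squares over a long format.
oracle_icc_oneway <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  ssb <- 0
  ssw <- 0
  for (i in seq_len(n)) {
    mi <- mean(m[i, ])
    ssb <- ssb + k * (mi - grand)^2
    for (j in seq_len(k)) ssw <- ssw + (m[i, j] - mi)^2
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# First-order features recomputed naively (loops, explicit formulas).
oracle_features <- function(v, voxel_volume = 27, bins = 64) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  qs <- quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  band <- v[v >= qs[1] & v <= qs[5]]
  # histogram on [min, max] with equal bins, right-closed top bin
  mn <- min(v)
  mx <- max(v)
  if (mx == mn) {
    p <- c(1, rep(0, bins - 1))
  } else {
    cnt <- integer(bins)
    for (x in v) {
      b <- min(bins, floor((x - mn) / ((mx - mn) / bins)) + 1)
      cnt[b] <- cnt[b] + 1
    }
    p <- cnt / n
  }
  pp <- p[p > 0]
  list(
    mean = m,
    median = qs[3],
    p10 = qs[1],
    p90 = qs[5],
    minimum = mn,
    maximum = mx,
    root_mean_squared = sqrt(sum(v^2) / n),
    variance = m2,
    skewness = if (n >= 3 && m2 > 0) m3 / m2^1.5 else NA_real_,
    kurtosis = if (n >= 3 && m2 > 0) m4 / m2^2 else NA_real_,
    range = mx - mn,
    interquartile_range = qs[4] - qs[2],
    mean_absolute_deviation = sum(abs(v - m)) / n,
    robust_mean_absolute_deviation = mean(abs(band - mean(band))),
    energy = sum(v^2),
    total_energy = sum(v^2) * voxel_volume,
    entropy = -sum(pp * log2(pp)),
    uniformity = sum(p^2)
  )
}

# Spearman's rho via explicit average ranks + Pearson on the ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Brute-force maximum pairwise in-plane distance over axial slices.
oracle_axial_diameter <- function(mask, spacing) {
  dims <- dim(mask)
  best <- 0
  for (z in seq_len(dims[3])) {
    pts <- which(mask[, , z], arr.ind = TRUE)
    if (nrow(pts) < 2) next
    for (i in seq_len(nrow(pts) - 1)) for (j in (i + 1):nrow(pts)) {
      d <- sqrt(sum((((pts[i, ] - pts[j, ]) * spacing[1:2]))^2))
      best <- max(best, d)
    }
  }
  best
}

# A noise-free single-lesion phantom on a 3 mm isotropic grid (resampling to
# the 3 mm feature grid is then the identity).
make_iso_phantom <- function(lesion_ff = 15, marrow_ff = 70, seed = 1) {
  cfg <- phantom_config(
    grid_shape = c(16, 16, 16), spacing_mm = c(3, 3, 3),
    marrow_ff_mean = marrow_ff, marrow_ff_sd = 0,
    lesions = list(lesion_spec(c(22, 22, 22), c(9, 9, 9),
                               lesion_ff_mean = lesion_ff,
                               lesion_ff_sd = 0)),
    interface_blur_mm = 0, noise_sd = 0, seed = seed
  )
  generate_dixon_phantom(cfg)
}

# Rasterized ellipsoid mask helper for ROI tests.
make_ellipsoid_mask <- function(dims, spacing, center, radii) {
  coords <- lapply(1:3, function(ax) (seq_len(dims[ax]) - 1) * spacing[ax])
  d2 <- outer(
    outer((coords[[1]] - center[1])^2 / radii[1]^2,
          (coords[[2]] - center[2])^2 / radii[2]^2, `+`),
    (coords[[3]] - center[3])^2 / radii[3]^2, `+`
  )
  d2 <= 1
}
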