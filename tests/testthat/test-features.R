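test_that("constant ROI passes preprocessing untouched (SD = 0 branch)", {
  ph <- make_iso_phantom(lesion_ff = 20, marrow_ff = 20)
  ff <- compute_ff_map(ph$volume)
  s <- preprocess_roi(ff, ph$lesions[[1]])
  expect_identical(s$n_removed, 0L)
  expect_true(all(s$values == 20))
})

test_that("the 3-SD rule removes a genuinely extreme value (hand oracle)", {
  # {10 x 10.0, one 90.0}: mean 190/11 = 17.27, sample SD 24.12;
  # |90 - 17.27| = 72.73 > 3 * 24.12 = 72.36, so the 90 is removed.
  v <- c(rep(10, 10), 90)
  m <- mean(v)
  s <- sd(v)
  expect_true(abs(90 - m) > 3 * s)
  ph <- make_iso_phantom(lesion_ff = 20, marrow_ff = 20)
  ff <- compute_ff_map(ph$volume)
  idx <- which(ph$lesions[[1]]$mask)
  ff$values[] <- 10
  ff$values[idx[1]] <- 90
  roi <- ph$lesions[[1]]
  keep <- array(FALSE, dim(roi$mask))
  keep[idx[1:11]] <- TRUE
  roi$mask <- keep
  out <- preprocess_roi(ff, roi)
  expect_identical(out$n_raw, 11L)
  expect_identical(out$n_removed, 1L)
  expect_true(all(out$values == 10))
})

test_that("3-SD rule removes exactly an implanted outlier in a Normal sample", {
  ph <- make_iso_phantom(lesion_ff = 20, marrow_ff = 20)
  ff <- compute_ff_map(ph$volume)
  roi <- ph$lesions[[1]]
  idx <- which(roi$mask)
  withr::with_seed(42, {
    ff$values[idx] <- rnorm(length(idx), 20, 2)
  })
  ff$values[idx[1]] <- 60
  out <- preprocess_roi(ff, roi)
  expect_identical(out$n_removed, 1L)
  expect_false(any(out$values == 60))
})

test_that("discretization matches the degenerate, uniform and oracle cases", {
  h0 <- discretize(rep(7, 5))
  expect_equal(h0$probabilities[1], 1)
  expect_equal(sum(h0$probabilities), 1)

  mids <- (0:63) + 0.5
  hu <- discretize(mids)
  expect_equal(hu$probabilities, rep(1 / 64, 64))

  withr::with_seed(1, v <- runif(100, 5, 60))
  h <- discretize(v)
  o <- oracle_features(v)
  expect_equal(sum(h$probabilities), 1)
  expect_equal(-sum(h$probabilities[h$probabilities > 0] *
                      log2(h$probabilities[h$probabilities > 0])),
               o$entropy)
  expect_equal(sum(h$probabilities^2), o$uniformity)
})

test_that("first-order features match hand arithmetic on {1,2,3}", {
  f <- first_order_features(c(1, 2, 3))
  expect_equal(f$mean, 2)
  expect_equal(f$median, 2)
  expect_equal(f$minimum, 1)
  expect_equal(f$maximum, 3)
  expect_equal(f$root_mean_squared, sqrt(14 / 3))
  expect_equal(f$variance, 2 / 3)
  expect_equal(f$range, 2)
})

test_that("features match the brute-force oracle on random samples", {
  withr::with_seed(99, {
    for (i in 1:50) {
      n <- sample(5:200, 1)
      v <- switch(sample(3, 1),
                  rnorm(n, 20, 5),
                  runif(n, 0, 100),
                  rexp(n, 0.1))
      f <- first_order_features(v)
      o <- oracle_features(v)
      for (nm in names(o)) {
        expect_equal(f[[nm]], o[[nm]], tolerance = 1e-9,
                     label = paste("feature", nm))
      }
    }
  })
})

test_that("feature invariants: ordering, entropy range, translation", {
  withr::with_seed(5, v <- rnorm(500, 30, 8))
  f <- first_order_features(v)
  expect_true(f$minimum <= f$p10 && f$p10 <= f$median &&
                f$median <= f$p90 && f$p90 <= f$maximum)
  expect_true(f$entropy >= 0 && f$entropy <= 6)
  expect_true(f$uniformity >= 1 / 64 && f$uniformity <= 1)

  g <- first_order_features(v + 7)
  expect_equal(g$mean, f$mean + 7)
  expect_equal(g$variance, f$variance)
  expect_equal(g$skewness, f$skewness)
  expect_equal(g$kurtosis, f$kurtosis)

  h <- first_order_features(sample(v))
  expect_equal(h$mean, f$mean)
  expect_equal(h$entropy, f$entropy)
})

test_that("degenerate samples flag undefined moments as missing, not zero", {
  f <- first_order_features(c(4, 4, 4, 4))
  expect_true(is.na(f$skewness))
  expect_true(is.na(f$kurtosis))
  expect_equal(f$entropy, 0)
  expect_equal(f$uniformity, 1)
  f2 <- first_order_features(c(1, 2))
  expect_true(is.na(f2$skewness))
})

test_that("noise-free phantom yields the configured mean FF in both modes", {
  ph <- make_iso_phantom(lesion_ff = 15, marrow_ff = 70)
  ff <- compute_ff_map(ph$volume)
  roi <- ph$lesions[[1]]
  expect_identical(measure_mean_ff(ff, roi, "volume"), 15)
  expect_identical(measure_mean_ff(ff, roi, "slice"), 15)
})

test_that("slice and volume means differ by the known offset under a gradient", {
  # ellipsoid centered exactly on slice 8 of a 3 mm isotropic grid, with an
  # axial FF gradient of value = slice index: symmetry makes the volume mean
  # exactly the central slice value
  dims <- c(16L, 16L, 16L)
  sp <- c(3, 3, 3)
  mask <- make_ellipsoid_mask(dims, sp, c(21, 21, 21), c(9, 9, 9))
  roi <- lesion_roi(mask, sp, "S1", "L1")
  grad <- array(rep(seq_len(dims[3]), each = prod(dims[1:2])), dims)
  ff <- ff_map(grad, sp)
  sl <- select_representative_slice(roi)
  expect_identical(sl, 8L)
  expect_equal(measure_mean_ff(ff, roi, "slice", slice_index = sl), 8)
  expect_equal(measure_mean_ff(ff, roi, "volume"), 8)
  # shifting the chosen slice shifts the slice mean by exactly one gradient step
  expect_equal(measure_mean_ff(ff, roi, "slice", slice_index = sl + 1L), 9)
})

test_that("single-slice lesions are rejected in volume mode", {
  ph <- make_iso_phantom()
  ff <- compute_ff_map(ph$volume)
  roi <- single_slice_mask(ph$lesions[[1]])
  roi2 <- lesion_roi(roi$mask, roi$spacing_mm, "S1", "L1")
  expect_error(measure_mean_ff(ff, roi2, "volume"), "ineligible")
})

test_that("resampling to the native 3 mm spacing is the identity on features", {
  ph <- make_iso_phantom(lesion_ff = 15)
  ff <- compute_ff_map(ph$volume)
  s <- preprocess_roi(ff, ph$lesions[[1]], target_spacing_mm = c(3, 3, 3))
  expect_identical(length(s$values), sum(ph$lesions[[1]]$mask))
  expect_true(all(abs(s$values - 15) < 1e-6))
})

test_that("feature table carries bookkeeping and removal counts", {
  ph <- make_iso_phantom()
  ff <- compute_ff_map(ph$volume)
  tab <- extract_features_table(ff, ph$lesions)
  expect_identical(nrow(tab), 1L)
  expect_true(all(c("subject_id", "lesion_id", "size_class", "reader_id",
                    "repeat", "mode", "n_raw", "n_removed", "mean",
                    "entropy") %in% names(tab)))
  expect_equal(tab$mean, 15)
})
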