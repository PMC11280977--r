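test_that("noise-free phantom reproduces configured FF exactly inside and outside lesions", {
  cfg <- phantom_config(
    grid_shape = c(20, 20, 10), spacing_mm = c(1, 1, 3),
    marrow_ff_mean = 70, marrow_ff_sd = 0,
    lesions = list(lesion_spec(c(9, 9, 13), c(4, 4, 4),
                               lesion_ff_mean = 15, lesion_ff_sd = 0)),
    interface_blur_mm = 0, noise_sd = 0, seed = 7
  )
  ph <- generate_dixon_phantom(cfg)
  ff <- compute_ff_map(ph$volume)
  m <- ph$lesions[[1]]$mask
  expect_identical(unique(ff$values[m]), 15)
  expect_identical(unique(ff$values[!m]), 70)
  expect_true(all(ff$valid_mask))
})

test_that("phantom generation is bit-identical for a fixed seed", {
  cfg <- phantom_config(
    grid_shape = c(16, 16, 8), spacing_mm = c(1, 1, 3),
    marrow_ff_sd = 5, noise_sd = 2, interface_blur_mm = 1,
    lesions = list(lesion_spec(c(7, 7, 10), c(4, 4, 4), lesion_ff_sd = 2)),
    seed = 123
  )
  a <- generate_dixon_phantom(cfg)
  b <- generate_dixon_phantom(cfg)
  expect_identical(a$volume$fat_only, b$volume$fat_only)
  expect_identical(a$volume$water_only, b$volume$water_only)
  expect_identical(a$lesions[[1]]$mask, b$lesions[[1]]$mask)
})

test_that("ground-truth lesions are size-classified by axial diameter", {
  mk <- function(r) {
    cfg <- phantom_config(
      grid_shape = c(30, 30, 14), spacing_mm = c(1, 1, 3),
      lesions = list(lesion_spec(c(14, 14, 20), c(r, r, r))), seed = 1
    )
    generate_dixon_phantom(cfg)$lesions[[1]]
  }
  expect_identical(mk(4)$size_class, "small")
  expect_identical(mk(6)$size_class, "large")
})

test_that("a lesion outside the grid is rejected with its id", {
  cfg <- phantom_config(
    grid_shape = c(10, 10, 5), spacing_mm = c(1, 1, 3),
    lesions = list(lesion_spec(c(8, 8, 6), c(4, 4, 4), id = "LX"))
  )
  expect_error(generate_dixon_phantom(cfg), "LX")
})

test_that("reader model with zero perturbation is the identity on masks", {
  ph <- make_iso_phantom()
  truth <- ph$lesions[[1]]
  seg <- simulate_reader_segmentation(truth, reader_model("R1", 0, 0), 1)
  expect_identical(seg$mask, truth$mask)
  expect_identical(seg$reader_id, "R1")
  expect_identical(seg$repeat_index, 1L)
})

test_that("positive dilation bias never shrinks the mask", {
  ph <- make_iso_phantom()
  truth <- ph$lesions[[1]]
  seg <- simulate_reader_segmentation(
    truth, reader_model("R2", 0, dilation_bias_mm = 3.5), 1
  )
  expect_true(all(seg$mask[truth$mask]))
  expect_gt(sum(seg$mask), sum(truth$mask))
})

test_that("reader segmentation is deterministic and varies across repeats", {
  cfg <- phantom_config(
    grid_shape = c(30, 30, 14), spacing_mm = c(1, 1, 3),
    lesions = list(lesion_spec(c(14, 14, 20), c(6, 6, 6))), seed = 5
  )
  truth <- generate_dixon_phantom(cfg)$lesions[[1]]
  rm1 <- reader_model("R1", boundary_sigma_mm = 1, seed = 11)
  a1 <- simulate_reader_segmentation(truth, rm1, 1)
  a2 <- simulate_reader_segmentation(truth, rm1, 1)
  b <- simulate_reader_segmentation(truth, rm1, 2)
  expect_identical(a1$mask, a2$mask)
  expect_false(identical(a1$mask, b$mask))
  expect_gt(dice_coefficient(a1$mask, truth$mask), 0.7)
})

test_that("boundary noise hurts small lesions more than large ones (Dice)", {
  mk <- function(r) {
    cfg <- phantom_config(
      grid_shape = c(30, 30, 14), spacing_mm = c(1, 1, 3),
      lesions = list(lesion_spec(c(14, 14, 20), c(r, r, 6))), seed = 7
    )
    generate_dixon_phantom(cfg)$lesions[[1]]
  }
  big <- mk(6)    # 12 mm axial diameter
  small <- mk(3)  # 6 mm
  dice <- vapply(1:200, function(s) {
    rm <- reader_model("R1", boundary_sigma_mm = 1, seed = s)
    c(
      dice_coefficient(simulate_reader_segmentation(big, rm, 1)$mask,
                       big$mask),
      dice_coefficient(simulate_reader_segmentation(small, rm, 1)$mask,
                       small$mask)
    )
  }, numeric(2))
  expect_gt(mean(dice[1, ]), mean(dice[2, ]))
})

test_that("zero within-subject variance gives identical repeats and ICC 1", {
  vc <- variance_components(16, 5, 0, k = 2, n_subjects = 20)
  tab <- simulate_measurement_table(vc, seed = 3)
  m <- matrix(tab$value, ncol = 2, byrow = TRUE)
  expect_equal(m[, 1], m[, 2])
  expect_identical(icc_oneway(m)$estimate, 1)
})

test_that("zero between-subject variance gives ICC near 0 at large n", {
  vc <- variance_components(16, 0, 2, k = 2, n_subjects = 10000)
  tab <- simulate_measurement_table(vc, seed = 9)
  m <- matrix(tab$value, ncol = 2, byrow = TRUE)
  expect_lt(abs(icc_oneway(m)$estimate), 0.03)
})

test_that("measurement-table simulator recovers the configured true ICC", {
  vc <- variance_components(16, 5, 1.6, k = 2, n_subjects = 500)
  expect_equal(true_icc(vc), 5^2 / (5^2 + 1.6^2))
  tab <- simulate_measurement_table(vc, seed = 11)
  m <- matrix(tab$value, ncol = 2, byrow = TRUE)
  expect_lt(abs(icc_oneway(m)$estimate - true_icc(vc)), 0.02)
})

test_that("variance of subject means converges to sigma_b^2 + sigma_w^2 / k", {
  vc <- variance_components(10, 3, 2, k = 2, n_subjects = 20000)
  tab <- simulate_measurement_table(vc, seed = 4)
  m <- matrix(tab$value, ncol = 2, byrow = TRUE)
  v <- var(rowMeans(m))
  expect_lt(abs(v - (3^2 + 2^2 / 2)) / (3^2 + 2^2 / 2), 0.05)
})

test_that("derived seeds differ across labels and stay in integer range", {
  s1 <- derive_seed(1, "a")
  s2 <- derive_seed(1, "b")
  s3 <- derive_seed(2, "a")
  expect_false(s1 == s2)
  expect_false(s1 == s3)
  expect_true(all(c(s1, s2, s3) >= 0 & c(s1, s2, s3) < 2^31))
  expect_identical(derive_seed(1, "a"), s1)
})
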