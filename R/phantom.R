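# Synthetic Dixon phantom: ellipsoidal low-FF lesions embedded in high-FF
# marrow, a Gaussian-blurred lesion/marrow interface, voxel noise, and a
# fat/water decomposition at constant total signal. Reader variability is
# simulated by displacing the mask boundary with a smooth random field added
# to the signed distance function.

#' Lesion specification for the Dixon phantom
#'
#' @param center_mm Physical center coordinates (mm), length 3.
#' @param radii_mm Ellipsoid semi-axes (mm), length 3; the axial diameter of
#'   the lesion is twice the largest in-plane semi-axis.
#' @param lesion_ff_mean Mean fat fraction inside the lesion (percent).
#' @param lesion_ff_sd Voxelwise FF heterogeneity inside the lesion (percent).
#' @param id Lesion label.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, radii_mm, lesion_ff_mean = 16,
                        lesion_ff_sd = 0, id = "L1") {
  stopifnot(length(center_mm) == 3L, length(radii_mm) == 3L,
            all(radii_mm > 0), lesion_ff_mean >= 0, lesion_ff_mean <= 100,
            lesion_ff_sd >= 0)
  structure(
    list(center_mm = as.numeric(center_mm), radii_mm = as.numeric(radii_mm),
         lesion_ff_mean = lesion_ff_mean, lesion_ff_sd = lesion_ff_sd,
         id = as.character(id)),
    class = "lesion_spec"
  )
}

#' Dixon phantom configuration
#'
#' Describes one synthetic subject: grid geometry, marrow fat-fraction
#' background, focal lesions, interface blur, voxel noise, the intensity
#' scale dialect used when FF maps are written to disk, and the seed.
#'
#' @param grid_shape Voxel counts per axis, length 3.
#' @param spacing_mm Voxel size per axis in mm, length 3, all positive.
#' @param marrow_ff_mean,marrow_ff_sd Marrow FF mean / voxelwise SD (percent).
#' @param lesions List of [lesion_spec()] objects.
#' @param interface_blur_mm Gaussian blur width (mm) applied to the
#'   lesion/marrow FF transition; 0 gives a sharp interface.
#' @param noise_sd Additive voxelwise FF noise SD (percent).
#' @param scale_dialect 100 or 1000: scale factor applied when FF maps are
#'   stored (per-cent vs per-mille map dialects found in the wild).
#' @param subject_id Subject label.
#' @param seed RNG seed for this subject's phantom.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape, spacing_mm,
                           marrow_ff_mean = 70, marrow_ff_sd = 0,
                           lesions = list(),
                           interface_blur_mm = 0, noise_sd = 0,
                           scale_dialect = 100, subject_id = "S1", seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            marrow_ff_mean >= 0, marrow_ff_mean <= 100, marrow_ff_sd >= 0,
            interface_blur_mm >= 0, noise_sd >= 0,
            scale_dialect %in% c(100, 1000))
  lesions <- lapply(lesions, function(l) {
    if (!inherits(l, "lesion_spec")) do.call(lesion_spec, l) else l
  })
  structure(
    list(grid_shape = as.integer(grid_shape),
         spacing_mm = as.numeric(spacing_mm),
         marrow_ff_mean = marrow_ff_mean, marrow_ff_sd = marrow_ff_sd,
         lesions = lesions, interface_blur_mm = interface_blur_mm,
         noise_sd = noise_sd, scale_dialect = scale_dialect,
         subject_id = as.character(subject_id), seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Simulated reader model
#'
#' Parameters governing how a simulated reader perturbs a ground-truth lesion
#' mask: a smooth random boundary displacement of magnitude
#' `boundary_sigma_mm`, a systematic over-/under-segmentation bias
#' `dilation_bias_mm` (positive dilates), and a probability
#' `slice_choice_jitter` of picking the second-largest slice when performing
#' single-slice measurements.
#'
#' @param reader_id Reader label.
#' @param boundary_sigma_mm SD of the random boundary displacement (mm).
#' @param dilation_bias_mm Systematic boundary offset (mm); positive values
#'   over-segment into the surrounding marrow.
#' @param slice_choice_jitter Probability in `[0, 1]` of choosing a
#'   near-maximal instead of the maximal-area slice.
#' @param field_scale_mm Correlation length (mm) of the smooth displacement
#'   field.
#' @param seed Reader-level RNG seed.
#' @return An object of class `reader_model`.
#' @export
reader_model <- function(reader_id, boundary_sigma_mm = 0.5,
                         dilation_bias_mm = 0, slice_choice_jitter = 0,
                         field_scale_mm = 3, seed = 1L) {
  stopifnot(boundary_sigma_mm >= 0, slice_choice_jitter >= 0,
            slice_choice_jitter <= 1, field_scale_mm > 0)
  structure(
    list(reader_id = as.character(reader_id),
         boundary_sigma_mm = boundary_sigma_mm,
         dilation_bias_mm = dilation_bias_mm,
         slice_choice_jitter = slice_choice_jitter,
         field_scale_mm = field_scale_mm, seed = as.integer(seed)),
    class = "reader_model"
  )
}

#' Variance components of a repeated-measurement model
#'
#' One-way random-effects decomposition `y_ij = mu + b_i + e_ij` with
#' `b_i ~ N(0, sigma_b^2)` (between-subject) and `e_ij ~ N(0, sigma_w^2)`
#' (within-subject error). The implied true reliability is
#' `ICC = sigma_b^2 / (sigma_b^2 + sigma_w^2)`.
#'
#' @param mu Population mean (percent).
#' @param sigma_b Between-subject SD.
#' @param sigma_w Within-subject SD.
#' @param k Observations per subject (>= 2).
#' @param n_subjects Number of subjects (>= 2).
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(mu, sigma_b, sigma_w, k = 2L,
                                n_subjects = 34L) {
  stopifnot(sigma_b >= 0, sigma_w >= 0, k >= 2, n_subjects >= 2,
            sigma_b + sigma_w > 0)
  structure(
    list(mu = mu, sigma_b = sigma_b, sigma_w = sigma_w, k = as.integer(k),
         n_subjects = as.integer(n_subjects)),
    class = "variance_components"
  )
}

#' True intraclass correlation implied by variance components
#'
#' @param vc A [variance_components()] object.
#' @return `sigma_b^2 / (sigma_b^2 + sigma_w^2)`.
#' @export
true_icc <- function(vc) {
  vc$sigma_b^2 / (vc$sigma_b^2 + vc$sigma_w^2)
}

#' Generate a synthetic Dixon phantom
#'
#' Builds paired fat-only and water-only volumes whose implied fat fraction
#' matches the configured field: high-FF marrow with ellipsoidal low-FF
#' lesions, an optional Gaussian-blurred interface, and additive voxel noise.
#' The fat/water decomposition uses a constant total signal `S` per voxel
#' (`fat = S f / 100`, `water = S (1 - f / 100)`), so the FF% formula recovers
#' the configured field exactly when noise and blur are zero. The generated
#' FF field is truncated to `[0, 100]` so that both channels stay
#' non-negative. One ground-truth mask (the unblurred ellipsoid interior) is
#' returned per lesion, with its size class.
#'
#' @param config A [phantom_config()].
#' @param total_signal Constant per-voxel total signal `S` (default 1000).
#' @return A list with elements `volume` (a [dixon_volume()]), `lesions`
#'   (list of ground-truth [lesion_roi()] masks) and `ff_true` (the generated
#'   FF field in percent, before fat/water decomposition).
#' @export
generate_dixon_phantom <- function(config, total_signal = 1000) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$grid_shape
  sp <- config$spacing_mm
  extent <- (dims - 1) * sp
  for (les in config$lesions) {
    if (any(les$center_mm - les$radii_mm < 0) ||
        any(les$center_mm + les$radii_mm > extent)) {
      stop(sprintf("lesion '%s' extends outside the grid", les$id))
    }
  }
  coords <- lapply(1:3, function(ax) (seq_len(dims[ax]) - 1) * sp[ax])

  with_seed(derive_seed(config$seed, config$subject_id, "phantom"), {
    ff <- array(config$marrow_ff_mean, dims)
    if (config$marrow_ff_sd > 0) {
      ff <- ff + array(rnorm(prod(dims), 0, config$marrow_ff_sd), dims)
    }
    truth <- vector("list", length(config$lesions))
    for (i in seq_along(config$lesions)) {
      les <- config$lesions[[i]]
      d2 <- outer(
        outer((coords[[1]] - les$center_mm[1])^2 / les$radii_mm[1]^2,
              (coords[[2]] - les$center_mm[2])^2 / les$radii_mm[2]^2, `+`),
        (coords[[3]] - les$center_mm[3])^2 / les$radii_mm[3]^2, `+`
      )
      inside <- d2 <= 1
      lesion_field <- array(les$lesion_ff_mean, dims)
      if (les$lesion_ff_sd > 0) {
        lesion_field <- lesion_field +
          array(rnorm(prod(dims), 0, les$lesion_ff_sd), dims)
      }
      w <- inside + 0
      if (config$interface_blur_mm > 0) {
        w <- smooth_gaussian(w, config$interface_blur_mm, sp)
        w <- pmin(1, pmax(0, w))
        w <- array(w, dims)
      }
      ff <- (1 - w) * ff + w * lesion_field
      truth[[i]] <- lesion_roi(inside, sp, config$subject_id, les$id)
    }
    if (config$noise_sd > 0) {
      ff <- ff + array(rnorm(prod(dims), 0, config$noise_sd), dims)
    }
    ff <- array(pmin(100, pmax(0, ff)), dims)
    fat <- total_signal * ff / 100
    water <- total_signal - fat
    list(
      volume = dixon_volume(fat, water, sp,
                            scale_dialect = config$scale_dialect),
      lesions = truth,
      ff_true = ff
    )
  })
}

#' Simulate a reader's manual segmentation of a lesion
#'
#' Perturbs a ground-truth mask the way an independent human reader would:
#' the mask's signed distance function is shifted by a smooth Gaussian random
#' displacement field (SD `boundary_sigma_mm`, correlation length
#' `field_scale_mm`) plus the reader's systematic `dilation_bias_mm`, and
#' re-thresholded. The result is restricted to its largest connected
#' component. With all perturbation parameters zero the output equals the
#' input. A perturbation that would empty the mask falls back to the
#' unperturbed truth with a warning.
#'
#' @param truth Ground-truth [lesion_roi()].
#' @param model A [reader_model()].
#' @param repeat_index Repeat index for this segmentation (1 or 2).
#' @return A [lesion_roi()] tagged with the reader id and repeat index.
#' @export
simulate_reader_segmentation <- function(truth, model, repeat_index = 1L) {
  stopifnot(inherits(truth, "lesion_roi"), inherits(model, "reader_model"))
  out <- truth
  out$reader_id <- model$reader_id
  out$repeat_index <- as.integer(repeat_index)
  if (model$boundary_sigma_mm == 0 && model$dilation_bias_mm == 0) {
    return(out)
  }

  dims <- dim(truth$mask)
  sp <- truth$spacing_mm
  margin_mm <- abs(model$dilation_bias_mm) + 4 * model$boundary_sigma_mm +
    3 * model$field_scale_mm
  margin <- pmax(2L, as.integer(ceiling(margin_mm / sp)))
  idx <- which(truth$mask, arr.ind = TRUE)
  lo <- pmax(1L, apply(idx, 2, min) - margin)
  hi <- pmin(dims, apply(idx, 2, max) + margin)
  crop <- truth$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cdims <- dim(crop)

  sdf <- signed_distance(crop, sp)
  field <- 0
  if (model$boundary_sigma_mm > 0) {
    seed <- derive_seed(model$seed, truth$subject_id, truth$lesion_id,
                        model$reader_id, repeat_index, "boundary")
    field <- with_seed(seed, array(rnorm(prod(cdims)), cdims))
    field <- smooth_gaussian(field, model$field_scale_mm, sp)
    fsd <- sd(field)
    if (fsd > 0) field <- field / fsd * model$boundary_sigma_mm
  }
  new_crop <- sdf < model$dilation_bias_mm + field
  if (!any(new_crop)) {
    warning(sprintf(
      "perturbation emptied mask for subject %s lesion %s (%s rep %d); using truth",
      truth$subject_id, truth$lesion_id, model$reader_id, repeat_index
    ))
    return(out)
  }
  new_crop <- largest_component(new_crop)
  mask <- array(FALSE, dims)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- new_crop
  out$mask <- mask
  out
}

#' Simulate a long-format measurement table from variance components
#'
#' Draws `y_ij = mu + b_i + e_ij` for `n_subjects` subjects with `k`
#' observations each, the exact generating model assumed by the one-way
#' single-measure ICC, so agreement statistics can be validated against a
#' known true reliability ([true_icc()]).
#'
#' @param vc A [variance_components()] object.
#' @param seed RNG seed.
#' @param size_class,mode Labels copied into the table (the simulator is
#'   measurement-mode agnostic).
#' @param reader_id Reader label; the `k` observations are tagged as repeats
#'   1..k of this reader.
#' @return A data.frame with columns `subject_id`, `lesion_id`, `size_class`,
#'   `reader_id`, `repeat`, `mode`, `value`.
#' @export
simulate_measurement_table <- function(vc, seed = 1L, size_class = "large",
                                       mode = "volume", reader_id = "R1") {
  stopifnot(inherits(vc, "variance_components"))
  n <- vc$n_subjects
  k <- vc$k
  with_seed(derive_seed(seed, "measurement_table"), {
    b <- rnorm(n, 0, vc$sigma_b)
    e <- matrix(rnorm(n * k, 0, vc$sigma_w), n, k)
    y <- vc$mu + b + e
    ids <- sprintf("S%03d", seq_len(n))
    df <- data.frame(
      subject_id = rep(ids, each = k),
      lesion_id = rep(ids, each = k),
      size_class = size_class,
      reader_id = reader_id,
      rep = rep(seq_len(k), n),
      mode = mode,
      value = as.vector(t(y)),
      stringsAsFactors = FALSE
    )
    names(df)[names(df) == "rep"] <- "repeat"
    df
  })
}
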