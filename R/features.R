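# ROI preprocessing and first-order histogram features, computed from the
# standard first-order definitions (IBSI-consistent): resample to a coarse
# isotropic grid, normalize intensities to percent, pool the masked voxels,
# drop outliers beyond 3 SD, then summarize the intensity histogram.

#' Preprocess an ROI into a voxel sample
#'
#' Fixed processing chain applied before any feature computation:
#' 1. the FF map is resampled to `target_spacing_mm` by trilinear
#'    interpolation and the mask by nearest-neighbour;
#' 2. intensities are normalized to percent ([normalize_ff_scale()]);
#' 3. valid masked voxels are pooled into one sample;
#' 4. a single pass removes voxels more than `outlier_sd` standard deviations
#'    (sample SD, `n - 1`) from the sample mean. When the SD is zero the
#'    removal step is skipped.
#'
#' @param ff An [ff_map()].
#' @param roi A [lesion_roi()] on the same grid as `ff`.
#' @param target_spacing_mm Resampling target (mm), default 3 mm isotropic.
#' @param outlier_sd Outlier cut in SD units (default 3).
#' @return An object of class `voxel_sample`: list with `values` (percent),
#'   `n_raw`, `n_removed`, `mode`, and `voxel_volume_mm3` at the target
#'   spacing.
#' @export
preprocess_roi <- function(ff, roi, target_spacing_mm = c(3, 3, 3),
                           outlier_sd = 3) {
  stopifnot(inherits(ff, "ff_map"), inherits(roi, "lesion_roi"),
            length(target_spacing_mm) == 3L, all(target_spacing_mm > 0),
            outlier_sd > 0)
  if (any(abs(ff$spacing_mm - roi$spacing_mm) > 1e-6) ||
      !identical(dim(ff$values), dim(roi$mask))) {
    stop("FF map and ROI must share grid and spacing")
  }
  ff <- normalize_ff_scale(ff, declared_dialect = 100)
  vals <- resample_volume(ff$values, ff$spacing_mm, target_spacing_mm,
                          method = "linear")
  mask <- resample_volume(roi$mask + 0L, roi$spacing_mm, target_spacing_mm,
                          method = "nearest") > 0.5
  sample_vals <- vals[mask]
  sample_vals <- sample_vals[!is.na(sample_vals)]
  n_raw <- length(sample_vals)
  if (n_raw == 0L) {
    stop(paste0(
      "ROI empty after resampling; the lesion is too small for this target ",
      "spacing (likely ineligible for volumetric measurement)"
    ))
  }
  s <- if (n_raw >= 2L) sd(sample_vals) else 0
  if (is.finite(s) && s > 0) {
    m <- mean(sample_vals)
    keep <- abs(sample_vals - m) <= outlier_sd * s
    sample_vals <- sample_vals[keep]
  }
  structure(
    list(values = sample_vals, n_raw = n_raw,
         n_removed = n_raw - length(sample_vals), mode = roi$mode,
         voxel_volume_mm3 = prod(target_spacing_mm)),
    class = "voxel_sample"
  )
}

as_voxel_sample <- function(x, voxel_volume_mm3 = 27, mode = "volume") {
  if (inherits(x, "voxel_sample")) return(x)
  x <- as.numeric(x)
  stopifnot(length(x) >= 1L, all(is.finite(x)))
  structure(
    list(values = x, n_raw = length(x), n_removed = 0L, mode = mode,
         voxel_volume_mm3 = voxel_volume_mm3),
    class = "voxel_sample"
  )
}

#' Discretize a voxel sample into a fixed-bin histogram
#'
#' 64 (by default) equal-width bins spanning `[min, max]` of the sample; a
#' constant sample puts all mass in a single bin. Probabilities sum to 1.
#'
#' @param sample A `voxel_sample` or numeric vector.
#' @param bin_count Number of bins (default 64).
#' @return List with `probabilities` (length `bin_count`), `counts`, and
#'   `breaks`.
#' @export
discretize <- function(sample, bin_count = 64L) {
  sample <- as_voxel_sample(sample)
  v <- sample$values
  stopifnot(length(v) >= 1L, bin_count >= 1L)
  mn <- min(v)
  mx <- max(v)
  counts <- integer(bin_count)
  if (mx == mn) {
    counts[1L] <- length(v)
    breaks <- rep(mn, bin_count + 1L)
  } else {
    width <- (mx - mn) / bin_count
    idx <- pmin(bin_count, as.integer(floor((v - mn) / width)) + 1L)
    counts <- tabulate(idx, nbins = bin_count)
    breaks <- mn + (0:bin_count) * width
  }
  list(probabilities = counts / length(v), counts = counts, breaks = breaks)
}

#' First-order features of a voxel sample
#'
#' Standard first-order intensity statistics of the pooled ROI sample.
#' Percentiles use linear interpolation between closest ranks
#' ([quantile()] type 7). Variance, skewness and kurtosis use population
#' (`n`) normalization and kurtosis is non-excess (Normal -> 3); skewness and
#' kurtosis are `NA` for samples smaller than 3 or with zero variance.
#' Entropy (bits) and uniformity come from the [discretize()] histogram;
#' total energy is energy times the voxel volume.
#'
#' @param sample A `voxel_sample` (or numeric vector, assumed preprocessed).
#' @param bin_count Histogram bins for entropy/uniformity (default 64).
#' @return A one-row data.frame with columns `mean`, `median`, `p10`, `p90`,
#'   `minimum`, `maximum`, `root_mean_squared`, `variance`, `skewness`,
#'   `kurtosis`, `range`, `interquartile_range`, `mean_absolute_deviation`,
#'   `robust_mean_absolute_deviation`, `energy`, `total_energy`, `entropy`,
#'   `uniformity`.
#' @export
first_order_features <- function(sample, bin_count = 64L) {
  sample <- as_voxel_sample(sample)
  v <- sample$values
  n <- length(v)
  stopifnot(n >= 1L)
  m <- mean(v)
  qs <- quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  m2 <- mean((v - m)^2)
  if (n >= 3L && m2 > 0) {
    skewness <- mean((v - m)^3) / m2^1.5
    kurtosis <- mean((v - m)^4) / m2^2
  } else {
    skewness <- NA_real_
    kurtosis <- NA_real_
  }
  in_band <- v >= qs[1] & v <= qs[5]
  rmad <- if (any(in_band)) {
    vb <- v[in_band]
    mean(abs(vb - mean(vb)))
  } else {
    NA_real_
  }
  h <- discretize(sample, bin_count)
  p <- h$probabilities[h$probabilities > 0]
  energy <- sum(v^2)
  data.frame(
    mean = m,
    median = qs[3],
    p10 = qs[1],
    p90 = qs[5],
    minimum = min(v),
    maximum = max(v),
    root_mean_squared = sqrt(mean(v^2)),
    variance = m2,
    skewness = skewness,
    kurtosis = kurtosis,
    range = max(v) - min(v),
    interquartile_range = qs[4] - qs[2],
    mean_absolute_deviation = mean(abs(v - m)),
    robust_mean_absolute_deviation = rmad,
    energy = energy,
    total_energy = energy * sample$voxel_volume_mm3,
    entropy = -sum(p * log2(p)),
    uniformity = sum(h$probabilities^2)
  )
}

#' Mean FF% of a lesion in slice or volume mode
#'
#' The scalar feeding all FF% agreement analyses: the mean of the
#' preprocessed voxel sample, either over the whole lesion (`"volume"`) or
#' over its representative axial slice (`"slice"`). Volumetric measurement
#' requires the mask to span at least two axial slices
#' ([eligible_for_volumetric()]).
#'
#' @inheritParams preprocess_roi
#' @param mode `"volume"` or `"slice"`.
#' @param slice_index For slice mode, the slice to use; defaults to the
#'   representative slice.
#' @return Mean FF in percent.
#' @export
measure_mean_ff <- function(ff, roi, mode = c("volume", "slice"),
                            target_spacing_mm = c(3, 3, 3), outlier_sd = 3,
                            slice_index = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(roi, "lesion_roi"))
  if (mode == "volume") {
    if (!eligible_for_volumetric(roi)) {
      stop("lesion spans a single slice: ineligible for volumetric measurement")
    }
    roi$mode <- "volume"
  } else {
    n_slices <- sum(apply(roi$mask, roi$axial_axis, any))
    if (n_slices > 1L || roi$mode != "slice") {
      roi <- single_slice_mask(roi, slice_index)
    }
  }
  mean(preprocess_roi(ff, roi, target_spacing_mm, outlier_sd)$values)
}

#' Extract a feature table from a set of ROIs
#'
#' Runs the preprocessing chain and [first_order_features()] for each ROI and
#' binds the results with bookkeeping columns, one row per
#' (subject, lesion, reader, repeat, mode).
#'
#' @inheritParams preprocess_roi
#' @param rois List of [lesion_roi()] objects.
#' @param bin_count Histogram bins (default 64).
#' @return A data.frame of bookkeeping + feature columns, including `n_raw`
#'   and `n_removed`.
#' @export
extract_features_table <- function(ff, rois, target_spacing_mm = c(3, 3, 3),
                                   outlier_sd = 3, bin_count = 64L) {
  rows <- lapply(rois, function(roi) {
    s <- preprocess_roi(ff, roi, target_spacing_mm, outlier_sd)
    cbind(
      data.frame(subject_id = roi$subject_id, lesion_id = roi$lesion_id,
                 size_class = roi$size_class, reader_id = roi$reader_id,
                 rep = roi$repeat_index, mode = roi$mode,
                 n_raw = s$n_raw, n_removed = s$n_removed,
                 stringsAsFactors = FALSE),
      first_order_features(s, bin_count)
    )
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "rep"] <- "repeat"
  rownames(out) <- NULL
  out
}
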