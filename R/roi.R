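# Lesion ROI bookkeeping: the container, the axial-diameter size rule, the
# representative-slice rule for single-slice measurements, and the
# volumetric-eligibility filter. By convention the axial (slice) axis is the
# third array axis; sizes are physical (mm), computed from voxel spacing.

#' Lesion region of interest
#'
#' A binary voxel mask tagged with the study bookkeeping needed by the
#' agreement analyses: subject, lesion, reader, repeat index, measurement
#' mode, and the lesion size class.
#'
#' @param mask Logical (or 0/1) 3-D array; must contain at least one voxel.
#' @param spacing_mm Numeric length-3 voxel size in mm.
#' @param subject_id,lesion_id Labels.
#' @param reader_id Reader label (`NA` for ground-truth masks).
#' @param repeat_index Repeat index (1 or 2).
#' @param size_class `"small"` or `"large"`; computed with
#'   [classify_lesion_size()] when `NULL`.
#' @param mode `"volume"` or `"slice"`.
#' @param axial_axis Index of the slice axis (default 3).
#' @return An object of class `lesion_roi`.
#' @export
lesion_roi <- function(mask, spacing_mm, subject_id, lesion_id,
                       reader_id = NA_character_, repeat_index = 1L,
                       size_class = NULL, mode = "volume", axial_axis = 3L) {
  mask <- array(as.logical(mask), dim(mask))
  stopifnot(length(dim(mask)) == 3L, length(spacing_mm) == 3L,
            all(spacing_mm > 0))
  if (!any(mask)) stop("lesion mask is empty")
  if (is.null(size_class)) {
    size_class <- classify_lesion_size(mask, spacing_mm, axial_axis)
  }
  size_class <- match.arg(size_class, c("small", "large"))
  mode <- match.arg(mode, c("volume", "slice"))
  structure(
    list(mask = mask, spacing_mm = as.numeric(spacing_mm),
         subject_id = as.character(subject_id),
         lesion_id = as.character(lesion_id),
         reader_id = as.character(reader_id),
         repeat_index = as.integer(repeat_index),
         size_class = size_class, mode = mode,
         axial_axis = as.integer(axial_axis)),
    class = "lesion_roi"
  )
}

#' @export
print.lesion_roi <- function(x, ...) {
  cat(sprintf(
    "<lesion_roi> subject %s lesion %s reader %s repeat %d [%s, %s]: %d voxels\n",
    x$subject_id, x$lesion_id, x$reader_id, x$repeat_index,
    x$size_class, x$mode, sum(x$mask)
  ))
  invisible(x)
}

roi_parts <- function(mask, spacing_mm, axial_axis) {
  if (inherits(mask, "lesion_roi")) {
    list(mask = mask$mask, spacing_mm = mask$spacing_mm,
         axial_axis = mask$axial_axis)
  } else {
    list(mask = array(as.logical(mask), dim(mask)),
         spacing_mm = spacing_mm, axial_axis = axial_axis)
  }
}

#' Maximum in-plane (axial) lesion diameter
#'
#' Largest pairwise distance, in mm, between the centers of masked voxels
#' lying on the same axial slice, maximized over slices. This is the caliper
#' ("Feret") diameter a radiologist would measure on the axial plane; a
#' single-voxel mask has diameter 0.
#'
#' @inheritParams lesion_roi
#' @param mask A `lesion_roi` or a logical 3-D array.
#' @return Diameter in mm.
#' @export
axial_diameter <- function(mask, spacing_mm = NULL, axial_axis = 3L) {
  p <- roi_parts(mask, spacing_mm, axial_axis)
  if (!any(p$mask)) stop("lesion mask is empty")
  in_plane <- setdiff(1:3, p$axial_axis)
  idx <- which(p$mask, arr.ind = TRUE)
  best <- 0
  for (s in unique(idx[, p$axial_axis])) {
    pts <- idx[idx[, p$axial_axis] == s, in_plane, drop = FALSE]
    if (nrow(pts) < 2L) next
    xy <- sweep(pts - 1, 2, p$spacing_mm[in_plane], `*`)
    if (nrow(xy) > 3L) {
      hull <- grDevices::chull(xy)
      xy <- xy[hull, , drop = FALSE]
    }
    best <- max(best, max(stats::dist(xy)))
  }
  best
}

#' Classify a lesion as small or large by axial diameter
#'
#' Lesions below 10 mm maximum axial diameter are `"small"`; lesions at or
#' above 10 mm are `"large"`.
#'
#' @inheritParams axial_diameter
#' @param threshold_mm Size cut-point in mm (default 10).
#' @return `"small"` or `"large"`.
#' @export
classify_lesion_size <- function(mask, spacing_mm = NULL, axial_axis = 3L,
                                 threshold_mm = 10) {
  d <- axial_diameter(mask, spacing_mm, axial_axis)
  if (d < threshold_mm) "small" else "large"
}

#' Representative axial slice of a lesion
#'
#' Returns the index of the axial slice with the largest masked
#' cross-sectional area (voxel count times in-plane voxel area). Ties are
#' broken deterministically toward the lowest slice index.
#'
#' @inheritParams axial_diameter
#' @return Integer slice index along the axial axis.
#' @export
select_representative_slice <- function(mask, spacing_mm = NULL,
                                        axial_axis = 3L) {
  p <- roi_parts(mask, spacing_mm, axial_axis)
  if (!any(p$mask)) stop("lesion mask is empty")
  counts <- apply(p$mask, p$axial_axis, sum)
  which.max(counts)
}

#' Restrict a lesion ROI to a single axial slice
#'
#' Zeroes every slice except `slice_index`, preserving all metadata and
#' tagging the result as a single-slice (`mode = "slice"`) measurement mask.
#'
#' @param roi A `lesion_roi`.
#' @param slice_index Axial slice to keep; defaults to the representative
#'   slice from [select_representative_slice()].
#' @return A `lesion_roi` with `mode = "slice"`.
#' @export
single_slice_mask <- function(roi, slice_index = NULL) {
  stopifnot(inherits(roi, "lesion_roi"))
  if (is.null(slice_index)) {
    slice_index <- select_representative_slice(roi)
  }
  keep <- array(FALSE, dim(roi$mask))
  ind <- slice.index(roi$mask, roi$axial_axis) == slice_index
  keep[ind] <- roi$mask[ind]
  if (!any(keep)) stop("selected slice contains no masked voxels")
  out <- roi
  out$mask <- keep
  out$mode <- "slice"
  out
}

#' Is a lesion eligible for volumetric measurement?
#'
#' Lesions segmented on a single axial slice only are excluded from
#' volumetric measurements; a mask is eligible iff it spans at least two
#' axial slices.
#'
#' @inheritParams axial_diameter
#' @return `TRUE` or `FALSE`.
#' @export
eligible_for_volumetric <- function(mask, spacing_mm = NULL, axial_axis = 3L) {
  p <- roi_parts(mask, spacing_mm, axial_axis)
  if (!any(p$mask)) stop("lesion mask is empty")
  sum(apply(p$mask, p$axial_axis, any)) >= 2L
}

# Representative-slice choice as performed by a simulated reader: with
# probability `jitter` the reader picks the second-largest slice (when one
# exists) instead of the largest, emulating blinded independent slice choice.
select_reader_slice <- function(roi, jitter, seed) {
  counts <- apply(roi$mask, roi$axial_axis, sum)
  best <- which.max(counts)
  if (jitter <= 0 || sum(counts > 0) < 2L) return(best)
  pick_alt <- with_seed(seed, stats::runif(1)) < jitter
  if (!pick_alt) return(best)
  counts2 <- counts
  counts2[best] <- -1L
  second <- which.max(counts2)
  if (counts2[second] <= 0L) best else second
}
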