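# Fat-fraction maps from Dixon fat-only / water-only volumes:
# FF% = 100 * FO / (FO + WO), plus normalization of the two map-scale
# dialects found in clinical exports (per-cent, factor 100, and per-mille,
# factor 1000).

#' Paired Dixon fat-only / water-only volumes
#'
#' @param fat_only,water_only Non-negative numeric 3-D arrays of identical
#'   shape.
#' @param spacing_mm Voxel size per axis in mm.
#' @param scale_dialect 100, 1000, or `NULL` when unknown; the scale factor
#'   used when FF maps derived from this volume are stored.
#' @return An object of class `dixon_volume`.
#' @export
dixon_volume <- function(fat_only, water_only, spacing_mm,
                         scale_dialect = NULL) {
  stopifnot(identical(dim(fat_only), dim(water_only)),
            length(dim(fat_only)) == 3L,
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  if (!is.null(scale_dialect)) stopifnot(scale_dialect %in% c(100, 1000))
  structure(
    list(fat_only = fat_only, water_only = water_only,
         spacing_mm = as.numeric(spacing_mm), scale_dialect = scale_dialect),
    class = "dixon_volume"
  )
}

#' Fat-fraction map
#'
#' Voxelwise fat fraction in percent with an explicit validity mask: voxels
#' where the total Dixon signal is zero carry no FF information and are
#' flagged invalid (`NA` value), never silently zeroed.
#'
#' @param values Numeric 3-D array of FF in percent (`NA` where invalid).
#' @param spacing_mm Voxel size per axis in mm.
#' @param valid_mask Logical array marking voxels with usable FF values;
#'   derived from `!is.na(values)` when omitted.
#' @return An object of class `ff_map`.
#' @export
ff_map <- function(values, spacing_mm, valid_mask = NULL) {
  stopifnot(length(dim(values)) == 3L, length(spacing_mm) == 3L,
            all(spacing_mm > 0))
  if (is.null(valid_mask)) valid_mask <- !is.na(values)
  stopifnot(identical(dim(values), dim(valid_mask)))
  structure(
    list(values = values, spacing_mm = as.numeric(spacing_mm),
         valid_mask = valid_mask),
    class = "ff_map"
  )
}

#' Compute a fat-fraction map from a Dixon volume
#'
#' Applies `FF% = 100 * FO / (FO + WO)` voxelwise. Voxels with `FO + WO = 0`
#' are flagged invalid. Output is always in percent regardless of the
#' volume's storage dialect.
#'
#' @param vol A [dixon_volume()].
#' @return An [ff_map()] with spacing copied from the input.
#' @export
compute_ff_map <- function(vol) {
  stopifnot(inherits(vol, "dixon_volume"))
  if (any(vol$fat_only < 0, na.rm = TRUE) ||
      any(vol$water_only < 0, na.rm = TRUE)) {
    stop("negative Dixon intensities: corrupt fat/water decomposition")
  }
  tot <- vol$fat_only + vol$water_only
  valid <- tot > 0
  values <- array(NA_real_, dim(tot))
  values[valid] <- 100 * vol$fat_only[valid] / tot[valid]
  ff_map(values, vol$spacing_mm, valid)
}

#' Normalize a stored FF map to percent scale
#'
#' Clinical FF maps come in two dialects: values scaled by 100 (percent) or
#' by 1000 (per-mille). With `declared_dialect` given, values are divided by
#' `dialect / 100`. When the dialect is unknown it is inferred per volume: if
#' the 99.9th percentile of valid values exceeds 110 the map is treated as
#' per-mille and divided by 10, otherwise it is already percent. The
#' inference decision is reported via [message()]. Values still exceeding the
#' percent range by more than 10% after inference raise an error
#' (unrecognized scale). An already-percent map is returned unchanged
#' (idempotence).
#'
#' @param x An [ff_map()] or a bare numeric array of stored FF values.
#' @param declared_dialect 100, 1000, or `NULL` to infer.
#' @return Same type as `x`, with values in percent.
#' @export
normalize_ff_scale <- function(x, declared_dialect = NULL) {
  is_map <- inherits(x, "ff_map")
  vals <- if (is_map) x$values else x
  if (any(vals < 0, na.rm = TRUE)) {
    stop("FF values must be non-negative")
  }
  if (!is.null(declared_dialect)) {
    stopifnot(declared_dialect %in% c(100, 1000))
    out <- vals / (declared_dialect / 100)
  } else {
    q <- quantile(vals[!is.na(vals)], 0.999, names = FALSE, type = 7)
    if (is.na(q)) {
      out <- vals
    } else if (q > 110) {
      message("normalize_ff_scale: inferred per-mille dialect (divided by 10)")
      out <- vals / 10
      q2 <- quantile(out[!is.na(out)], 0.999, names = FALSE, type = 7)
      if (q2 > 110) stop("unrecognized FF scale: values exceed 1100")
    } else {
      out <- vals
    }
  }
  if (is_map) {
    x$values <- out
    x
  } else {
    out
  }
}

# --- NIfTI I/O ------------------------------------------------------------

nifti_spacing <- function(img) {
  as.numeric(RNifti::pixdim(img))[1:3]
}

#' Read a Dixon volume from paired NIfTI files
#'
#' Spacing is taken from the NIfTI headers; a mismatch between the fat and
#' water headers beyond 1e-3 mm is an error.
#'
#' @param fat_path,water_path Paths to the fat-only and water-only NIfTI
#'   volumes.
#' @param scale_dialect Declared dialect of FF maps associated with this
#'   acquisition, or `NULL`.
#' @return A [dixon_volume()].
#' @export
read_dixon_volume <- function(fat_path, water_path, scale_dialect = NULL) {
  fat <- RNifti::readNifti(fat_path)
  water <- RNifti::readNifti(water_path)
  sf <- nifti_spacing(fat)
  sw <- nifti_spacing(water)
  if (any(abs(sf - sw) > 1e-3)) {
    stop("fat/water voxel spacing mismatch exceeds 1e-3 mm")
  }
  dixon_volume(array(as.numeric(fat), dim(fat)[1:3]),
               array(as.numeric(water), dim(water)[1:3]),
               sf, scale_dialect)
}

write_nifti_volume <- function(a, spacing_mm, path, datatype = "float") {
  img <- RNifti::asNifti(array(as.numeric(a), dim(a)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a Dixon volume as paired NIfTI files
#'
#' @param vol A [dixon_volume()].
#' @param fat_path,water_path Output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_dixon_volume <- function(vol, fat_path, water_path) {
  stopifnot(inherits(vol, "dixon_volume"))
  write_nifti_volume(vol$fat_only, vol$spacing_mm, fat_path)
  write_nifti_volume(vol$water_only, vol$spacing_mm, water_path)
  invisible(c(fat_path, water_path))
}

#' Write an FF map as NIfTI
#'
#' Values are stored multiplied by `dialect / 100`; invalid voxels are
#' written as `NaN`.
#'
#' @param map An [ff_map()].
#' @param path Output path.
#' @param dialect Storage dialect, 100 (percent, default) or 1000.
#' @return Invisibly, the path.
#' @export
write_ff_map <- function(map, path, dialect = 100) {
  stopifnot(inherits(map, "ff_map"), dialect %in% c(100, 1000))
  vals <- map$values * (dialect / 100)
  vals[!map$valid_mask] <- NaN
  write_nifti_volume(vals, map$spacing_mm, path)
}

#' Read a stored FF map from NIfTI and normalize it to percent
#'
#' @param path NIfTI path.
#' @param declared_dialect 100, 1000, or `NULL` to infer
#'   (see [normalize_ff_scale()]).
#' @return An [ff_map()] in percent.
#' @export
read_ff_map <- function(path, declared_dialect = NULL) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img)[1:3])
  vals[!is.finite(vals)] <- NA_real_
  vals <- normalize_ff_scale(vals, declared_dialect)
  ff_map(vals, nifti_spacing(img))
}

#' Write a lesion mask as NIfTI
#'
#' @param roi A [lesion_roi()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_lesion_mask <- function(roi, path) {
  stopifnot(inherits(roi, "lesion_roi"))
  write_nifti_volume(roi$mask + 0L, roi$spacing_mm, path, datatype = "uint8")
}
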