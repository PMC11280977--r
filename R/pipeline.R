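# End-to-end simulated reader study: for each synthetic subject, generate a
# Dixon phantom with one small and one large focal lesion, segment each
# lesion three times (reader 1 twice, reader 2 once), measure mean FF% in
# single-slice and volumetric mode, extract first-order features from the
# volumetric masks, and collect everything into the long-format measurement
# table consumed by run_agreement_study().

#' Default simulated reader models
#'
#' Two readers emulating the study design: reader 1 (two repeats) with purely
#' random boundary variability, and reader 2 with the same random variability
#' plus a systematic over-segmentation bias, so that inter-reader agreement
#' is lower than intra-reader agreement. Both readers occasionally pick a
#' near-maximal slice for single-slice measurements.
#'
#' @param seed Global seed; reader-level seeds are derived from it.
#' @param boundary_sigma_mm Random boundary displacement SD (mm).
#' @param reader2_bias_mm Reader 2's systematic boundary offset (mm).
#' @param slice_choice_jitter Probability of picking the second-largest
#'   slice.
#' @return Named list of two [reader_model()] objects (`R1`, `R2`).
#' @export
default_reader_models <- function(seed = 1L, boundary_sigma_mm = 1,
                                  reader2_bias_mm = 0.9,
                                  slice_choice_jitter = 0.15) {
  list(
    R1 = reader_model("R1", boundary_sigma_mm = boundary_sigma_mm,
                      dilation_bias_mm = 0,
                      slice_choice_jitter = slice_choice_jitter,
                      seed = derive_seed(seed, "reader", "R1")),
    R2 = reader_model("R2", boundary_sigma_mm = boundary_sigma_mm,
                      dilation_bias_mm = reader2_bias_mm,
                      slice_choice_jitter = slice_choice_jitter,
                      seed = derive_seed(seed, "reader", "R2"))
  )
}

# Draw one subject's phantom configuration: a small (< 10 mm axial diameter)
# and a large (>= 10 mm) ellipsoidal lesion with subject-specific FF.
subject_phantom_config <- function(subject_id, seed, grid_shape, spacing_mm,
                                   marrow_ff_mean, marrow_ff_sd,
                                   interface_blur_mm, noise_sd,
                                   lesion_ff_mean, lesion_ff_sd_between,
                                   lesion_ff_sd_voxel, scale_dialect) {
  with_seed(derive_seed(seed, subject_id, "design"), {
    mu <- min(40, max(4, rnorm(1, lesion_ff_mean, lesion_ff_sd_between)))
    ff_small <- min(45, max(2, mu + rnorm(1, 0, 1)))
    ff_large <- min(45, max(2, mu + rnorm(1, 0, 1)))
    extent <- (grid_shape - 1) * spacing_mm
    z_small <- stats::runif(1, 20, extent[3] - 20)
    z_large <- stats::runif(1, 20, extent[3] - 20)
    small <- lesion_spec(
      center_mm = c(12, extent[2] / 2, z_small),
      radii_mm = c(stats::runif(1, 2.6, 4.4), stats::runif(1, 2.6, 4.4),
                   stats::runif(1, 1.6, 4.6)),
      lesion_ff_mean = ff_small, lesion_ff_sd = lesion_ff_sd_voxel,
      id = "SAL"
    )
    large <- lesion_spec(
      center_mm = c(extent[1] - 12, extent[2] / 2, z_large),
      radii_mm = c(stats::runif(1, 6.5, 9), stats::runif(1, 6.5, 9),
                   stats::runif(1, 5, 8)),
      lesion_ff_mean = ff_large, lesion_ff_sd = lesion_ff_sd_voxel,
      id = "LAL"
    )
    phantom_config(
      grid_shape = grid_shape, spacing_mm = spacing_mm,
      marrow_ff_mean = marrow_ff_mean, marrow_ff_sd = marrow_ff_sd,
      lesions = list(small, large), interface_blur_mm = interface_blur_mm,
      noise_sd = noise_sd, scale_dialect = scale_dialect,
      subject_id = subject_id, seed = derive_seed(seed, subject_id, "phantom")
    )
  })
}

#' Simulate a full FF% reader study
#'
#' Generates `n_subjects` synthetic Dixon phantoms, each carrying one small
#' (< 10 mm axial diameter) and one large (>= 10 mm) low-FF lesion in high-FF
#' marrow; segments every lesion three times (reader 1 repeats 1 and 2,
#' reader 2 once); computes the FF% map; and measures mean FF% in
#' single-slice and volumetric mode for each segmentation. Lesions for which
#' any segmentation spans a single axial slice are excluded from volumetric
#' measurements (and from feature extraction), mirroring routine practice
#' with sub-centimetre lesions. First-order features are extracted from the
#' volumetric segmentations.
#'
#' @param n_subjects Number of synthetic subjects (default 34).
#' @param seed Global seed; all phantom, design and reader seeds derive from
#'   it, so a fixed seed reproduces the study bit-for-bit.
#' @param readers Named list of two [reader_model()] objects; defaults to
#'   [default_reader_models()].
#' @param grid_shape,spacing_mm Phantom grid (default 44 x 44 x 20 voxels at
#'   1 x 1 x 3 mm, a cropped field of view around the two index lesions).
#' @param marrow_ff_mean,marrow_ff_sd Marrow FF distribution (percent).
#' @param interface_blur_mm Lesion/marrow interface blur (mm).
#' @param noise_sd Additive voxel FF noise (percent).
#' @param lesion_ff_mean,lesion_ff_sd_between Population mean and
#'   between-subject SD of lesion FF (percent).
#' @param lesion_ff_sd_voxel Voxelwise FF heterogeneity inside lesions.
#' @param target_spacing_mm Feature/measurement resampling target.
#' @param extract_features Compute first-order feature tables (default TRUE).
#' @param scale_dialect Stored-map dialect for the generated volumes.
#' @param verbose Log exclusions with [message()].
#' @return An object of class `ff_study`: list with `measurements` (long
#'   measurement table), `features` (feature table or NULL), `lesion_summary`
#'   (per-lesion diameter, slice span, eligibility), `readers`, and the
#'   generation parameters.
#' @export
simulate_ff_study <- function(n_subjects = 34L, seed = 1L, readers = NULL,
                              grid_shape = c(44L, 44L, 20L),
                              spacing_mm = c(1, 1, 3),
                              marrow_ff_mean = 70, marrow_ff_sd = 5,
                              interface_blur_mm = 1, noise_sd = 2,
                              lesion_ff_mean = 16, lesion_ff_sd_between = 5,
                              lesion_ff_sd_voxel = 2,
                              target_spacing_mm = c(3, 3, 3),
                              extract_features = TRUE,
                              scale_dialect = 100, verbose = FALSE) {
  stopifnot(n_subjects >= 2L)
  if (is.null(readers)) readers <- default_reader_models(seed)
  stopifnot(length(readers) == 2L)
  log_msg <- function(...) if (verbose) message(sprintf(...))

  seg_plan <- list(
    list(reader = readers[[1]], rep = 1L),
    list(reader = readers[[1]], rep = 2L),
    list(reader = readers[[2]], rep = 1L)
  )

  meas_rows <- list()
  feat_rows <- list()
  lesion_rows <- list()

  for (s in seq_len(n_subjects)) {
    subject_id <- sprintf("S%03d", s)
    config <- subject_phantom_config(
      subject_id, seed, grid_shape, spacing_mm, marrow_ff_mean, marrow_ff_sd,
      interface_blur_mm, noise_sd, lesion_ff_mean, lesion_ff_sd_between,
      lesion_ff_sd_voxel, scale_dialect
    )
    phantom <- generate_dixon_phantom(config)
    ff <- compute_ff_map(phantom$volume)

    for (truth in phantom$lesions) {
      segs <- lapply(seg_plan, function(p) {
        simulate_reader_segmentation(truth, p$reader, p$rep)
      })
      eligible <- all(vapply(segs, eligible_for_volumetric, logical(1)))
      lesion_rows[[length(lesion_rows) + 1L]] <- data.frame(
        subject_id = subject_id, lesion_id = truth$lesion_id,
        size_class = truth$size_class,
        diameter_mm = axial_diameter(truth),
        n_slices_truth = sum(apply(truth$mask, truth$axial_axis, any)),
        volumetric_eligible = eligible,
        stringsAsFactors = FALSE
      )
      if (!eligible) {
        log_msg("subject %s lesion %s: single-slice only, excluded from volume",
                subject_id, truth$lesion_id)
      }
      for (i in seq_along(segs)) {
        seg <- segs[[i]]
        rd <- seg_plan[[i]]$reader
        slice_idx <- select_reader_slice(
          seg, rd$slice_choice_jitter,
          derive_seed(rd$seed, subject_id, truth$lesion_id,
                      seg$repeat_index, "slice_choice")
        )
        val_slice <- tryCatch(
          measure_mean_ff(ff, seg, "slice",
                          target_spacing_mm = target_spacing_mm,
                          slice_index = slice_idx),
          error = function(e) {
            log_msg("subject %s lesion %s %s rep %d slice: %s", subject_id,
                    truth$lesion_id, seg$reader_id, seg$repeat_index,
                    conditionMessage(e))
            NA_real_
          }
        )
        val_vol <- if (eligible) {
          tryCatch(
            measure_mean_ff(ff, seg, "volume",
                            target_spacing_mm = target_spacing_mm),
            error = function(e) {
              log_msg("subject %s lesion %s %s rep %d volume: %s", subject_id,
                      truth$lesion_id, seg$reader_id, seg$repeat_index,
                      conditionMessage(e))
              NA_real_
            }
          )
        } else {
          NA_real_
        }
        for (md in c("slice", "volume")) {
          v <- if (md == "slice") val_slice else val_vol
          if (is.na(v)) next
          meas_rows[[length(meas_rows) + 1L]] <- data.frame(
            subject_id = subject_id, lesion_id = truth$lesion_id,
            size_class = truth$size_class, reader_id = seg$reader_id,
            rep = seg$repeat_index, mode = md, value = v,
            stringsAsFactors = FALSE
          )
        }
        if (extract_features && eligible) {
          fr <- tryCatch(
            extract_features_table(ff, list(seg),
                                   target_spacing_mm = target_spacing_mm),
            error = function(e) NULL
          )
          if (!is.null(fr)) feat_rows[[length(feat_rows) + 1L]] <- fr
        }
      }
    }
  }

  measurements <- do.call(rbind, meas_rows)
  names(measurements)[names(measurements) == "rep"] <- "repeat"
  rownames(measurements) <- NULL
  structure(
    list(
      measurements = measurements,
      features = if (length(feat_rows)) do.call(rbind, feat_rows) else NULL,
      lesion_summary = do.call(rbind, lesion_rows),
      readers = readers,
      n_subjects = n_subjects,
      seed = seed,
      params = list(
        grid_shape = grid_shape, spacing_mm = spacing_mm,
        marrow_ff_mean = marrow_ff_mean, marrow_ff_sd = marrow_ff_sd,
        interface_blur_mm = interface_blur_mm, noise_sd = noise_sd,
        lesion_ff_mean = lesion_ff_mean,
        lesion_ff_sd_between = lesion_ff_sd_between,
        lesion_ff_sd_voxel = lesion_ff_sd_voxel,
        target_spacing_mm = target_spacing_mm,
        scale_dialect = scale_dialect
      )
    ),
    class = "ff_study"
  )
}

#' @export
print.ff_study <- function(x, ...) {
  cat(sprintf(
    "<ff_study> %d subjects, %d measurements, %d/%d lesions volumetric-eligible\n",
    x$n_subjects, nrow(x$measurements),
    sum(x$lesion_summary$volumetric_eligible), nrow(x$lesion_summary)
  ))
  invisible(x)
}

#' Run the full phantom pipeline: simulate a study and analyse agreement
#'
#' Convenience wrapper chaining [simulate_ff_study()] and
#' [run_agreement_study()].
#'
#' @inheritParams simulate_ff_study
#' @param n_boot Bootstrap resamples for Spearman CIs.
#' @param ... Passed to [simulate_ff_study()].
#' @return List with `study` (the `ff_study`) and `report` (the
#'   `agreement_report`).
#' @export
run_phantom_study <- function(n_subjects = 34L, seed = 1L, n_boot = 2000L,
                              ...) {
  study <- simulate_ff_study(n_subjects = n_subjects, seed = seed, ...)
  report <- run_agreement_study(study$measurements,
                                reader1 = study$readers[[1]]$reader_id,
                                reader2 = study$readers[[2]]$reader_id,
                                n_boot = n_boot, seed = seed)
  list(study = study, report = report)
}
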