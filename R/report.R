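# The full agreement study on a long-format measurement table: intra-reader
# (reader 1, repeats 1 vs 2) and inter-reader (mean of reader 1's repeats vs
# reader 2) cells per size class and measurement mode, Levene variance
# comparison between size classes, and slice-volume Spearman correlation
# pooling the three measurements per lesion.

check_measurement_table <- function(table) {
  needed <- c("subject_id", "lesion_id", "size_class", "reader_id",
              "repeat", "mode", "value")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop("measurement table lacks columns: ", paste(missing, collapse = ", "))
  }
  invisible(table)
}

cell_values <- function(table, size, md, reader, rep_idx) {
  sub <- table[table$size_class == size & table$mode == md &
                 table$reader_id == reader & table[["repeat"]] == rep_idx, ]
  stats::setNames(sub$value, paste(sub$subject_id, sub$lesion_id, sep = "|"))
}

paired_cell <- function(a, b) {
  keys <- intersect(names(a), names(b))
  cbind(a[keys], b[keys])
}

#' Run the full agreement study on a measurement table
#'
#' For every size class (`small`, `large`) and measurement mode (`slice`,
#' `volume`) present in the table, computes:
#' * intra-reader agreement: reader 1 repeat 1 vs repeat 2 — ICC,
#'   Bland-Altman, within-subject SD;
#' * inter-reader agreement for mean FF%: the mean of reader 1's two repeats
#'   vs reader 2's single measurement — ICC, Bland-Altman;
#' * Levene comparison of within-subject variances between small and large
#'   lesions per mode (from the intra-reader repeats);
#' * slice-volume Spearman correlation per size class, pooling the three
#'   measurements per lesion (reader 1 twice, reader 2 once), with a
#'   bootstrap CI.
#'
#' Cells with fewer than 2 complete lesions are skipped and the reason is
#' recorded in `$excluded`.
#'
#' @param table Long-format data.frame with columns `subject_id`,
#'   `lesion_id`, `size_class`, `reader_id`, `repeat`, `mode`, `value`.
#' @param reader1,reader2 Reader labels (reader 1 has repeats 1 and 2).
#' @param n_boot Bootstrap resamples for the Spearman CI.
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return An object of class `agreement_report`: list of data.frames `icc`,
#'   `bland_altman`, `wsd`, `levene`, `spearman`, plus `plot_data` (per-pair
#'   Bland-Altman points) and `excluded` (skipped cells with reasons).
#' @export
run_agreement_study <- function(table, reader1 = "R1", reader2 = "R2",
                                n_boot = 2000L, seed = 1L,
                                conf_level = 0.95) {
  check_measurement_table(table)
  sizes <- intersect(c("small", "large"), unique(table$size_class))
  modes <- intersect(c("slice", "volume"), unique(table$mode))
  icc_rows <- list()
  ba_rows <- list()
  wsd_rows <- list()
  plot_rows <- list()
  excluded <- list()
  intra_cells <- list()

  add_excluded <- function(size, md, comparison, reason) {
    excluded[[length(excluded) + 1L]] <<- data.frame(
      size_class = size, mode = md, comparison = comparison, reason = reason,
      stringsAsFactors = FALSE
    )
    message(sprintf("skipping %s/%s %s: %s", size, md, comparison, reason))
  }

  for (size in sizes) for (md in modes) {
    r1a <- cell_values(table, size, md, reader1, 1L)
    r1b <- cell_values(table, size, md, reader1, 2L)
    r2 <- cell_values(table, size, md, reader2, 1L)

    # intra-reader: reader 1 repeat 1 vs repeat 2
    intra <- paired_cell(r1a, r1b)
    if (nrow(intra) >= 2L) {
      intra_cells[[paste(size, md)]] <- intra
      ic <- icc_oneway(intra, conf_level)
      ba <- bland_altman(intra[, 1], intra[, 2], conf_level)
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        size_class = size, mode = md, comparison = "intra-reader",
        n = ic$n_subjects, icc = ic$estimate, ci_low = ic$ci_low,
        ci_high = ic$ci_high, category = ic$category,
        stringsAsFactors = FALSE
      )
      ba_rows[[length(ba_rows) + 1L]] <- data.frame(
        size_class = size, mode = md, comparison = "intra-reader",
        n = ba$n, mean_pct = ba$mean_of_means, bias = ba$bias,
        bias_ci_low = ba$bias_ci[1], bias_ci_high = ba$bias_ci[2],
        loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        stringsAsFactors = FALSE
      )
      wsd_rows[[length(wsd_rows) + 1L]] <- data.frame(
        size_class = size, mode = md, comparison = "intra-reader",
        wsd = within_subject_sd(intra), stringsAsFactors = FALSE
      )
      plot_rows[[length(plot_rows) + 1L]] <- cbind(
        data.frame(size_class = size, mode = md,
                   comparison = "intra-reader", stringsAsFactors = FALSE),
        ba$plot_data
      )
    } else {
      add_excluded(size, md, "intra-reader", "fewer than 2 complete pairs")
    }

    # inter-reader: mean of reader 1's repeats vs reader 2
    keys <- Reduce(intersect, list(names(r1a), names(r1b), names(r2)))
    if (length(keys) >= 2L) {
      inter <- cbind((r1a[keys] + r1b[keys]) / 2, r2[keys])
      ic <- icc_oneway(inter, conf_level)
      ba <- bland_altman(inter[, 1], inter[, 2], conf_level)
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        size_class = size, mode = md, comparison = "inter-reader",
        n = ic$n_subjects, icc = ic$estimate, ci_low = ic$ci_low,
        ci_high = ic$ci_high, category = ic$category,
        stringsAsFactors = FALSE
      )
      ba_rows[[length(ba_rows) + 1L]] <- data.frame(
        size_class = size, mode = md, comparison = "inter-reader",
        n = ba$n, mean_pct = ba$mean_of_means, bias = ba$bias,
        bias_ci_low = ba$bias_ci[1], bias_ci_high = ba$bias_ci[2],
        loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        stringsAsFactors = FALSE
      )
      plot_rows[[length(plot_rows) + 1L]] <- cbind(
        data.frame(size_class = size, mode = md,
                   comparison = "inter-reader", stringsAsFactors = FALSE),
        ba$plot_data
      )
    } else {
      add_excluded(size, md, "inter-reader", "fewer than 2 complete pairs")
    }
  }

  # Levene: small vs large within-subject variance per mode
  levene_rows <- list()
  for (md in modes) {
    sm <- intra_cells[[paste("small", md)]]
    lg <- intra_cells[[paste("large", md)]]
    if (!is.null(sm) && !is.null(lg) && nrow(sm) >= 2L && nrow(lg) >= 2L) {
      lv <- levene_size_comparison(sm, lg)
      levene_rows[[length(levene_rows) + 1L]] <- data.frame(
        mode = md, f_value = lv$statistic, df1 = lv$df[1], df2 = lv$df[2],
        p_value = lv$p_value, mean_score_small = lv$mean_score["small"],
        mean_score_large = lv$mean_score["large"], stringsAsFactors = FALSE
      )
    }
  }

  # slice-volume Spearman per size class, pooling the three measurements
  spearman_rows <- list()
  if (all(c("slice", "volume") %in% modes)) {
    for (size in sizes) {
      sl <- table[table$size_class == size & table$mode == "slice", ]
      vl <- table[table$size_class == size & table$mode == "volume", ]
      key <- function(d) paste(d$subject_id, d$lesion_id, d$reader_id,
                               d[["repeat"]], sep = "|")
      ks <- key(sl)
      kv <- key(vl)
      keys <- intersect(ks, kv)
      if (length(keys) >= 5L) {
        x <- sl$value[match(keys, ks)]
        y <- vl$value[match(keys, kv)]
        sp <- spearman_bootstrap(x, y, n_boot = n_boot,
                                 seed = derive_seed(seed, "spearman", size),
                                 conf_level = conf_level)
        spearman_rows[[length(spearman_rows) + 1L]] <- data.frame(
          size_class = size, n = sp$n, rho = sp$rho, ci_low = sp$ci_low,
          ci_high = sp$ci_high, stringsAsFactors = FALSE
        )
      } else {
        add_excluded(size, "slice-volume", "spearman",
                     "fewer than 5 complete slice/volume pairs")
      }
    }
  }

  bind <- function(rows) {
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  structure(
    list(
      icc = bind(icc_rows),
      bland_altman = bind(ba_rows),
      wsd = bind(wsd_rows),
      levene = bind(levene_rows),
      spearman = bind(spearman_rows),
      plot_data = bind(plot_rows),
      excluded = bind(excluded)
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("Agreement report\n")
  cat("\nICC (one-way single-measure absolute agreement):\n")
  print(x$icc, digits = digits, row.names = FALSE)
  cat("\nBland-Altman bias and limits of agreement:\n")
  print(x$bland_altman, digits = digits, row.names = FALSE)
  if (!is.null(x$levene)) {
    cat("\nLevene comparison of within-subject variances (small vs large):\n")
    print(x$levene, digits = digits, row.names = FALSE)
  }
  if (!is.null(x$spearman)) {
    cat("\nSlice-volume Spearman correlation:\n")
    print(x$spearman, digits = digits, row.names = FALSE)
  }
  if (!is.null(x$excluded)) {
    cat("\nExcluded cells:\n")
    print(x$excluded, row.names = FALSE)
  }
  invisible(x)
}

#' Feature-level reader agreement
#'
#' ICC per first-order feature and size class from a feature table
#' (one row per subject/lesion/reader/repeat, volume mode). Intra-reader
#' agreement compares reader 1's two repeats; inter-reader agreement compares
#' reader 1's first measurement with reader 2's single measurement (feature
#' values such as skewness can be negative, so reader 1's repeats are not
#' averaged).
#'
#' @param features Data.frame as returned by [extract_features_table()].
#' @param feature_cols Character vector of feature columns; defaults to all
#'   numeric non-bookkeeping columns.
#' @param reader1,reader2 Reader labels.
#' @param conf_level Confidence level.
#' @return Data.frame with one row per size class x feature x comparison:
#'   `n`, `icc`, `ci_low`, `ci_high`, `category`.
#' @export
feature_agreement <- function(features, feature_cols = NULL,
                              reader1 = "R1", reader2 = "R2",
                              conf_level = 0.95) {
  bookkeeping <- c("subject_id", "lesion_id", "size_class", "reader_id",
                   "repeat", "mode", "n_raw", "n_removed")
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   logical(1))],
                            bookkeeping)
  }
  key <- function(d) paste(d$subject_id, d$lesion_id, sep = "|")
  rows <- list()
  for (size in intersect(c("small", "large"), unique(features$size_class))) {
    sub <- features[features$size_class == size, ]
    r1a <- sub[sub$reader_id == reader1 & sub[["repeat"]] == 1L, ]
    r1b <- sub[sub$reader_id == reader1 & sub[["repeat"]] == 2L, ]
    r2 <- sub[sub$reader_id == reader2 & sub[["repeat"]] == 1L, ]
    for (feat in feature_cols) {
      for (cmp in c("intra-reader", "inter-reader")) {
        a <- r1a
        b <- if (cmp == "intra-reader") r1b else r2
        keys <- intersect(key(a), key(b))
        x <- a[[feat]][match(keys, key(a))]
        y <- b[[feat]][match(keys, key(b))]
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 2L) next
        ic <- icc_oneway(cbind(x[ok], y[ok]), conf_level)
        rows[[length(rows) + 1L]] <- data.frame(
          size_class = size, feature = feat, comparison = cmp,
          n = ic$n_subjects, icc = ic$estimate, ci_low = ic$ci_low,
          ci_high = ic$ci_high, category = ic$category,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a measurement table as CSV
#'
#' @param table Measurement table data.frame.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_measurement_table <- function(table, path) {
  check_measurement_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a measurement table from CSV
#'
#' @param path CSV path with columns `subject_id`, `lesion_id`, `size_class`,
#'   `reader_id`, `repeat`, `mode`, `value`.
#' @return A data.frame.
#' @export
read_measurement_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_measurement_table(df)
  df
}

#' Write an agreement report to CSV and JSON
#'
#' Writes one CSV per result table (`icc`, `bland_altman`, `wsd`, `levene`,
#' `spearman`, `plot_data`) plus a combined JSON file.
#'
#' @param report An `agreement_report`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"agreement"`).
#' @return Invisibly, the paths written.
#' @export
write_agreement_report <- function(report, dir, prefix = "agreement") {
  stopifnot(inherits(report, "agreement_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("icc", "bland_altman", "wsd", "levene", "spearman",
               "plot_data", "excluded")) {
    if (is.null(report[[nm]])) next
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
    write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  pj <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))], pj,
                       dataframe = "rows", digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, pj))
}
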