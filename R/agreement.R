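# Agreement statistics for repeated FF% measurements: one-way single-measure
# absolute-agreement ICC with exact F-based confidence limits, Bland-Altman
# limits of agreement, within-subject SD, Levene comparison of within-subject
# variances between lesion size classes, bootstrap Spearman correlation, and
# the Walter-Eliasziw-Donner reliability-study sample-size approximation.

cell_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else if (is.data.frame(x)) {
    stopifnot(all(c("subject_id", "value") %in% names(x)))
    counts <- table(x$subject_id)
    if (length(unique(counts)) != 1L) {
      bad <- names(counts)[counts != as.integer(names(which.max(table(counts))))]
      stop("unbalanced cell: subjects with deviating observation counts: ",
           paste(bad, collapse = ", "))
    }
    k <- unname(counts[1])
    ord <- order(x$subject_id)
    m <- matrix(x$value[ord], ncol = k, byrow = TRUE)
    rownames(m) <- unique(x$subject_id[ord])
  } else {
    stop("expected an n x k matrix or a data.frame with subject_id and value")
  }
  if (anyNA(m)) stop("cell contains missing values")
  m
}

#' One-way single-measure absolute-agreement ICC
#'
#' ICC(1,1) from the one-way random-effects ANOVA:
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)`, with the exact F-based 95%
#' confidence interval (Searle form): with `F = MSB / MSW`,
#' `FL = F / qf(1 - a/2, n - 1, n(k - 1))`,
#' `FU = F * qf(1 - a/2, n(k - 1), n - 1)`, and each limit mapped through
#' `(F* - 1) / (F* + k - 1)`. A degenerate table with all values identical
#' returns estimate 1 with interval `[1, 1]`.
#'
#' @param x An `n x k` matrix (rows = subjects) or a long data.frame with
#'   columns `subject_id` and `value` (must be balanced).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_result`: list with `estimate`, `ci_low`,
#'   `ci_high`, `n_subjects`, `k`, `msb`, `msw`, `f_value`, `category`.
#' @export
icc_oneway <- function(x, conf_level = 0.95) {
  m <- cell_matrix(x)
  n <- nrow(m)
  k <- ncol(m)
  stopifnot(n >= 2L, k >= 2L)
  mi <- rowMeans(m)
  gm <- mean(m)
  msb <- k * sum((mi - gm)^2) / (n - 1)
  msw <- sum((m - mi)^2) / (n * (k - 1))
  a <- 1 - conf_level
  if (msw == 0) {
    res <- list(estimate = 1, ci_low = 1, ci_high = 1)
    fv <- Inf
  } else {
    fv <- msb / msw
    est <- (msb - msw) / (msb + (k - 1) * msw)
    fl <- fv / qf(1 - a / 2, n - 1, n * (k - 1))
    fu <- fv * qf(1 - a / 2, n * (k - 1), n - 1)
    res <- list(
      estimate = est,
      ci_low = (fl - 1) / (fl + k - 1),
      ci_high = (fu - 1) / (fu + k - 1)
    )
  }
  structure(
    c(res, list(n_subjects = n, k = k, msb = msb, msw = msw, f_value = fv,
                conf_level = conf_level,
                category = interpret_icc(res$estimate))),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(1,1) = %.3f, %d%% CI [%.3f, %.3f] (%s; n = %d, k = %d)\n",
    x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high, x$category,
    x$n_subjects, x$k
  ))
  invisible(x)
}

#' Interpret an ICC estimate
#'
#' Reliability bands: poor below 0.5, moderate in `[0.5, 0.75)`, good in
#' `[0.75, 0.9]`, excellent above 0.9. Boundary handling: exactly 0.5 is
#' moderate, exactly 0.75 is good, and exactly 0.9 is good (only values
#' strictly above 0.9 are excellent).
#'
#' @param estimate ICC estimate (at most 1).
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
interpret_icc <- function(estimate) {
  stopifnot(estimate <= 1 + 1e-12)
  if (estimate > 0.9) {
    "excellent"
  } else if (estimate >= 0.75) {
    "good"
  } else if (estimate >= 0.5) {
    "moderate"
  } else {
    "poor"
  }
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences `d = m1 - m2`; bias = mean difference; limits of agreement
#' `bias +/- 1.96 sd(d)`; bias confidence interval from the t distribution.
#'
#' @param m1,m2 Paired measurement vectors (same length, at least 2).
#' @param conf_level Confidence level for the bias CI (default 0.95).
#' @return An object of class `bland_altman_result`: list with
#'   `mean_of_means`, `bias`, `bias_ci` (length 2), `sd_diff`, `loa_lower`,
#'   `loa_upper`, `n`, and `plot_data` (per-pair mean and difference).
#' @export
bland_altman <- function(m1, m2, conf_level = 0.95) {
  stopifnot(length(m1) == length(m2), length(m1) >= 2L,
            all(is.finite(m1)), all(is.finite(m2)))
  d <- m1 - m2
  n <- length(d)
  bias <- mean(d)
  sd_diff <- sd(d)
  half <- qt(1 - (1 - conf_level) / 2, n - 1) * sd_diff / sqrt(n)
  structure(
    list(
      mean_of_means = mean((m1 + m2) / 2),
      bias = bias,
      bias_ci = c(bias - half, bias + half),
      sd_diff = sd_diff,
      loa_lower = bias - 1.96 * sd_diff,
      loa_upper = bias + 1.96 * sd_diff,
      n = n,
      plot_data = data.frame(mean = (m1 + m2) / 2, difference = d)
    ),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.3f [%.3f, %.3f], LoA [%.3f, %.3f] (n = %d)\n",
    x$bias, x$bias_ci[1], x$bias_ci[2], x$loa_lower, x$loa_upper, x$n
  ))
  invisible(x)
}

#' Within-subject standard deviation
#'
#' Square root of the mean per-subject sample variance across repeats;
#' on a balanced table this equals `sqrt(MSW)` from the one-way ANOVA.
#'
#' @inheritParams icc_oneway
#' @return Within-subject SD (same units as the measurements).
#' @export
within_subject_sd <- function(x) {
  m <- cell_matrix(x)
  stopifnot(ncol(m) >= 2L)
  sqrt(mean(apply(m, 1, var)))
}

#' Levene comparison of within-subject variances between size classes
#'
#' Tests whether the within-subject (repeat-to-repeat) variance differs
#' between small and large lesions. Each subject contributes one dispersion
#' score `|y_i1 - y_i2| / sqrt(2)` (its absolute within-subject deviation,
#' an unbiased-scale estimate of the within-subject SD for k = 2); the
#' scores are compared across the two size groups with the classic Levene
#' one-way ANOVA F test. With two repeats the subject-level mean and median
#' coincide, so the mean-centered (Levene) and median-centered
#' (Brown-Forsythe) dispersion scores are identical.
#'
#' @param small_cell,large_cell `n x 2` matrices (or balanced long
#'   data.frames with `subject_id`, `value`) of paired repeats for the small
#'   and large lesion groups.
#' @return List with `statistic` (F), `df` (length 2), `p_value`, and the
#'   per-group mean dispersion scores.
#' @export
levene_size_comparison <- function(small_cell, large_cell) {
  ms <- cell_matrix(small_cell)
  ml <- cell_matrix(large_cell)
  stopifnot(ncol(ms) == 2L, ncol(ml) == 2L, nrow(ms) >= 2L, nrow(ml) >= 2L)
  s_small <- abs(ms[, 1] - ms[, 2]) / sqrt(2)
  s_large <- abs(ml[, 1] - ml[, 2]) / sqrt(2)
  score <- c(s_small, s_large)
  group <- factor(rep(c("small", "large"), c(length(s_small), length(s_large))))
  fit <- anova(lm(score ~ group))
  structure(
    list(statistic = fit[["F value"]][1],
         df = c(fit[["Df"]][1], fit[["Df"]][2]),
         p_value = fit[["Pr(>F)"]][1],
         mean_score = c(small = mean(s_small), large = mean(s_large))),
    class = "levene_result"
  )
}

#' @export
print.levene_result <- function(x, ...) {
  cat(sprintf("Levene F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$statistic, x$p_value))
  invisible(x)
}

#' Spearman correlation with bootstrap confidence interval
#'
#' Spearman's rho (Pearson correlation of average ranks, so ties are
#' handled) with a percentile bootstrap CI over paired resamples,
#' deterministic for a fixed seed.
#'
#' @param x,y Paired vectors, length at least 5.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed RNG seed.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `rho`, `ci_low`, `ci_high`, `n`, `n_boot`. Constant `x`
#'   or `y` gives `rho = NA` with a warning (correlation undefined).
#' @export
spearman_bootstrap <- function(x, y, n_boot = 2000L, seed = 1L,
                               conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 5L,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n = n, n_boot = n_boot))
  }
  rho <- cor(x, y, method = "spearman")
  a <- 1 - conf_level
  rhos <- with_seed(derive_seed(seed, "spearman_boot"), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(x[idx]) == 0 || sd(y[idx]) == 0) return(NA_real_)
      cor(x[idx], y[idx], method = "spearman")
    }, numeric(1))
  })
  ci <- quantile(rhos, c(a / 2, 1 - a / 2), na.rm = TRUE, names = FALSE,
                 type = 7)
  list(rho = rho, ci_low = ci[1], ci_high = ci[2], n = n, n_boot = n_boot)
}

#' Sample size for a reliability (ICC) study
#'
#' Walter-Eliasziw-Donner approximation for the number of subjects needed to
#' detect reliability `rho1` against a minimum acceptable reliability `rho0`
#' with `k` observations per subject: with `theta = rho / (1 - rho)` and
#' `C0 = (1 + k theta0) / (1 + k theta1)`,
#' `n = 1 + 2 k (z_alpha + z_beta)^2 / ((k - 1) ln(C0)^2)`, rounded up.
#' By default `alpha` is interpreted two-sided (`z_alpha = z_{1 - alpha/2}`);
#' set `two_sided = FALSE` for the one-sided variant.
#'
#' @param rho0 Minimum acceptable reliability, in `[0, 1)`.
#' @param rho1 Expected reliability, `rho0 < rho1 < 1`.
#' @param k Observations per subject (>= 2).
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param two_sided Interpret `alpha` two-sided (default `TRUE`).
#' @return Minimum number of subjects (integer).
#' @export
#' @examples
#' walter_sample_size(0.75, 0.9, k = 2) # 33
walter_sample_size <- function(rho0, rho1, k = 2L, alpha = 0.05,
                               power = 0.8, two_sided = TRUE) {
  stopifnot(rho0 >= 0, rho0 < 1, k >= 2, alpha > 0, alpha < 1,
            power > 0, power < 1)
  if (rho1 <= rho0) stop("rho1 must exceed rho0: no detectable effect")
  if (rho1 >= 1) stop("rho1 must be below 1")
  za <- qnorm(1 - alpha / (if (two_sided) 2 else 1))
  zb <- qnorm(power)
  theta0 <- rho0 / (1 - rho0)
  theta1 <- rho1 / (1 - rho1)
  c0 <- (1 + k * theta0) / (1 + k * theta1)
  n <- 1 + 2 * k * (za + zb)^2 / ((k - 1) * log(c0)^2)
  as.integer(ceiling(n - 1e-9))
}
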