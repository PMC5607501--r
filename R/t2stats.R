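## Subject-level T2 statistics: meanT2, maxT2, meanSD, madSD — the latter
## two summarizing within-segment tissue inhomogeneity — plus the
## two-group cohort comparison table.

#' Subject-level T2 summary statistics
#'
#' From a 16-row segment table computes, over the unflagged segments:
#' `mean_t2` (mean of segmental mean T2), `max_t2` (the highest segmental
#' mean T2), `mean_sd` (mean of the segmental pixel-SDs), and `mad_sd` —
#' the mean absolute deviation of the segmental pixel-SDs about their mean,
#' `(1/K) * sum |pixel_sd_i - mean_sd|`. High madSD indicates spatially
#' heterogeneous within-segment T2 spread, the signature of focal
#' myocardial inflammation.
#'
#' @param table A `segment_table` from [segment_statistics()].
#' @param center `"mean"` (default; mean absolute deviation about the
#'   mean) or `"median"` (about the median).
#' @return List of class `t2_summary`: `mean_t2`, `max_t2`, `mean_sd`,
#'   `mad_sd` (all ms), `n_segments_used`.
#' @export
t2_summary <- function(table, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(is.data.frame(table), nrow(table) >= 1L,
            all(c("mean_t2_ms", "pixel_sd_ms") %in% names(table)))
  use <- if ("flagged" %in% names(table)) !table$flagged else
    rep(TRUE, nrow(table))
  use <- use & is.finite(table$mean_t2_ms) & is.finite(table$pixel_sd_ms)
  if (!any(use)) stop("no usable segments")
  if (sum(use) < 16L)
    warning("only ", sum(use), " of 16 segments usable")
  t2 <- table$mean_t2_ms[use]
  psd <- table$pixel_sd_ms[use]
  ctr <- if (center == "mean") mean(psd) else median(psd)
  structure(list(mean_t2 = mean(t2), max_t2 = max(t2),
                 mean_sd = mean(psd), mad_sd = mean(abs(psd - ctr)),
                 n_segments_used = sum(use)),
            class = "t2_summary")
}

#' @export
print.t2_summary <- function(x, ...) {
  cat(sprintf(
    "T2 summary over %d segments: meanT2 %.1f ms, maxT2 %.1f ms, meanSD %.2f ms, madSD %.2f ms\n",
    x$n_segments_used, x$mean_t2, x$max_t2, x$mean_sd, x$mad_sd))
  invisible(x)
}

#' Two-group descriptive and inferential comparison of cohort parameters
#'
#' For every numeric parameter column, reports mean and SD per group and a
#' two-sided p-value from either Welch's t-test (when a Shapiro-Wilk test
#' at alpha = 0.05 does not reject normality in either group) or the
#' Wilcoxon rank-sum test otherwise.
#'
#' @param cohort A `cohort_table` data.frame with a `group` column
#'   (control/patient) and numeric parameter columns.
#' @param parameters Character vector of columns to compare; defaults to
#'   all numeric columns except `LGE`.
#' @param shapiro_alpha Normality-gate significance level.
#' @return Data.frame: parameter, control mean/SD, patient mean/SD, test
#'   used, p-value.
#' @export
summarize_cohort <- function(cohort, parameters = NULL,
                             shapiro_alpha = 0.05) {
  stopifnot("group" %in% names(cohort))
  g <- cohort$group
  stopifnot(all(levels(factor(g)) %in% c("control", "patient")))
  if (is.null(parameters)) {
    num <- vapply(cohort, is.numeric, logical(1))
    parameters <- setdiff(names(cohort)[num], c("LGE"))
  }
  n_c <- sum(g == "control"); n_p <- sum(g == "patient")
  if (n_c == 0 || n_p == 0) stop("both groups must be non-empty")
  do_tests <- n_c >= 3 && n_p >= 3
  if (!do_tests) warning("fewer than 3 subjects in a group: tests skipped")
  rows <- lapply(parameters, function(p) {
    xc <- cohort[[p]][g == "control"]
    xp <- cohort[[p]][g == "patient"]
    test <- NA_character_; pval <- NA_real_
    if (do_tests) {
      normal <- tryCatch(
        shapiro.test(xc)$p.value > shapiro_alpha &&
          shapiro.test(xp)$p.value > shapiro_alpha,
        error = function(e) FALSE)   # e.g. zero-variance samples
      if (normal) {
        test <- "welch"
        pval <- t.test(xc, xp)$p.value
      } else {
        test <- "wilcoxon"
        pval <- wilcox.test(xc, xp, exact = FALSE)$p.value
      }
    }
    data.frame(parameter = p,
               mean_control = mean(xc), sd_control = sd(xc),
               mean_patient = mean(xp), sd_patient = sd(xp),
               test = test, p_value = pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
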