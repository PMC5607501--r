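## Quantitative Lake Louise criteria: T2-ratio, early gadolinium
## enhancement ratio (EGEr), and the 2-of-3 diagnosis rule.

#' Myocardium-to-skeletal-muscle T2 signal-intensity ratio
#'
#' On T2-weighted black-blood images, the ratio of mean myocardial to mean
#' skeletal-muscle signal intensity; deemed pathological (edema) when
#' >= 1.9 (boundary inclusive).
#'
#' @param si_myo Mean myocardial signal intensity (> 0).
#' @param si_sm Mean skeletal-muscle signal intensity (> 0).
#' @return List with `ratio` and logical `positive`.
#' @export
t2_ratio <- function(si_myo, si_sm) {
  if (any(si_sm <= 0)) stop("skeletal-muscle signal intensity must be > 0")
  r <- si_myo / si_sm
  list(ratio = r, positive = r >= 1.9)
}

#' Early gadolinium enhancement ratio (EGEr)
#'
#' Relative myocardial enhancement normalized to skeletal-muscle relative
#' enhancement:
#' `EGEr = [(myo_post - myo_pre)/myo_pre] / [(sm_post - sm_pre)/sm_pre]`.
#' Pathological (hyperemia) when >= 4. When the muscle relative
#' enhancement is not positive the ratio is undefined and flagged.
#'
#' @param si_myo_pre,si_myo_post Myocardial SI before/after contrast (> 0
#'   pre).
#' @param si_sm_pre,si_sm_post Skeletal-muscle SI before/after contrast.
#' @return List with `eger`, logical `positive`, logical `undefined`.
#' @export
ege_ratio <- function(si_myo_pre, si_myo_post, si_sm_pre, si_sm_post) {
  if (any(si_myo_pre <= 0) || any(si_sm_pre <= 0))
    stop("pre-contrast signal intensities must be > 0")
  rel_myo <- (si_myo_post - si_myo_pre) / si_myo_pre
  rel_sm <- (si_sm_post - si_sm_pre) / si_sm_pre
  und <- rel_sm <= 0
  e <- ifelse(und, NA_real_, rel_myo / rel_sm)
  list(eger = e, positive = !und & e >= 4, undefined = und)
}

#' Lake Louise 2-of-3 diagnosis
#'
#' Counts the positive criteria among edema, early gadolinium enhancement
#' and late gadolinium enhancement; the CMR diagnosis of myocarditis is
#' positive when at least 2 of the 3 are met.
#'
#' @param edema_positive,ege_positive,lge_positive Logical flags
#'   (vectorized).
#' @return List with integer `count` and logical `positive`.
#' @export
llc_diagnosis <- function(edema_positive, ege_positive, lge_positive) {
  cnt <- as.integer(edema_positive) + as.integer(ege_positive) +
    as.integer(lge_positive)
  list(count = cnt, positive = cnt >= 2L)
}

#' Edema positivity from T2-ratio and visual read
#'
#' The edema criterion is met when the quantitative T2-ratio is >= 1.9 or,
#' if `use_visual`, when the visual read was positive.
#'
#' @param ratio_positive Logical: T2-ratio >= 1.9.
#' @param visual_positive Logical visual-edema flag.
#' @param use_visual Combine the visual read with the ratio (default
#'   TRUE); set FALSE for ratio-only positivity.
#' @return Logical.
#' @export
edema_positive <- function(ratio_positive, visual_positive = FALSE,
                           use_visual = TRUE) {
  if (use_visual) ratio_positive | visual_positive else ratio_positive
}
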