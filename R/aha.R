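## AHA 16-segment parcellation of short-axis myocardial masks and the
## segmental T2 statistics (mean T2, pixel-SD) extracted from a T2 map.

AHA_SEGMENT_NAMES <- c(
  "basal anterior", "basal anteroseptal", "basal inferoseptal",
  "basal inferior", "basal inferolateral", "basal anterolateral",
  "mid anterior", "mid anteroseptal", "mid inferoseptal",
  "mid inferior", "mid inferolateral", "mid anterolateral",
  "apical anterior", "apical septal", "apical inferior", "apical lateral")

#' Assign AHA segment labels to the masked pixels of one short-axis slice
#'
#' Each masked pixel is labeled by the angular sector containing its angle
#' about the mask centroid, measured counterclockwise (as displayed) from
#' the anterior RV-insertion ray. Basal and mid slices use six 60-degree
#' sectors in AHA order (anterior, anteroseptal, inferoseptal, inferior,
#' inferolateral, anterolateral); the apical slice uses four 90-degree
#' sectors (anterior, septal, inferior, lateral). Sectors are half-open
#' `[a, a + width)`: a pixel exactly on a boundary belongs to the
#' counterclockwise-following segment.
#'
#' @param mask 2-D logical matrix (non-empty).
#' @param rv_insertion_angle Angle (degrees) of the anterior RV-insertion
#'   ray about the centroid, counterclockwise as displayed, 0 = +x axis.
#' @param level Slice level, one of `"basal"`, `"mid"`, `"apical"`.
#' @param centroid Optional length-2 (x, y); defaults to the mask centroid.
#' @return Integer matrix, same shape as `mask`: 0 outside the mask,
#'   AHA segment id (1-16 global numbering) inside.
#' @export
assign_segments <- function(mask, rv_insertion_angle,
                            level = c("basal", "mid", "apical"),
                            centroid = NULL) {
  level <- match.arg(level)
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("mask is empty: cannot define a centroid")
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(centroid)) centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  dx <- idx[, 1] - centroid[1]
  dy <- idx[, 2] - centroid[2]
  if (all(dx == 0 & dy == 0)) stop("degenerate mask: zero angular extent")
  ang <- (atan2(dy, dx) * 180 / pi - rv_insertion_angle) %% 360
  n_sect <- if (level == "apical") 4L else 6L
  sect <- pmin(floor(ang / (360 / n_sect)), n_sect - 1L) + 1L
  offset <- switch(level, basal = 0L, mid = 6L, apical = 12L)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[idx] <- sect + offset
  lab
}

#' AHA labels for a 3-slice short-axis volume
#'
#' Applies [assign_segments()] to the basal, mid and apical slices of a
#' 3-D mask, with one RV-insertion angle per slice.
#'
#' @param mask 3-D logical array (x, y, 3 slices ordered basal, mid,
#'   apical).
#' @param rv_insertion_angle Scalar or length-3 vector of degrees.
#' @return Integer 3-D array of labels 0 / 1-16.
#' @export
assign_segments_volume <- function(mask, rv_insertion_angle) {
  stopifnot(length(dim(mask)) == 3L, dim(mask)[3] == 3L)
  rv <- rep(rv_insertion_angle, length.out = 3)
  levels <- c("basal", "mid", "apical")
  out <- array(0L, dim(mask))
  for (s in 1:3)
    out[, , s] <- assign_segments(mask[, , s], rv[s], levels[s])
  out
}

#' Segmental T2 statistics
#'
#' For each AHA segment, averages the T2 values of its pixels (the
#' segmental mean T2) and records their sample standard deviation (n - 1)
#' as the segment's pixel-SD, a within-segment tissue-inhomogeneity
#' measure. Only pixels with fit status `"ok"` contribute. Segments with
#' fewer than `min_pixels` contributing pixels are flagged and excluded
#' from downstream subject-level statistics.
#'
#' @param t2map A `t2map` object (or a bare 3-D numeric array of T2
#'   values, all treated as ok).
#' @param labels Integer label array from [assign_segments_volume()].
#' @param min_pixels Minimum pixels per segment (default 10).
#' @return A data.frame of class `segment_table` with columns
#'   `segment_id`, `segment`, `level`, `mean_t2_ms`, `pixel_sd_ms`,
#'   `n_pixels`, `flagged`.
#' @export
segment_statistics <- function(t2map, labels, min_pixels = 10L) {
  if (inherits(t2map, "t2map")) {
    vals <- t2map$t2
    ok <- t2map$status == "ok"
  } else {
    vals <- t2map
    ok <- is.finite(vals)
  }
  stopifnot(all(dim(vals) == dim(labels)))
  lv <- as.vector(labels)
  keep <- lv > 0 & as.vector(ok)
  lab <- lv[keep]
  v <- as.vector(vals)[keep]
  out <- data.frame(
    segment_id = 1:16,
    segment = AHA_SEGMENT_NAMES,
    level = rep(c("basal", "mid", "apical"), c(6, 6, 4)),
    mean_t2_ms = NA_real_, pixel_sd_ms = NA_real_, n_pixels = 0L,
    flagged = TRUE, stringsAsFactors = FALSE)
  for (s in 1:16) {
    x <- v[lab == s]
    out$n_pixels[s] <- length(x)
    if (length(x) >= 1L) out$mean_t2_ms[s] <- mean(x)
    if (length(x) >= 2L) out$pixel_sd_ms[s] <- sd(x)
    out$flagged[s] <- length(x) < min_pixels
  }
  if (any(out$flagged))
    warning(sum(out$flagged), " segment(s) below the ", min_pixels,
            "-pixel minimum were flagged")
  class(out) <- c("segment_table", "data.frame")
  out
}
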