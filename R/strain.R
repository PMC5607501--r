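## Feature-tracking strain: normalized cross-correlation block matching of
## an end-diastolic endocardial contour through the cine cycle, Lagrangian
## perimeter strain, strain rate, and global (3-slice averaged) summaries.

## Bilinear sampling of image `img` (matrix, indices x = row, y = col) at
## fractional coordinates; clamps to the image border.
bilinear_patch <- function(img, cx, cy, half) {
  rng <- (-half):half
  xs <- cx + rng
  ys <- cy + rng
  x0 <- pmin(pmax(floor(xs), 1L), nrow(img) - 1L)
  y0 <- pmin(pmax(floor(ys), 1L), ncol(img) - 1L)
  fx <- pmin(pmax(xs - x0, 0), 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  a <- img[x0, y0, drop = FALSE]
  b <- img[x0 + 1L, y0, drop = FALSE]
  cc <- img[x0, y0 + 1L, drop = FALSE]
  d <- img[x0 + 1L, y0 + 1L, drop = FALSE]
  wa <- outer(1 - fx, 1 - fy); wb <- outer(fx, 1 - fy)
  wc <- outer(1 - fx, fy);     wd <- outer(fx, fy)
  a * wa + b * wb + cc * wc + d * wd
}

## Normalized cross-correlation of one template against every integer
## shift in [-sh, sh]^2 around (cx, cy) in `img`. Returns the best shift
## with parabolic subpixel refinement and the peak correlation.
ncc_match <- function(img, template, cx, cy, sh) {
  th <- (nrow(template) - 1L) %/% 2L
  ## search neighborhood sampled about the exact (fractional) center, so a
  ## zero shift compares identically-sampled patches
  half <- th + sh
  S <- bilinear_patch(img, cx, cy, half)
  n <- 2L * sh + 1L
  tw <- 2L * th + 1L
  tv <- as.vector(template) - mean(template)
  tn <- sqrt(sum(tv^2))
  if (tn == 0) return(list(dx = 0, dy = 0, peak = 0))
  scores <- matrix(-Inf, n, n)
  for (j in seq_len(n)) {
    cols <- (j - 1L) + seq_len(tw)
    block <- S[, cols, drop = FALSE]
    for (i in seq_len(n)) {
      p <- as.vector(block[(i - 1L) + seq_len(tw), , drop = FALSE])
      pv <- p - mean(p)
      pn <- sqrt(sum(pv^2))
      scores[i, j] <- if (pn == 0) 0 else sum(pv * tv) / (pn * tn)
    }
  }
  k <- arrayInd(which.max(scores), dim(scores))
  peak <- scores[k]
  di <- k[1] - sh - 1L
  dj <- k[2] - sh - 1L
  ## parabolic subpixel refinement along each axis, interior peaks only
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else max(min(0.5 * (cm - cp) / den, 0.5), -0.5)
  }
  ddx <- ddy <- 0
  if (k[1] > 1 && k[1] < n)
    ddx <- refine(scores[k[1] - 1, k[2]], peak, scores[k[1] + 1, k[2]])
  if (k[2] > 1 && k[2] < n)
    ddy <- refine(scores[k[1], k[2] - 1], peak, scores[k[1], k[2] + 1])
  list(dx = di + ddx, dy = dj + ddy, peak = peak)
}

#' Track a contour through a cine sequence
#'
#' Propagates each end-diastolic contour point frame to frame by
#' normalized cross-correlation block matching (template from the current
#' frame, search window in the next), with parabolic subpixel refinement.
#' Points whose correlation peak falls below `min_peak` are interpolated
#' from their neighbors and flagged. The sequence is closed cyclically:
#' after tracking the final frame back onto the first, the residual drift
#' of each point is removed by linear redistribution across frames, so the
#' end of the cycle maps onto the end-diastolic contour.
#'
#' @param frames 3-D array (x, y, frame) of cine images, or a
#'   `cine_phantom`.
#' @param ed_contour Two-column matrix of end-diastolic points (frame 1).
#' @param template Template side length in pixels (odd; default 15).
#' @param search Search window side length in pixels (odd; default 25).
#' @param min_peak Minimum acceptable correlation peak (default 0.5).
#' @param drift_correct Remove cumulative drift by cyclic closure
#'   (default TRUE). Disable for sequences that do not return to the
#'   end-diastolic configuration (e.g. a one-way translation).
#' @param frame_times_ms Frame times (ms); taken from the phantom, or
#'   35 ms spacing by default.
#' @param closed Is the contour closed (SAX ring) or an open polyline?
#' @return Object of class `tracked_contour`: list with `points` (list of
#'   per-frame two-column matrices), `frame_times_ms`, `closed`,
#'   `flagged` (logical matrix points x frames).
#' @export
track_contour <- function(frames, ed_contour = NULL, template = 15L,
                          search = 25L, min_peak = 0.5,
                          frame_times_ms = NULL, closed = TRUE,
                          drift_correct = TRUE) {
  if (inherits(frames, "cine_phantom")) {
    if (is.null(ed_contour)) ed_contour <- frames$contours[[1]]
    if (is.null(frame_times_ms)) frame_times_ms <- frames$frame_times_ms
    frames <- frames$frames
  }
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] >= 2L,
            !is.null(ed_contour))
  ed_contour <- as.matrix(ed_contour)
  nf <- dim(frames)[3]
  np <- nrow(ed_contour)
  if (is.null(frame_times_ms)) frame_times_ms <- (seq_len(nf) - 1) * 35
  th <- (as.integer(template) - 1L) %/% 2L
  sh <- (as.integer(search) - 1L) %/% 2L - th
  if (sh < 1L) stop("search window must exceed the template size")

  pts <- vector("list", nf)
  pts[[1]] <- ed_contour
  flagged <- matrix(FALSE, np, nf)
  step <- function(cur, img_from, img_to, t_index) {
    nxt <- cur
    for (k in seq_len(np)) {
      tmpl <- bilinear_patch(img_from, cur[k, 1], cur[k, 2], th)
      mt <- ncc_match(img_to, tmpl, cur[k, 1], cur[k, 2], sh)
      if (mt$peak < min_peak) {
        flagged[k, t_index] <<- TRUE
        nxt[k, ] <- NA_real_
      } else {
        nxt[k, ] <- cur[k, ] + c(mt$dx, mt$dy)
      }
    }
    bad <- which(is.na(nxt[, 1]))
    if (length(bad)) {                 # neighbor interpolation on the ring
      good <- which(!is.na(nxt[, 1]))
      if (!length(good)) stop("tracking lost every contour point")
      disp <- nxt[good, , drop = FALSE] - cur[good, , drop = FALSE]
      for (k in bad) {
        d <- pmin(abs(good - k), np - abs(good - k))
        w <- 1 / pmax(d, 1)
        nxt[k, ] <- cur[k, ] + colSums(disp * w) / sum(w)
      }
    }
    nxt
  }
  for (t in seq_len(nf - 1L))
    pts[[t + 1L]] <- step(pts[[t]], frames[, , t], frames[, , t + 1L], t + 1L)
  ## cyclic closure: track the last frame back onto frame 1 and remove the
  ## accumulated drift linearly across the cycle
  if (drift_correct) {
    final <- step(pts[[nf]], frames[, , nf], frames[, , 1L], 1L)
    drift <- final - ed_contour
    for (t in seq_len(nf))
      pts[[t]] <- pts[[t]] - drift * ((t - 1) / nf)
  }
  structure(list(points = pts, frame_times_ms = frame_times_ms,
                 closed = closed, flagged = flagged),
            class = "tracked_contour")
}

polyline_length <- function(pts, closed = TRUE) {
  d <- diff(pts)
  len <- sum(sqrt(rowSums(d^2)))
  if (closed) {
    e <- pts[1, ] - pts[nrow(pts), ]
    len <- len + sqrt(sum(e^2))
  }
  len
}

#' Lagrangian strain and strain rate from a tracked contour
#'
#' Computes the contour length per frame (perimeter for closed contours),
#' the Lagrangian strain `100 * (L(t) - L(0)) / L(0)` in percent, and the
#' strain rate in 1/s as the time derivative of the fractional strain by
#' central differences on the frame times (one-sided at the endpoints).
#'
#' @param tracked A `tracked_contour`, or a list of per-frame contour
#'   matrices (then `frame_times_ms` and `closed` apply).
#' @param kind `"circumferential"` or `"longitudinal"` (annotation only).
#' @param chamber `"LV"` or `"RV"` (annotation only).
#' @param frame_times_ms,closed Used when `tracked` is a bare list.
#' @return Object of class `strain_curve`: list with `epsilon` (%),
#'   `strain_rate` (1/s), `length` (px), `frame_times_ms`, `kind`,
#'   `chamber`.
#' @export
strain_from_contour <- function(tracked,
                                kind = c("circumferential", "longitudinal"),
                                chamber = c("LV", "RV"),
                                frame_times_ms = NULL, closed = TRUE) {
  kind <- match.arg(kind)
  chamber <- match.arg(chamber)
  if (inherits(tracked, "tracked_contour")) {
    pts <- tracked$points
    frame_times_ms <- tracked$frame_times_ms
    closed <- tracked$closed
  } else pts <- tracked
  stopifnot(is.list(pts), length(pts) >= 2L)
  if (is.null(frame_times_ms))
    frame_times_ms <- (seq_along(pts) - 1) * 35
  L <- vapply(pts, polyline_length, numeric(1), closed = closed)
  if (L[1] <= 0) stop("zero initial contour length")
  eps <- 100 * (L - L[1]) / L[1]
  tt <- frame_times_ms / 1000           # seconds
  f <- eps / 100                        # fractional strain
  n <- length(f)
  sr <- numeric(n)
  if (n >= 3) {
    sr[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  }
  sr[1] <- (f[2] - f[1]) / (tt[2] - tt[1])
  sr[n] <- (f[n] - f[n - 1]) / (tt[n] - tt[n - 1])
  structure(list(epsilon = eps, strain_rate = sr, length = L,
                 frame_times_ms = frame_times_ms, kind = kind,
                 chamber = chamber),
            class = "strain_curve")
}

## signed extremum: the value of largest magnitude, sign kept
## (most negative for a contracting contour)
peak_signed <- function(x) x[which.max(abs(x))]

#' Peak strain of a strain curve
#'
#' @param curve A `strain_curve`.
#' @return The signed extremum of the strain curve (%).
#' @export
peak_strain <- function(curve) peak_signed(curve$epsilon)

#' Global strain and strain-rate summary
#'
#' Global circumferential strain (GCS) is the arithmetic mean of the
#' per-slice peak strains over the basal, mid and apical short-axis
#' curves; global longitudinal strain (GLS) is the peak of the single
#' four-chamber curve. Peak values are signed extrema (most negative for
#' contraction); peak strain rates are summarized the same way.
#'
#' @param sax_curves List of (ideally 3) short-axis `strain_curve`s for
#'   the circumferential components; may be NULL.
#' @param long_curve Four-chamber `strain_curve` for the longitudinal
#'   components; may be NULL.
#' @param chamber `"LV"` or `"RV"`.
#' @return List of class `strain_summary` with `GCS`, `GLS` (%),
#'   `SR_circ`, `SR_long` (1/s), and `chamber`; components NA when the
#'   input curves are missing.
#' @export
global_strain <- function(sax_curves = NULL, long_curve = NULL,
                          chamber = c("LV", "RV")) {
  chamber <- match.arg(chamber)
  GCS <- SRc <- GLS <- SRl <- NA_real_
  if (!is.null(sax_curves) && length(sax_curves)) {
    if (length(sax_curves) < 3L)
      warning("only ", length(sax_curves),
              " short-axis curves available; global values use those")
    GCS <- mean(vapply(sax_curves, peak_strain, numeric(1)))
    SRc <- mean(vapply(sax_curves,
                       function(cv) peak_signed(cv$strain_rate),
                       numeric(1)))
  }
  if (!is.null(long_curve)) {
    GLS <- peak_strain(long_curve)
    SRl <- peak_signed(long_curve$strain_rate)
  }
  structure(list(GCS = GCS, GLS = GLS, SR_circ = SRc, SR_long = SRl,
                 chamber = chamber),
            class = "strain_summary")
}

#' @export
print.strain_summary <- function(x, ...) {
  cat(sprintf("%s strain summary: GCS %.1f%%, GLS %.1f%%, peak SR circ %.2f/s, long %.2f/s\n",
              x$chamber, x$GCS, x$GLS, x$SR_circ, x$SR_long))
  invisible(x)
}

#' @export
plot.strain_curve <- function(x, ...) {
  plot(x$frame_times_ms, x$epsilon, type = "b", xlab = "time [ms]",
       ylab = "strain [%]",
       main = paste(x$chamber, x$kind, "strain"), ...)
  invisible(x)
}
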