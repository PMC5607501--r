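#' @importFrom stats rnorm rbinom sd optim optimize coef glm binomial
#'   shapiro.test wilcox.test t.test predict quantile median lm runif
#' @importFrom utils head tail
NULL

## ---------------------------------------------------------------------------
## Specification constructors (validated parameter bundles for the generators)
## ---------------------------------------------------------------------------

#' Mono-exponential decay specification
#'
#' Bundles the parameters of a single-compartment transverse-relaxation decay
#' observed at a set of echo times, with Rician magnitude noise.
#'
#' @param s0 Signal amplitude at TE = 0 (arbitrary units, > 0).
#' @param t2 Transverse relaxation time in ms (> 0).
#' @param echo_times Strictly increasing vector of echo times in ms
#'   (at least two).
#' @param sigma Rician noise scale in the same units as `s0` (>= 0).
#'   `sigma = 0` gives the noiseless exponential exactly.
#' @return An object of class `decay_spec`.
#' @export
decay_spec <- function(s0, t2, echo_times, sigma = 0) {
  stopifnot(is.numeric(s0), length(s0) == 1L, is.finite(s0),
            is.numeric(t2), length(t2) == 1L, is.finite(t2),
            is.numeric(echo_times), length(echo_times) >= 2L,
            all(is.finite(echo_times)),
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (s0 <= 0) stop("s0 must be positive")
  if (t2 <= 0) stop("t2 must be positive")
  if (any(diff(echo_times) <= 0)) stop("echo_times must be strictly increasing")
  structure(list(s0 = s0, t2 = t2, echo_times = as.numeric(echo_times),
                 sigma = sigma),
            class = "decay_spec")
}

#' Annular heart-phantom specification
#'
#' Describes a short-axis myocardial annulus with optional focal lesions of
#' elevated, spatially heterogeneous T2 — the imaging signature of focal
#' myocardial edema.
#'
#' Each lesion is a sector of the annulus starting at `angle_deg` (degrees
#' from the RV-insertion ray, increasing in AHA segment order) and spanning
#' `extent_deg`; it occupies the outer (subepicardial) `transmural` fraction
#' of the wall; inside it the true T2 is `base_t2 + dt2` plus zero-mean
#' Gaussian jitter of SD `spread`.
#'
#' @param grid_size Image side length in pixels.
#' @param center Numeric length-2 pixel coordinates (x, y) of the LV center.
#' @param r_endo,r_epi Endocardial and epicardial radii in pixels
#'   (0 < r_endo < r_epi).
#' @param base_t2 Remote-myocardium T2 in ms.
#' @param lesions List of lesions, each a list/vector with elements
#'   `angle_deg`, `extent_deg`, `transmural`, `dt2`, `spread`.
#' @param rv_insertion_angle Angle (degrees) of the anterior RV-insertion
#'   point on the epicardium, in image convention (counterclockwise as
#'   displayed, 0 = +x axis).
#' @param s0 Proton-density amplitude for the decay signal.
#' @param sigma Rician noise scale of the simulated echoes.
#' @param echo_times Echo times (ms) of the simulated multi-echo acquisition.
#' @param n_slices Number of short-axis slices to replicate (default 3:
#'   basal, mid, apical).
#' @param seed Integer seed controlling lesion jitter and noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 64, center = NULL, r_endo = 12,
                         r_epi = 20, base_t2 = 55, lesions = list(),
                         rv_insertion_angle = 90, s0 = 1000, sigma = 0,
                         echo_times = seq(16, 96, by = 16), n_slices = 3,
                         seed = 1L) {
  if (is.null(center)) center <- c(grid_size, grid_size) / 2 + 0.5
  stopifnot(grid_size >= 8, length(center) == 2L,
            r_endo > 0, r_epi > r_endo, base_t2 > 0, sigma >= 0,
            n_slices >= 1)
  for (L in lesions) {
    L <- as.list(L)
    stopifnot(L$extent_deg > 0, L$extent_deg <= 360,
              L$transmural > 0, L$transmural <= 1)
    if (L$angle_deg < 0 || L$angle_deg >= 360)
      stop("lesion angle_deg must lie in [0, 360)")
  }
  structure(list(grid_size = grid_size, center = center, r_endo = r_endo,
                 r_epi = r_epi, base_t2 = base_t2, lesions = lesions,
                 rv_insertion_angle = rv_insertion_angle, s0 = s0,
                 sigma = sigma, echo_times = as.numeric(echo_times),
                 n_slices = as.integer(n_slices), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Deforming cine-phantom specification
#'
#' A closed end-diastolic contour deformed over one cardiac cycle by a
#' prescribed Lagrangian strain curve (perimeter strain, percent), with an
#' optional rigid per-frame translation, rendered as trackable image frames.
#'
#' @param contour Two-column matrix (x, y) of ordered end-diastolic contour
#'   points (>= 16, closed implicitly).
#' @param strain_curve Percent strain per frame; `strain_curve[1]` must be 0.
#' @param translation Either NULL (none) or an n_frames x 2 matrix of rigid
#'   offsets per frame.
#' @param noise_sd Additive Gaussian image-intensity noise SD (image peak is
#'   1).
#' @param grid_size Rendered frame side length in pixels.
#' @param frame_interval_ms Time between frames in ms (default 35).
#' @param seed Integer seed for the rendered noise.
#' @return An object of class `cine_spec`.
#' @export
cine_spec <- function(contour, strain_curve, translation = NULL,
                      noise_sd = 0, grid_size = 96, frame_interval_ms = 35,
                      seed = 1L) {
  contour <- as.matrix(contour)
  stopifnot(ncol(contour) == 2L, nrow(contour) >= 16L,
            is.numeric(strain_curve), length(strain_curve) >= 2L)
  if (abs(strain_curve[1]) > 1e-12) stop("strain_curve must start at 0")
  if (any(strain_curve <= -100)) stop("strain below -100% is not physical")
  n <- length(strain_curve)
  if (is.null(translation)) translation <- matrix(0, n, 2)
  translation <- as.matrix(translation)
  stopifnot(nrow(translation) == n, ncol(translation) == 2L, noise_sd >= 0)
  structure(list(contour = contour, strain_curve = as.numeric(strain_curve),
                 translation = translation, noise_sd = noise_sd,
                 grid_size = grid_size,
                 frame_interval_ms = frame_interval_ms,
                 seed = as.integer(seed)),
            class = "cine_spec")
}

#' Two-group cohort specification
#'
#' Gaussian generative model for a control/patient cohort over the imaging
#' parameters of the diagnostic analysis. Defaults reproduce the study
#' conditions of an acute-myocarditis cohort: 17 controls vs 67 patients,
#' per-parameter means and SDs for madSD, maxT2, meanT2, LV global
#' longitudinal/circumferential strain and longitudinal strain rate, and
#' per-group LGE positivity rates (0.52 in patients, 0 in controls).
#'
#' @param n_controls,n_patients Subject counts per group.
#' @param params Named list; each element is `c(mean_control, sd_control,
#'   mean_patient, sd_patient)`.
#' @param lge_rate_control,lge_rate_patient Bernoulli LGE-positivity
#'   probabilities per group.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 17, n_patients = 67,
                        params = cohort_reference_params(),
                        lge_rate_control = 0, lge_rate_patient = 0.52,
                        seed = 1L) {
  stopifnot(n_controls >= 1, n_patients >= 1,
            lge_rate_control >= 0, lge_rate_control <= 1,
            lge_rate_patient >= 0, lge_rate_patient <= 1,
            is.list(params), length(params) >= 1,
            !is.null(names(params)))
  for (p in params) {
    stopifnot(length(p) == 4L, p[2] >= 0, p[4] >= 0)
  }
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients), params = params,
                 lge_rate_control = lge_rate_control,
                 lge_rate_patient = lge_rate_patient,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Reference cohort parameters
#'
#' Group means and SDs (control mean, control SD, patient mean, patient SD)
#' for the simulated myocarditis cohort: madSD and maxT2 in ms, strains in
#' percent (negative = contraction), strain rate in 1/s.
#'
#' @return Named list of length-4 numeric vectors.
#' @export
cohort_reference_params <- function() {
  list(
    madSD_ms       = c(1.7, 1.0, 2.9, 1.4),
    maxT2_ms       = c(69, 11, 79, 13),
    meanT2_ms      = c(58, 5, 63, 6),
    meanSD_ms      = c(7.9, 2.3, 9.9, 3.1),
    GLS_LV_pct     = c(-17, 5, -14, 6),
    GCS_LV_pct     = c(-29, 4, -26, 4),
    SRlong_LV_per_s = c(-1.1, 0.3, -0.9, 0.4)
  )
}

## ---------------------------------------------------------------------------
## Generators
## ---------------------------------------------------------------------------

#' Simulate Rician-noise multi-echo decay signals
#'
#' Draws `n_pixels` independent pixels; each observed magnitude is
#' `sqrt((s0 * exp(-TE/t2) + g1)^2 + g2^2)` with `g1, g2 ~ N(0, sigma^2)` —
#' the magnitude of a complex Gaussian perturbation, the standard
#' construction of Rician magnitude noise.
#'
#' @param spec A [decay_spec()].
#' @param n_pixels Number of pixels (rows) to draw.
#' @param seed Optional integer seed; if supplied the draw is reproducible.
#' @return Numeric matrix, `n_pixels` x `length(echo_times)`, with echo
#'   times as column names.
#' @export
simulate_decay <- function(spec, n_pixels, seed = NULL) {
  stopifnot(inherits(spec, "decay_spec"), n_pixels >= 1)
  if (!is.null(seed)) set.seed(seed)
  nu <- spec$s0 * exp(-spec$echo_times / spec$t2)
  ne <- length(nu)
  if (spec$sigma == 0) {
    m <- matrix(nu, nrow = n_pixels, ncol = ne, byrow = TRUE)
  } else {
    g1 <- matrix(rnorm(n_pixels * ne, sd = spec$sigma), n_pixels, ne)
    g2 <- matrix(rnorm(n_pixels * ne, sd = spec$sigma), n_pixels, ne)
    m <- sqrt((matrix(nu, n_pixels, ne, byrow = TRUE) + g1)^2 + g2^2)
  }
  colnames(m) <- format(spec$echo_times, trim = TRUE)
  m
}

## Rician magnitudes for an arbitrary vector of noiseless intensities.
## Used internally by the phantom generator (per-pixel nu differ).
rician_sample <- function(nu, sigma) {
  if (sigma == 0) return(nu)
  sqrt((nu + rnorm(length(nu), sd = sigma))^2 +
         rnorm(length(nu), sd = sigma)^2)
}

#' Simulate an annular heart phantom with focal T2 lesions
#'
#' Builds, per slice, a ring-shaped myocardial mask, a ground-truth T2 field
#' (base T2 plus lesion elevations with intra-lesion jitter), and a
#' multi-echo magnitude stack generated pixel-wise by mono-exponential decay
#' with Rician noise. Lesions are placed subepicardially, occupying the
#' outer `transmural` fraction of the wall.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `heart_phantom` with elements `stack` (4-D array
#'   x, y, slice, echo), `mask` (3-D logical), `truth_t2` (3-D, NA outside
#'   mask), `echo_times`, `center`, `rv_insertion_angle`, `sigma`,
#'   `slice_labels`.
#' @export
simulate_heart_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- spec$grid_size
  xs <- matrix(seq_len(g), g, g)              # x = column-like first index
  ys <- matrix(seq_len(g), g, g, byrow = TRUE)
  dx <- xs - spec$center[1]
  dy <- ys - spec$center[2]
  r <- sqrt(dx^2 + dy^2)
  mask2d <- r >= spec$r_endo & r <= spec$r_epi
  if (!any(mask2d)) stop("empty annulus: no pixels between r_endo and r_epi")
  ## angle from RV insertion, counterclockwise as displayed, in [0, 360)
  ang <- (atan2(dy, dx) * 180 / pi - spec$rv_insertion_angle) %% 360
  ## transmural depth 0 at endo, 1 at epi
  depth <- (r - spec$r_endo) / (spec$r_epi - spec$r_endo)

  n_slices <- spec$n_slices
  ne <- length(spec$echo_times)
  stack <- array(0, dim = c(g, g, n_slices, ne))
  mask <- array(FALSE, dim = c(g, g, n_slices))
  truth <- array(NA_real_, dim = c(g, g, n_slices))

  for (s in seq_len(n_slices)) {
    t2f <- matrix(NA_real_, g, g)
    t2f[mask2d] <- spec$base_t2
    for (L in spec$lesions) {
      L <- as.list(L)
      a0 <- L$angle_deg %% 360
      in_sector <- ((ang - a0) %% 360) < L$extent_deg
      in_depth <- depth >= (1 - L$transmural)   # subepicardial placement
      sel <- mask2d & in_sector & in_depth
      n_sel <- sum(sel)
      if (n_sel) {
        jitter <- if (is.null(L$spread) || L$spread == 0) 0 else
          rnorm(n_sel, sd = L$spread)
        t2f[sel] <- t2f[sel] + L$dt2 + jitter
      }
    }
    t2f[mask2d] <- pmax(t2f[mask2d], 1)         # keep physical
    idx <- which(mask2d)
    for (e in seq_len(ne)) {
      sl <- matrix(0, g, g)
      nu <- spec$s0 * exp(-spec$echo_times[e] / t2f[idx])
      sl[idx] <- rician_sample(nu, spec$sigma)
      if (spec$sigma > 0) {
        bg <- which(!mask2d)
        sl[bg] <- rician_sample(rep(0, length(bg)), spec$sigma)
      }
      stack[, , s, e] <- sl
    }
    mask[, , s] <- mask2d
    truth[, , s] <- t2f
  }
  structure(list(stack = stack, mask = mask, truth_t2 = truth,
                 echo_times = spec$echo_times, center = spec$center,
                 rv_insertion_angle = spec$rv_insertion_angle,
                 sigma = spec$sigma,
                 slice_labels = slice_levels(n_slices)),
            class = "heart_phantom")
}

slice_levels <- function(n) {
  if (n == 3L) c("basal", "mid", "apical") else paste0("slice", seq_len(n))
}

#' Simulate a deforming cine phantom
#'
#' The end-diastolic contour is scaled about its centroid so that the
#' perimeter at frame t equals `perimeter(0) * (1 + strain(t)/100)`, then
#' rigidly translated. Frames render each contour vertex as a Gaussian blob
#' whose brightness varies along the contour, so every vertex is a
#' trackable local feature.
#'
#' @param spec A [cine_spec()].
#' @return A list of class `cine_phantom` with `frames` (3-D array x, y,
#'   frame), `contours` (list of per-frame ground-truth contour matrices),
#'   `frame_times_ms`, `strain_curve`.
#' @export
simulate_cine <- function(spec) {
  stopifnot(inherits(spec, "cine_spec"))
  set.seed(spec$seed)
  n <- length(spec$strain_curve)
  ed <- spec$contour
  ctr <- colMeans(ed)
  g <- spec$grid_size
  ## per-vertex brightness texture, fixed across frames
  np <- nrow(ed)
  amp <- 0.7 + 0.3 * sin(seq_len(np) * 2.4)
  frames <- array(0, dim = c(g, g, n))
  contours <- vector("list", n)
  xs <- matrix(seq_len(g), g, g)
  ys <- matrix(seq_len(g), g, g, byrow = TRUE)
  for (t in seq_len(n)) {
    sc <- 1 + spec$strain_curve[t] / 100   # perimeter scales linearly
    pts <- sweep(sweep(ed, 2, ctr), 2, c(sc, sc), "*")
    pts <- sweep(pts, 2, ctr + spec$translation[t, ], "+")
    contours[[t]] <- pts
    img <- matrix(0, g, g)
    for (k in seq_len(np)) {
      d2 <- (xs - pts[k, 1])^2 + (ys - pts[k, 2])^2
      img <- img + amp[k] * exp(-d2 / (2 * 1.8^2))
    }
    if (spec$noise_sd > 0) img <- img + rnorm(g * g, sd = spec$noise_sd)
    frames[, , t] <- img
  }
  structure(list(frames = frames, contours = contours,
                 frame_times_ms = (seq_len(n) - 1) * spec$frame_interval_ms,
                 strain_curve = spec$strain_curve),
            class = "cine_phantom")
}

## Location mu' of a zero-truncated Normal(mu', sd) whose truncated mean
## equals `target`: solves target = mu' + sd * dnorm(mu'/sd)/pnorm(mu'/sd).
trunc0_location <- function(target, sd) {
  if (sd == 0 || target / sd > 8) return(target)
  if (target <= 0) stop("truncated parameters need a positive mean")
  f <- function(mu) {
    a <- mu / sd
    mu + sd * stats::dnorm(a) / stats::pnorm(a) - target
  }
  stats::uniroot(f, lower = target - 6 * sd, upper = target,
                 tol = 1e-10)$root
}

#' Simulate a two-group diagnostic cohort
#'
#' Per-group independent Gaussian draws for every parameter in the spec
#' (madSD truncated at zero by rejection resampling), Bernoulli LGE status
#' per group, and a `group` factor. Parameters are drawn independently of
#' one another.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame of class `cohort_table`: `subject_id`, `group`
#'   (factor control/patient), one numeric column per parameter, `LGE`
#'   (integer 0/1).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_controls < 1 || spec$n_patients < 1)
    stop("both groups must contain at least one subject")
  set.seed(spec$seed)
  n <- spec$n_controls + spec$n_patients
  group <- factor(rep(c("control", "patient"),
                      c(spec$n_controls, spec$n_patients)),
                  levels = c("control", "patient"))
  out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), group = group,
                    stringsAsFactors = FALSE)
  truncate0 <- function(p) grepl("madSD", p) || grepl("meanSD", p)
  for (p in names(spec$params)) {
    v <- spec$params[[p]]
    if (truncate0(p)) {
      ## zero-truncated draws with the location recalibrated so the
      ## truncated mean equals the nominal group mean
      mu_c <- trunc0_location(v[1], v[2])
      mu_p <- trunc0_location(v[3], v[4])
      mu <- rep(c(mu_c, mu_p), c(spec$n_controls, spec$n_patients))
      sdv <- rep(c(v[2], v[4]), c(spec$n_controls, spec$n_patients))
      x <- rnorm(n, mu, sdv)
      bad <- which(x < 0)
      while (length(bad)) {            # rejection sampling above zero
        x[bad] <- rnorm(length(bad), mu[bad], sdv[bad])
        bad <- bad[x[bad] < 0]
      }
    } else {
      x <- c(rnorm(spec$n_controls, v[1], v[2]),
             rnorm(spec$n_patients, v[3], v[4]))
    }
    out[[p]] <- x
  }
  out$LGE <- c(rbinom(spec$n_controls, 1, spec$lge_rate_control),
               rbinom(spec$n_patients, 1, spec$lge_rate_patient))
  class(out) <- c("cohort_table", "data.frame")
  out
}
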