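## T2 relaxometry: per-pixel mono-exponential fitting of multi-echo
## magnitude data, by maximum likelihood under a Rician noise model, with an
## ordinary log-linear least-squares fit as initializer and comparator.

#' Rician log-likelihood of magnitude observations
#'
#' Sum over echoes of
#' `log(m/sigma^2) - (m^2 + nu^2)/(2 sigma^2) + log I0(m nu / sigma^2)`,
#' the log-density of magnitudes `m` with noiseless intensity `nu` and noise
#' scale `sigma`. The Bessel term uses the exponentially scaled `besselI`
#' so large arguments do not overflow.
#'
#' @param m Observed magnitudes (one per echo).
#' @param nu Noiseless intensities, same length.
#' @param sigma Noise scale (> 0).
#' @return Scalar log-likelihood.
#' @export
rician_loglik <- function(m, nu, sigma) {
  z <- m * nu / sigma^2
  sum(log(pmax(m, .Machine$double.xmin) / sigma^2) -
        (m^2 + nu^2) / (2 * sigma^2) + log_bessel_i0(z))
}

## log I0(z), overflow-safe: exponentially scaled Bessel for moderate z,
## uniform asymptotic expansion where the scaled Bessel underflows.
log_bessel_i0 <- function(z) {
  out <- numeric(length(z))
  small <- z < 700
  if (any(small))
    out[small] <- log(besselI(z[small], 0, expon.scaled = TRUE)) + z[small]
  if (any(!small)) {
    zb <- z[!small]
    out[!small] <- zb - 0.5 * log(2 * pi * zb) +
      log1p(1 / (8 * zb) + 9 / (128 * zb^2))
  }
  out
}

#' Log-linear least-squares T2 fit for one pixel
#'
#' Ordinary least squares of `log(m)` on echo time; `t2 = -1/slope`.
#' Ignores the Rician noise floor, so it overestimates T2 at low SNR; used
#' as the initializer and bias comparator for the maximum-likelihood fit.
#' Non-positive magnitudes are excluded echo-wise.
#'
#' @param m Magnitudes per echo.
#' @param te Echo times (ms).
#' @return List with `t2`, `s0`, `status` (one of `"ok"`, `"failed"`).
#' @export
fit_pixel_loglinear <- function(m, te) {
  stopifnot(length(m) == length(te))
  use <- which(m > 0)
  if (length(use) < 3L)
    return(list(t2 = NA_real_, s0 = NA_real_, status = "failed"))
  x <- te[use]; y <- log(m[use])
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  if (slope >= 0)
    return(list(t2 = NA_real_, s0 = NA_real_, status = "failed"))
  list(t2 = -1 / slope, s0 = exp(yb - slope * xb), status = "ok")
}

#' Rician maximum-likelihood T2 fit for one pixel
#'
#' Maximizes the summed Rician log-likelihood over `(s0, t2)` with the
#' noise scale treated as known, starting from the log-linear fit and using
#' bounded quasi-Newton (`L-BFGS-B`) in `(log s0, t2)`. If the optimizer
#' fails to converge, a coarse grid search over t2 (profile-optimal s0 per
#' candidate) restarts it. Solutions at the T2 bounds are flagged.
#'
#' @param m Magnitudes per echo (>= 3 echoes).
#' @param te Echo times (ms).
#' @param sigma Known noise scale (> 0).
#' @param t2_bounds Search interval for T2 in ms; default `c(1, 300)`
#'   covers the myocardial range with headroom.
#' @return List with `t2`, `s0`, `status` in
#'   `{"ok", "clipped_low", "clipped_high", "failed"}`, and `loglik`.
#' @export
fit_pixel_mle <- function(m, te, sigma, t2_bounds = c(1, 300)) {
  stopifnot(length(m) == length(te), length(m) >= 3L)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (all(m == 0))
    return(list(t2 = NA_real_, s0 = NA_real_, status = "failed",
                loglik = NA_real_))
  ll <- fit_pixel_loglinear(m, te)
  s0_init <- if (ll$status == "ok") ll$s0 else max(m)
  t2_init <- if (ll$status == "ok") ll$t2 else mean(t2_bounds)
  t2_init <- min(max(t2_init, t2_bounds[1]), t2_bounds[2])
  s0_init <- max(s0_init, sigma * 1e-3)

  negll <- function(p) {
    nu <- exp(p[1]) * exp(-te / p[2])
    -rician_loglik(m, nu, sigma)
  }
  lower <- c(log(sigma * 1e-6), t2_bounds[1])
  upper <- c(log(max(m) * 1e3 + sigma), t2_bounds[2])
  fit <- tryCatch(
    optim(c(log(s0_init), t2_init), negll, method = "L-BFGS-B",
          lower = lower, upper = upper),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    ## grid-search restart: profile s0 at each candidate t2
    t2g <- seq(t2_bounds[1], t2_bounds[2], length.out = 60)
    vals <- vapply(t2g, function(t2) {
      op <- optimize(function(ls0) negll(c(ls0, t2)), lower = lower[1],
                     upper = upper[1])
      op$objective
    }, numeric(1))
    t2_init <- t2g[which.min(vals)]
    fit <- tryCatch(
      optim(c(log(s0_init), t2_init), negll, method = "L-BFGS-B",
            lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(fit))
      return(list(t2 = NA_real_, s0 = NA_real_, status = "failed",
                  loglik = NA_real_))
  }
  t2 <- fit$par[2]
  eps <- 1e-6 * diff(t2_bounds)
  status <- if (t2 <= t2_bounds[1] + eps) "clipped_low"
            else if (t2 >= t2_bounds[2] - eps) "clipped_high"
            else "ok"
  list(t2 = t2, s0 = exp(fit$par[1]), status = status, loglik = -fit$value)
}

#' Estimate the Rician noise scale from a background region
#'
#' In a signal-free region magnitude noise is Rayleigh with
#' `E[m^2] = 2 sigma^2`, so `sigma = RMS(background) / sqrt(2)`. Computed
#' per slice.
#'
#' @param stack 4-D array (x, y, slice, echo) of magnitudes, or a
#'   `heart_phantom`.
#' @param background_mask 3-D logical array marking signal-free pixels.
#' @return Numeric vector, one sigma per slice.
#' @export
estimate_sigma <- function(stack, background_mask) {
  if (inherits(stack, "heart_phantom")) stack <- stack$stack
  stopifnot(length(dim(stack)) == 4L, length(dim(background_mask)) == 3L)
  n_slices <- dim(stack)[3]
  vapply(seq_len(n_slices), function(s) {
    bg <- as.vector(background_mask[, , s])
    if (!any(bg)) stop("background mask is empty for slice ", s)
    sl <- matrix(stack[, , s, ], length(bg), dim(stack)[4])
    sqrt(mean(sl[bg, ]^2) / 2)
  }, numeric(1))
}

#' Fit a pixel-wise T2 map
#'
#' Applies the chosen per-pixel fit to every masked pixel of a multi-echo
#' stack and assembles a T2 map with per-pixel fit status.
#'
#' @param stack 4-D array (x, y, slice, echo) or a `heart_phantom` (whose
#'   mask and echo times are then used by default).
#' @param mask 3-D logical array of myocardial pixels.
#' @param echo_times Echo times in ms (taken from the phantom if omitted).
#' @param method `"rician_mle"` (default) or `"loglinear"`.
#' @param sigma Known per-slice noise scale (scalar recycled, or one value
#'   per slice). Required for the MLE; estimate it with [estimate_sigma()].
#' @param t2_bounds T2 search bounds in ms.
#' @param max_fail_frac Abort if more than this fraction of masked pixels
#'   fail (default 0.5).
#' @return An object of class `t2map`: list with `t2` (3-D, NA where not
#'   fitted), `s0`, `status` (3-D character), `method`, `echo_times`,
#'   `sigma`, `slice_labels`.
#' @export
fit_t2_map <- function(stack, mask = NULL, echo_times = NULL,
                       method = c("rician_mle", "loglinear"), sigma = NULL,
                       t2_bounds = c(1, 300), max_fail_frac = 0.5) {
  method <- match.arg(method)
  if (inherits(stack, "heart_phantom")) {
    if (is.null(mask)) mask <- stack$mask
    if (is.null(echo_times)) echo_times <- stack$echo_times
    if (is.null(sigma) && stack$sigma > 0) sigma <- stack$sigma
    stack <- stack$stack
  }
  stopifnot(length(dim(stack)) == 4L, !is.null(mask), !is.null(echo_times),
            dim(stack)[4] == length(echo_times))
  n_slices <- dim(stack)[3]
  if (method == "rician_mle") {
    if (is.null(sigma)) stop("sigma is required for the Rician MLE fit")
    sigma <- rep(sigma, length.out = n_slices)
  }
  dims <- dim(stack)[1:3]
  t2 <- array(NA_real_, dims)
  s0 <- array(NA_real_, dims)
  status <- array("absent", dims)
  n_fail <- 0L; n_tot <- 0L
  for (s in seq_len(n_slices)) {
    idx <- which(mask[, , s])
    if (!length(idx)) next
    sl <- matrix(stack[, , s, ], prod(dims[1:2]), dim(stack)[4])
    for (i in idx) {
      m <- sl[i, ]
      f <- if (method == "rician_mle")
        fit_pixel_mle(m, echo_times, sigma[s], t2_bounds)
      else fit_pixel_loglinear(m, echo_times)
      n_tot <- n_tot + 1L
      if (f$status == "failed") n_fail <- n_fail + 1L
      arr_i <- arrayInd(i, dims[1:2])
      t2[arr_i[1], arr_i[2], s] <- f$t2
      s0[arr_i[1], arr_i[2], s] <- f$s0
      status[arr_i[1], arr_i[2], s] <- f$status
    }
  }
  if (n_tot > 0 && n_fail / n_tot > max_fail_frac)
    stop(sprintf("T2 fit failed for %d of %d masked pixels", n_fail, n_tot))
  structure(list(t2 = t2, s0 = s0, status = status, method = method,
                 echo_times = echo_times,
                 sigma = if (method == "rician_mle") sigma else NA_real_,
                 slice_labels = slice_levels(n_slices)),
            class = "t2map")
}

#' @export
print.t2map <- function(x, ...) {
  ok <- x$status == "ok"
  cat("Pixel-wise T2 map (", x$method, ")\n", sep = "")
  cat("  slices:", paste(x$slice_labels, collapse = ", "), "\n")
  cat("  fitted pixels:", sum(x$status != "absent"),
      "(ok:", sum(ok), ")\n")
  if (any(ok))
    cat(sprintf("  T2 range (ok): %.1f - %.1f ms, median %.1f ms\n",
                min(x$t2[ok]), max(x$t2[ok]), median(x$t2[ok])))
  invisible(x)
}

#' @export
summary.t2map <- function(object, ...) {
  ok <- object$status == "ok"
  data.frame(
    slice = object$slice_labels,
    n_fitted = vapply(seq_along(object$slice_labels), function(s)
      sum(object$status[, , s] != "absent"), integer(1)),
    n_ok = vapply(seq_along(object$slice_labels), function(s)
      sum(object$status[, , s] == "ok"), integer(1)),
    mean_t2_ms = vapply(seq_along(object$slice_labels), function(s) {
      v <- object$t2[, , s][object$status[, , s] == "ok"]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  )
}
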