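#' Flickering-checkerboard stimulus
#'
#' Generates the binary white-noise checkerboard used for receptive-field
#' mapping: a grid of rectangular fields (3.7 deg wide, 2.9 deg high),
#' each field modulated independently by binary white noise at the update
#' rate. Values are coded {0, 1} and mean-subtracted at analysis time.
#'
#' @param nx,ny Grid size in fields (defaults 19 x 15, covering roughly the
#'   70 x 44 deg stimulated visual field).
#' @param update_hz Update rate in Hz (default 4).
#' @param duration_s Stimulus duration in seconds (default 600, i.e. 10 min).
#' @param bin_s Analysis bin width in seconds (default 1/60 s = 16.7 ms);
#'   must evenly subdivide the update interval.
#' @param seed Integer seed; the movie is reproducible.
#' @return An object of class `checker_stimulus`: list with `frames`
#'   (fields x update-frames 0/1 matrix, fields in column-major `(x, y)`
#'   order), `nx`, `ny`, `update_hz`, `bin_s`, `field_deg` and `seed`.
#' @examples
#' stim <- checkerboard(duration_s = 10, seed = 1)
#' dim(stim$frames)
#' @export
checkerboard <- function(nx = 19, ny = 15, update_hz = 4, duration_s = 600,
                         bin_s = 1 / 60, seed = 1) {
  nx <- stopifnot_scalar_count(nx, "nx")
  ny <- stopifnot_scalar_count(ny, "ny")
  n_frames <- round(duration_s * update_hz)
  if (n_frames < 1) abort("stimulus duration too short for one frame")
  reps <- round(1 / (update_hz * bin_s))
  if (abs(reps - 1 / (update_hz * bin_s)) > 1e-6 || reps < 1) {
    abort("`bin_s` must evenly subdivide the update interval")
  }
  frames <- with_seed(seed, {
    matrix(as.integer(runif(nx * ny * n_frames) < 0.5), nx * ny, n_frames)
  })
  structure(list(frames = frames, nx = nx, ny = ny, update_hz = update_hz,
                 bin_s = bin_s, field_deg = c(width = 3.7, height = 2.9),
                 seed = seed),
            class = "checker_stimulus")
}

# Expand the update-rate movie onto the analysis bin clock.
stimulus_bins <- function(stimulus) {
  reps <- round(1 / (stimulus$update_hz * stimulus$bin_s))
  stimulus$frames[, rep(seq_len(ncol(stimulus$frames)), each = reps),
                  drop = FALSE]
}

#' Receptive-field estimation by reverse correlation
#'
#' Computes the response-weighted average (RWA) of the mean-subtracted
#' stimulus over a trailing window: for each spatial field and lag bin, the
#' activity-weighted mean of the stimulus value `lag` bins before each
#' activity sample.
#'
#' @param activity Numeric activity trace on the stimulus bin clock (one
#'   value per `bin_s`), e.g. from [simulate_rf_unit()].
#' @param stimulus A [checkerboard()] stimulus.
#' @param window_s RWA window length in seconds (default 0.5).
#' @return An object of class `rf_kernel`: list with `kernel` (fields x
#'   lags matrix), `lags_s`, `nx`, `ny`.
#' @export
reverse_correlation <- function(activity, stimulus, window_s = 0.5) {
  if (inherits(activity, "rf_unit")) activity <- activity$activity
  s <- stimulus_bins(stimulus)
  n <- min(length(activity), ncol(s))
  activity <- activity[seq_len(n)]
  s <- s[, seq_len(n), drop = FALSE]
  denom <- sum(abs(activity))
  if (denom == 0) abort("activity trace is identically zero")
  n_lags <- round(window_s / stimulus$bin_s)
  sc <- s - rowMeans(s)
  # lag-embedded activity: column l holds the activity l-1 bins after each
  # stimulus bin, so kernel = sc %*% A in one BLAS call
  A <- matrix(0, n, n_lags)
  for (l in seq_len(n_lags)) {
    A[seq_len(n - l + 1L), l] <- activity[seq.int(l, n)]
  }
  kernel <- (sc %*% A) / denom
  structure(list(kernel = kernel, lags_s = (seq_len(n_lags) - 1) * stimulus$bin_s,
                 nx = stimulus$nx, ny = stimulus$ny),
            class = "rf_kernel")
}

gauss2d <- function(x, y, amp, x0, y0, sx, sy, theta, offset) {
  ct <- cos(theta); st <- sin(theta)
  xr <- (x - x0) * ct + (y - y0) * st
  yr <- -(x - x0) * st + (y - y0) * ct
  amp * exp(-(xr^2 / (2 * sx^2) + yr^2 / (2 * sy^2))) + offset
}

#' Fit a 2-D Gaussian receptive field to a reverse-correlation kernel
#'
#' Picks the peak latency as the lag with the largest spatially-summed
#' absolute kernel, then fits an elliptical 2-D Gaussian (amplitude, center,
#' long/short-axis standard deviations, orientation, offset) to the spatial
#' slice at that latency by nonlinear least squares with moment-based
#' initialization. The RF size is twice the mean of the long- and
#' short-axis standard deviations.
#'
#' @param kernel An `rf_kernel` from [reverse_correlation()].
#' @return An object of class `rf_fit`: list with `center` (x, y in
#'   fields), `sd_long`, `sd_short`, `theta`, `size` (= `sd_long +
#'   sd_short`, i.e. twice the mean SD), `peak_latency_s`, `amplitude`,
#'   `converged` and `r_squared`. Non-convergent fits are flagged with
#'   `size = NA`.
#' @export
fit_rf <- function(kernel) {
  if (!inherits(kernel, "rf_kernel")) abort("`kernel` must come from reverse_correlation()")
  power <- colSums(abs(kernel$kernel))
  peak_lag <- which.max(power)
  slice <- kernel$kernel[, peak_lag]
  if (max(abs(slice)) == 0) {
    return(structure(list(center = c(NA, NA), sd_long = NA_real_,
                          sd_short = NA_real_, theta = NA_real_,
                          size = NA_real_,
                          peak_latency_s = kernel$lags_s[peak_lag],
                          amplitude = 0, converged = FALSE,
                          r_squared = NA_real_),
                     class = "rf_fit"))
  }
  sign_flip <- sign(slice[which.max(abs(slice))])
  z <- slice * sign_flip
  x <- rep(seq_len(kernel$nx), times = kernel$ny)
  y <- rep(seq_len(kernel$ny), each = kernel$nx)
  # moment initialization on the positive part
  w <- pmax(z - stats::quantile(z, 0.75), 0)
  if (sum(w) == 0) w <- pmax(z, 0)
  x0 <- sum(w * x) / sum(w); y0 <- sum(w * y) / sum(w)
  sx0 <- sqrt(sum(w * (x - x0)^2) / sum(w)) %||% 1
  sy0 <- sqrt(sum(w * (y - y0)^2) / sum(w)) %||% 1
  sx0 <- max(sx0, 0.3); sy0 <- max(sy0, 0.3)
  dat <- data.frame(x = x, y = y, z = z)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ gauss2d(x, y, amp, x0, y0, sx, sy, theta, offset),
      data = dat,
      start = list(amp = max(z), x0 = x0, y0 = y0, sx = sx0, sy = sy0,
                   theta = 0, offset = 0),
      lower = c(amp = 0, x0 = 0, y0 = 0, sx = 0.05, sy = 0.05,
                theta = -pi, offset = -Inf),
      upper = c(amp = Inf, x0 = kernel$nx + 1, y0 = kernel$ny + 1,
                sx = kernel$nx, sy = kernel$ny, theta = pi, offset = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(center = c(NA, NA), sd_long = NA_real_,
                          sd_short = NA_real_, theta = NA_real_,
                          size = NA_real_,
                          peak_latency_s = kernel$lags_s[peak_lag],
                          amplitude = max(abs(slice)), converged = FALSE,
                          r_squared = NA_real_),
                     class = "rf_fit"))
  }
  cf <- coef(fit)
  sds <- sort(c(cf[["sx"]], cf[["sy"]]), decreasing = TRUE)
  rsq <- 1 - sum(stats::residuals(fit)^2) / sum((z - mean(z))^2)
  structure(list(center = c(x = cf[["x0"]], y = cf[["y0"]]),
                 sd_long = sds[1], sd_short = sds[2], theta = cf[["theta"]],
                 size = sds[1] + sds[2],
                 peak_latency_s = kernel$lags_s[peak_lag],
                 amplitude = cf[["amp"]] * sign_flip, converged = TRUE,
                 r_squared = rsq),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("<rf_fit> center (%.2f, %.2f) fields, size %.2f fields, peak %.0f ms, R^2 %.3f\n",
                x$center[1], x$center[2], x$size, 1000 * x$peak_latency_s,
                x$r_squared))
  } else cat("<rf_fit> non-convergent (no RF structure)\n")
  invisible(x)
}

#' @rdname fit_rf
#' @param x An `rf_fit` object.
#' @param ... Unused.
#' @export
tidy.rf_fit <- function(x, ...) {
  tibble(center_x = x$center[1], center_y = x$center[2],
         sd_long = x$sd_long, sd_short = x$sd_short, theta = x$theta,
         size = x$size, peak_latency_s = x$peak_latency_s,
         amplitude = x$amplitude, converged = x$converged,
         r_squared = x$r_squared)
}
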