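#' Per-trial aversive responses of every cell
#'
#' Computes, for each cell and each analyzed aversive-outcome trial, the
#' time-averaged z-scored response over the outcome window,
#' `zbar_k = <Z(t)>_t`. Z-scoring is within-epoch; trials are ordered by
#' presentation, and the within-epoch aversive index `j` (1..36 at the
#' default design) is attached for decay tiling.
#'
#' @param recording A [simulate_recording()] result.
#' @param exclude_excursion Drop trials above the 0.25 mm excursion
#'   threshold (default `FALSE`: trajectories keep all aversive trials so
#'   every stimulus type retains its full balanced trial count).
#' @return Tibble with columns `cell`, `k_av` (aversive trial index, 1-based
#'   over the analyzed task), `j` (within-epoch aversive index), `epoch`,
#'   `type` (aversive subtype) and `zbar`.
#' @export
aversive_trial_responses <- function(recording, exclude_excursion = FALSE) {
  cfg <- attr(recording$session, "config")
  window <- round(cfg$outcome_duration_s * recording$frame_rate)
  out <- list()
  for (ep in c("ES", "LS", "VL")) {
    Z <- zscore_epoch(recording, ep)
    frames <- attr(Z, "frames")
    ev <- recording$events |>
      dplyr::filter(.data$epoch == !!ep, .data$outcome == "aversive")
    if (exclude_excursion) {
      ev <- ev[recording$excursion[ev$trial] <= 0.25, , drop = FALSE]
    }
    ons <- ev$outcome_onset_frame - frames[1] + 1L
    zb <- vapply(ons, function(on) {
      rowMeans(Z[, seq.int(on, on + window - 1L), drop = FALSE])
    }, numeric(nrow(Z)))
    out[[ep]] <- tibble(
      cell = rep(seq_len(nrow(Z)), times = length(ons)),
      k = rep(ev$k, each = nrow(Z)),
      j = rep(seq_along(ons), each = nrow(Z)),
      epoch = ep,
      type = rep(ev$aversive_type, each = nrow(Z)),
      zbar = as.numeric(zb)
    )
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$cell, .data$k) |>
    dplyr::group_by(.data$cell) |>
    dplyr::mutate(k_av = dplyr::row_number(), .after = "cell") |>
    dplyr::ungroup() |>
    dplyr::mutate(epoch = factor(.data$epoch, levels = c("ES", "LS", "VL")))
}

#' Stimulus-type-normalized neuronal trajectory
#'
#' Subtracts, per cell and aversive stimulus type, the mean response of that
#' type across all three epochs (18 trials per type at defaults):
#' `dz_k = zbar_k - <zbar_k | type>`. The concatenated per-cell series in
#' presentation order is the neuronal trajectory, independent of the
#' stimulus type.
#'
#' @param responses Tibble from [aversive_trial_responses()] (or any tibble
#'   with `cell`, `k_av`, `type`, `zbar`).
#' @param session Optional session used to validate that every configured
#'   aversive type is present.
#' @return The input tibble with a `dz` column appended.
#' @export
stimulus_normalized_trajectory <- function(responses, session = NULL) {
  if (!is.null(session)) {
    cfg <- attr(session, "config")
    expected <- aversive_type_names(cfg$n_aversive_types)
    missing <- setdiff(expected, unique(responses$type))
    if (length(missing)) {
      abort(paste("missing aversive types:", paste(missing, collapse = ", ")))
    }
  }
  responses |>
    dplyr::group_by(.data$cell, .data$type) |>
    dplyr::mutate(dz = .data$zbar - mean(.data$zbar)) |>
    dplyr::ungroup()
}

#' Fit the population photobleaching decay curve
#'
#' Fits the power function `f(j) = a * j^b + c` by nonlinear least squares
#' to the population average of all neuronal trajectories, averaged across
#' epochs onto the within-epoch aversive-trial index `j` (1..36 at
#' defaults). The fit is multi-started over `b` in {-1, -0.5, -0.1} with
#' moment-based `a`, `c` starts; the best sum of squared errors is kept.
#'
#' @param trajectories Tibble from [stimulus_normalized_trajectory()]
#'   (needs `cell`, `j`, `dz`).
#' @return An object of class `decay_fit`: list with `coefficients`
#'   (a, b, c), `curve` (tibble of `j`, observed mean, fitted), `residual_sd`
#'   and `converged`. `tidy()`/`glance()` methods are provided.
#' @export
fit_decay <- function(trajectories) {
  if (dplyr::n_distinct(trajectories$cell) < 2L) {
    abort("decay fitting needs at least two cells")
  }
  curve <- trajectories |>
    dplyr::group_by(.data$j) |>
    dplyr::summarise(mean_dz = mean(.data$dz), .groups = "drop") |>
    dplyr::arrange(.data$j)
  y <- curve$mean_dz
  x <- curve$j
  if (any(!is.finite(y))) abort("non-finite values in the population trajectory")
  # For fixed b the model is linear in (a, c): profile the SSE over b on a
  # grid, refine with 1-D optimization, then polish the full triple with
  # Levenberg-Marquardt. Power-law fits are initialization-sensitive; the
  # profile makes the solution robust, including the degenerate flat case
  # (a ~ 0, b unidentifiable).
  prof <- function(b) {
    ft <- stats::lm.fit(cbind(x^b, 1), y)
    sum(ft$residuals^2)
  }
  grid <- seq(-3, 3, by = 0.1)
  grid <- grid[grid != 0]
  sse_grid <- vapply(grid, prof, numeric(1))
  b0 <- grid[which.min(sse_grid)]
  opt <- stats::optimize(prof, c(b0 - 0.1, b0 + 0.1))
  b_hat <- opt$minimum
  ac <- stats::lm.fit(cbind(x^b_hat, 1), y)$coefficients
  cf <- c(a = unname(ac[1]), b = b_hat, c = unname(ac[2]))
  polish <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^b + c, data = data.frame(x = x, y = y),
                      start = as.list(cf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (!is.null(polish) &&
      sum(stats::residuals(polish)^2) <= opt$objective + 1e-12) {
    cfp <- coef(polish)
    cf <- c(a = cfp[["a"]], b = cfp[["b"]], c = cfp[["c"]])
  }
  fitted_y <- cf[["a"]] * x^cf[["b"]] + cf[["c"]]
  structure(
    list(coefficients = cf,
         curve = tibble(j = x, mean_dz = y, fitted = fitted_y),
         residual_sd = sd(y - fitted_y),
         converged = TRUE),
    class = "decay_fit"
  )
}

#' Evaluate a fitted decay curve
#'
#' @param fit A `decay_fit`.
#' @param j Within-epoch trial indices.
#' @return `a * j^b + c`.
#' @export
decay_curve <- function(fit, j) {
  cf <- fit$coefficients
  cf[["a"]] * j^cf[["b"]] + cf[["c"]]
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> f(j) = %.4g * j^%.4g + %.4g (residual SD %.4g)\n",
              x$coefficients[["a"]], x$coefficients[["b"]],
              x$coefficients[["c"]], x$residual_sd))
  invisible(x)
}

#' @rdname fit_decay
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname fit_decay
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(residual_sd = x$residual_sd, converged = x$converged,
         n_points = nrow(x$curve))
}

#' Remove the scaled decay from each cell's trajectory
#'
#' Subtracts `d * f(j)` from every cell's trajectory, with the fitted decay
#' curve tiled per epoch (the within-epoch index `j` restarts at 1 each
#' epoch) and a single scalar `d` per cell shared across epochs, so the
#' context-dependent epoch structure is untouched. `d` is the
#' ordinary-least-squares projection coefficient of the cell's trajectory
#' onto the tiled curve, which makes the residual's Pearson correlation
#' with the decay exactly zero (well inside the +/-0.05 requirement).
#'
#' @param trajectories Tibble from [stimulus_normalized_trajectory()].
#' @param fit A [fit_decay()] result.
#' @return List with `trajectories` (input plus `f` and `dz_res` columns)
#'   and `d` (per-cell tibble of projection coefficients).
#' @export
remove_decay <- function(trajectories, fit) {
  f_tiled <- decay_curve(fit, trajectories$j)
  if (var(f_tiled) < .Machine$double.eps) {
    warn("fitted decay curve is constant; d set to 0 for all cells")
    traj <- trajectories |>
      dplyr::mutate(f = f_tiled, dz_res = .data$dz)
    d <- traj |> dplyr::distinct(.data$cell) |> dplyr::mutate(d = 0)
    return(list(trajectories = traj, d = d))
  }
  traj <- trajectories |>
    dplyr::mutate(f = f_tiled) |>
    dplyr::group_by(.data$cell) |>
    dplyr::mutate(d = stats::cov(.data$dz, .data$f) / stats::var(.data$f),
                  dz_res = .data$dz - .data$d * .data$f) |>
    dplyr::ungroup()
  d <- traj |> dplyr::distinct(.data$cell, .data$d)
  list(trajectories = traj |> dplyr::select(-"d"), d = d)
}

# Wide cells x trials matrix of a trajectory column.
trajectory_matrix <- function(trajectories, value = "dz_res") {
  wide <- trajectories |>
    dplyr::select("cell", "k_av", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "k_av", values_from = dplyr::all_of(value)) |>
    dplyr::arrange(.data$cell)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$cell
  m
}
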