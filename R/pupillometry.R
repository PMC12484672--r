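#' Pupil area from the long-axis diameter
#'
#' Converts a per-frame long-axis pupil diameter (pixels) to the estimated
#' circular area in mm^2, `A = pi * (D/2)^2 / calibration`. The long-axis
#' convention makes the measure invariant to eye position (a circular pupil
#' on a spherical eyeball projects to an ellipse whose long axis is
#' preserved). Non-positive or missing diameters become missing frames.
#'
#' @param diameter_px Numeric vector of long-axis diameters in pixels, or a
#'   `pupil_raw` object from [simulate_pupil()].
#' @param calibration Pixels-squared per mm-squared (default 6e3).
#' @return Numeric vector of areas in mm^2 (`NA` for invalid frames).
#' @export
area_from_long_axis <- function(diameter_px, calibration = 6e3) {
  if (inherits(diameter_px, "pupil_raw")) {
    calibration <- diameter_px$calibration
    diameter_px <- diameter_px$diameter_px
  }
  a <- pi * (diameter_px / 2)^2 / calibration
  a[!is.finite(a) | diameter_px <= 0] <- NA_real_
  a
}

#' Evoked pupil traces and epoch-normalized dilation
#'
#' For each analysis epoch, aligns the pupil-area series to the aversive
#' outcome onsets, normalizes each trial by its baseline `A0` (mean area
#' over the 10 frames before onset), averages the proportional change over
#' trials, `a(t) = <A(t)/A0>_trials`, then time-averages over the 2-s
#' outcome window, `abar = <a(t)>_t`, and subtracts the across-epoch mean,
#' `da = abar - <abar>_epochs` (zero-sum across epochs). Trials with more
#' than `max_missing` missing frames in the baseline or window are dropped.
#'
#' @param pupil A `pupil_raw` object, or a numeric area series (mm^2) if
#'   `events` is supplied.
#' @param events Event table with `epoch`, `outcome` and
#'   `outcome_onset_frame` (taken from `pupil` when absent).
#' @param frame_rate Frames per second (taken from `pupil` when absent).
#' @param window_s Averaging window from outcome onset (default 2 s).
#' @param baseline_frames Baseline length before onset (default 10 frames).
#' @param max_missing Maximum tolerated fraction of missing frames per
#'   trial segment (default 0.2).
#' @return An object of class `pupil_response`: list with `trace` (tibble:
#'   epoch, `t`, `a`), `summary` (tibble: epoch, `abar`, `da`, `n_trials`,
#'   `n_dropped`), and `median_area` (mm^2, over all frames).
#' @export
evoked_trace <- function(pupil, events = NULL, frame_rate = NULL,
                         window_s = 2, baseline_frames = 10,
                         max_missing = 0.2) {
  if (inherits(pupil, "pupil_raw")) {
    events <- events %||% pupil$events
    frame_rate <- frame_rate %||% pupil$frame_rate
    A <- area_from_long_axis(pupil)
  } else {
    A <- pupil
    if (is.null(events) || is.null(frame_rate)) {
      abort("supply `events` and `frame_rate` with a bare area series")
    }
  }
  window <- round(window_s * frame_rate)
  traces <- list(); summaries <- list()
  for (ep in c("ES", "LS", "VL")) {
    ev <- events |>
      dplyr::filter(.data$epoch == !!ep, .data$outcome == "aversive")
    segs <- list(); dropped <- 0L
    for (on in ev$outcome_onset_frame) {
      if (on - baseline_frames < 1 || on + window - 1 > length(A)) {
        dropped <- dropped + 1L
        next
      }
      base <- A[seq.int(on - baseline_frames, on - 1L)]
      seg <- A[seq.int(on - baseline_frames, on + window - 1L)]
      if (mean(is.na(base)) > max_missing ||
          mean(is.na(seg[-seq_len(baseline_frames)])) > max_missing) {
        dropped <- dropped + 1L
        next
      }
      a0 <- mean(base, na.rm = TRUE)
      segs[[length(segs) + 1L]] <- seg / a0
    }
    if (length(segs) == 0L) {
      abort(sprintf("no usable aversive trials in epoch %s", ep))
    }
    a_t <- colMeans(do.call(rbind, segs), na.rm = TRUE)
    t_rel <- (seq_along(a_t) - baseline_frames - 1) / frame_rate
    traces[[ep]] <- tibble(epoch = ep, t = t_rel, a = a_t)
    summaries[[ep]] <- tibble(
      epoch = ep,
      abar = mean(a_t[t_rel >= 0 & t_rel < window_s]),
      n_trials = length(segs), n_dropped = dropped)
  }
  summary <- dplyr::bind_rows(summaries) |>
    dplyr::mutate(da = .data$abar - mean(.data$abar),
                  epoch = factor(.data$epoch, levels = c("ES", "LS", "VL")))
  structure(
    list(trace = dplyr::bind_rows(traces) |>
           dplyr::mutate(epoch = factor(.data$epoch,
                                        levels = c("ES", "LS", "VL"))),
         summary = summary,
         median_area = median(A, na.rm = TRUE)),
    class = "pupil_response"
  )
}

#' @export
print.pupil_response <- function(x, ...) {
  cat("<pupil_response> median area", sprintf("%.3f mm^2", x$median_area), "\n")
  print(as.data.frame(x$summary))
  invisible(x)
}

#' Group statistics for pupillometry
#'
#' Compares median pupil areas between two groups with a Mann-Whitney
#' U-test, fits the two-way ANOVA of the epoch-normalized dilation `da`
#' (Group x Epoch, full interaction), and performs Tukey-Kramer pairwise
#' epoch comparisons within each group.
#'
#' @param data Tibble with one row per animal and epoch: `mouse`, `group`,
#'   `epoch`, `da`, `median_area`.
#' @return List of class `pupil_stats`: `mann_whitney` (tibble or `NULL`
#'   when not exactly two groups), `anova` (tibble), `pairwise`
#'   (Tukey-Kramer contrasts), and the fitted model. Groups with a single
#'   animal skip the U-test with a warning.
#' @export
pupil_group_stats <- function(data) {
  need <- c("mouse", "group", "epoch", "da", "median_area")
  if (!all(need %in% names(data))) {
    abort(paste("`data` must contain columns:", paste(need, collapse = ", ")))
  }
  df <- data |>
    dplyr::mutate(group = factor(.data$group), epoch = factor(.data$epoch))
  mw <- NULL
  if (nlevels(df$group) == 2L) {
    med <- df |>
      dplyr::distinct(.data$mouse, .data$group, .data$median_area)
    gs <- split(med$median_area, med$group)
    if (any(lengths(gs) < 2L)) {
      warn("a group has fewer than two animals; Mann-Whitney test skipped")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(gs[[1]], gs[[2]]))
      mw <- tibble(statistic = unname(wt$statistic), p.value = wt$p.value,
                   median1 = median(gs[[1]]), median2 = median(gs[[2]]),
                   group1 = names(gs)[1], group2 = names(gs)[2])
    }
  }
  form <- if (nlevels(df$group) > 1L) da ~ group * epoch else da ~ epoch
  fit <- stats::aov(form, data = df)
  an <- summary(fit)[[1]]
  anova_tbl <- tibble(term = trimws(rownames(an)), df = an[["Df"]],
                      statistic = an[["F value"]], p.value = an[["Pr(>F)"]])
  em <- if (nlevels(df$group) > 1L) emmeans::emmeans(fit, ~ epoch | group) else
    emmeans::emmeans(fit, ~ epoch)
  pw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey")) |> as_tibble()
  structure(list(mann_whitney = mw, anova = anova_tbl, pairwise = pw,
                 model = fit),
            class = "pupil_stats")
}

#' @export
print.pupil_stats <- function(x, ...) {
  if (!is.null(x$mann_whitney)) {
    cat("Mann-Whitney on median pupil area:\n")
    print(as.data.frame(x$mann_whitney))
  }
  cat("\nTwo-way ANOVA on da:\n")
  print(as.data.frame(x$anova))
  cat("\nTukey-Kramer pairwise epochs:\n")
  print(as.data.frame(x$pairwise))
  invisible(x)
}
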