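#' Cohort presets for the synthetic-data generator
#'
#' A preset bundles the qualitative response structure of one experimental
#' group: per-epoch mean response multipliers for the aversive, cue and
#' omitted stimulus classes; the fraction of responsive cells; the fraction
#' of cells whose trial-to-trial gain is linked to a hierarchical Gaussian
#' filter parameter (with signed gains); and pupil dynamics. The eight named
#' presets encode the sign patterns of the study groups:
#'
#' * `WT_SC` — collicular somata with adaptation: weaker aversive responses
#'   in the late-stable epoch, recovery under volatility; response gain of a
#'   labeled subset linked negatively to level-3 observer parameters.
#' * `SCN2A_SC` — no late-stable adaptation but elevated volatile-epoch
#'   responses; gain linked positively to the level-1 outcome prediction.
#' * `WT_V1BLOCK`, `SCN2A_V1BLOCK` — corticotectal input silenced: flat
#'   epoch profile, little observer linkage.
#' * `WT_V1AXON` — corticotectal boutons with contextual modulation and
#'   broad low-level observer linkage; `SCN2A_V1AXON` — flat, sparse linkage.
#' * `WT_RGC`, `SCN2A_RGC` — retinal boutons: faithful stimulus responses,
#'   flat across epochs, no observer linkage.
#'
#' Pupil baselines give the wild-type presets a larger median pupil area
#' than the mutant presets, cue-evoked constriction, and outcome-evoked
#' dilation whose magnitude drops under volatility only in wild type.
#'
#' @param name Preset name (see above), or `"flat"` for a fully
#'   uniform-multiplier null preset used in calibration tests.
#' @param ... Named overrides of any preset field.
#' @return A list of class `cohort_preset`.
#' @export
cohort_preset <- function(name = c("WT_SC", "SCN2A_SC", "WT_V1BLOCK",
                                   "SCN2A_V1BLOCK", "WT_V1AXON",
                                   "SCN2A_V1AXON", "WT_RGC", "SCN2A_RGC",
                                   "flat"),
                          ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    aversive_mult = c(ES = 1, LS = 1, VL = 1),
    cue_mult = c(ES = 1, LS = 1, VL = 1),
    omitted_mult = c(ES = 0, LS = 0, VL = 0),
    late_component_weight = 0.5,    # share of response carried by the late window half
    responsive_frac = 0.5,
    cue_responsive_frac = 0.4,
    ori_selective_frac = 0.25,
    ori_bias = 0,                   # excess probability of vertical preference
    linked_frac = 0,
    linked_gains = numeric(0),      # named signed gains on standardized HGF parameters
    amp_mean = 3,
    amp_sd_log = 0.3,
    trial_noise_sd = 0.3,           # truncated-at-zero Gaussian, relative
    frame_noise_sd = 0.5,           # half-truncated Gaussian shot noise, activity units
    decay = c(a = 0.5, b = -0.3, c = 0.8),
    excursion_frac = 0.05,
    pupil_area_mm2 = 0.79,
    pupil_constriction = 0.06,
    pupil_dilation = c(ES = 0.20, LS = 0.18, VL = 0.10),
    pupil_noise_sd = 0.015
  )
  tweak <- switch(
    name,
    WT_SC = list(aversive_mult = c(ES = 1, LS = 0.6, VL = 1.05),
                 linked_frac = 0.25,
                 linked_gains = c(mu_hat3 = -0.6, unc3 = -0.6)),
    SCN2A_SC = list(aversive_mult = c(ES = 0.95, LS = 1, VL = 1.4),
                    linked_frac = 0.2,
                    linked_gains = c(mu_hat1 = 0.6),
                    pupil_area_mm2 = 0.62,
                    pupil_dilation = c(ES = 0.15, LS = 0.15, VL = 0.15)),
    WT_V1BLOCK = list(linked_frac = 0.05,
                      linked_gains = c(mu_hat2 = 0.4),
                      pupil_dilation = c(ES = 0.15, LS = 0.15, VL = 0.15)),
    SCN2A_V1BLOCK = list(linked_frac = 0.05,
                         linked_gains = c(mu_hat2 = 0.4),
                         pupil_area_mm2 = 0.62,
                         pupil_dilation = c(ES = 0.15, LS = 0.15, VL = 0.15)),
    WT_V1AXON = list(aversive_mult = c(ES = 1, LS = 0.7, VL = 1.05),
                     linked_frac = 0.3,
                     linked_gains = c(mu_hat1 = 0.6, unc3 = -0.6)),
    SCN2A_V1AXON = list(linked_frac = 0.08,
                        linked_gains = c(unc3 = -0.4),
                        pupil_area_mm2 = 0.62),
    WT_RGC = list(),
    SCN2A_RGC = list(pupil_area_mm2 = 0.62),
    flat = list(pupil_dilation = c(ES = 0.15, LS = 0.15, VL = 0.15))
  )
  preset <- utils::modifyList(base, tweak)
  preset <- utils::modifyList(preset, list(...))
  if (any(unlist(preset[c("aversive_mult", "cue_mult")]) < 0)) {
    abort("response multipliers must be non-negative")
  }
  fr <- unlist(preset[c("responsive_frac", "cue_responsive_frac",
                        "ori_selective_frac", "linked_frac")])
  if (any(fr < 0 | fr > 1)) abort("cell fractions must lie in [0, 1]")
  structure(preset, class = "cohort_preset")
}

# Gaussian temporal bump on a frame grid, peak value 1.
response_kernel <- function(t, latency, width) {
  exp(-(t - latency)^2 / (2 * width^2))
}

#' Simulate a trial-aligned population recording
#'
#' Generates a cells-by-frames non-negative activity matrix in
#' deconvolved-spike-estimate units, aligned to a session's trial events.
#' Each responsive cell carries a stimulus-type-specific temporal kernel
#' (randomized peak latency, emulating the retinotopy-driven timing spread
#' of the moving aversive stimuli) whose trial amplitude is scaled by the
#' preset's epoch multiplier, a shared power-law photobleaching decay
#' `g(trial) = a * trial^b + c` over the presented trial index, an optional
#' gain linked to a standardized HGF parameter trajectory for a labeled
#' subset of cells, and truncated-Gaussian trial noise. Frame-level shot
#' noise is added throughout; a stated fraction of trials receives a
#' platform excursion above the 0.25 mm analysis threshold.
#'
#' @param session A [generate_session()] result.
#' @param preset A [cohort_preset()] (or preset name).
#' @param n_cells Number of cells to simulate.
#' @param seed Integer seed; the generator is fully reproducible.
#' @param frame_rate Imaging frame rate in Hz (default 30.9).
#' @param hgf Optional precomputed [run_hgf()] trajectories for the session
#'   (computed internally when any preset gain is linked).
#' @param decay Logical; apply the photobleaching decay (default `TRUE`).
#' @return An object of class `recording`: a list with `activity`
#'   (cells x frames matrix), `frame_rate`, `events` (per-trial cue/outcome
#'   onset frames joined to the session table), `excursion` (per-trial mm),
#'   `ground_truth` (per-cell tibble: responsive, cue-responsive,
#'   orientation preference, linked parameter and gain), `preset` and
#'   `seed`.
#' @export
simulate_recording <- function(session, preset = cohort_preset("WT_SC"),
                               n_cells = 100, seed = 1,
                               frame_rate = 30.9, hgf = NULL,
                               decay = TRUE) {
  if (is.character(preset)) preset <- cohort_preset(preset)
  if (!inherits(preset, "cohort_preset")) abort("unknown preset")
  n_cells <- stopifnot_scalar_count(n_cells, "n_cells")
  cfg <- attr(session, "config")
  n_trials <- nrow(session)
  trial_dur <- cfg$cue_duration_s + cfg$isi_s + cfg$outcome_duration_s + cfg$iti_s
  n_frames <- ceiling(n_trials * trial_dur * frame_rate)

  # standardized HGF parameter values per presented trial (0 for excluded)
  gain_traj <- NULL
  if (preset$linked_frac > 0 && length(preset$linked_gains) > 0) {
    if (is.null(hgf)) hgf <- run_hgf(contingency_vector(session), session = session)
    gain_traj <- matrix(0, n_trials, length(preset$linked_gains),
                        dimnames = list(NULL, names(preset$linked_gains)))
    analyzed <- !is.na(session$k)
    for (pn in names(preset$linked_gains)) {
      v <- hgf[[pn]]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      gain_traj[analyzed, pn] <- as.numeric(scale(v))
    }
  }

  types <- aversive_type_names(cfg$n_aversive_types)
  out_win <- seq_len(round(cfg$outcome_duration_s * frame_rate))
  cue_win <- seq_len(round(cfg$cue_duration_s * frame_rate))
  t_out <- (out_win - 1) / frame_rate
  t_cue <- (cue_win - 1) / frame_rate

  with_seed(seed, {
    responsive <- runif(n_cells) < preset$responsive_frac
    cue_responsive <- runif(n_cells) < preset$cue_responsive_frac
    ori_selective <- cue_responsive & runif(n_cells) < preset$ori_selective_frac
    pref_vertical <- runif(n_cells) < 0.5 + preset$ori_bias
    amp <- exp(rnorm(n_cells, log(preset$amp_mean), preset$amp_sd_log))
    linked <- responsive & runif(n_cells) < preset$linked_frac
    linked_param <- rep(NA_character_, n_cells)
    linked_gain <- rep(0, n_cells)
    if (any(linked) && length(preset$linked_gains) > 0) {
      pick <- sample(names(preset$linked_gains), sum(linked), replace = TRUE)
      linked_param[linked] <- pick
      linked_gain[linked] <- unname(preset$linked_gains[pick])
    }

    # per cell x subtype latencies (s), widths, and relative amplitudes
    lat <- matrix(runif(n_cells * length(types), 0.2,
                        cfg$outcome_duration_s - 0.2),
                  n_cells, length(types), dimnames = list(NULL, types))
    wid <- matrix(runif(n_cells * length(types), 0.12, 0.3),
                  n_cells, length(types))
    rel <- matrix(runif(n_cells * length(types), 0.3, 1),
                  n_cells, length(types), dimnames = list(NULL, types))
    # outcome-window kernels per subtype (cells x window frames), with the
    # preset's early/late component weighting applied across the window halves
    half <- t_out >= cfg$outcome_duration_s / 2
    late_w <- 2 * preset$late_component_weight
    early_w <- 2 - late_w
    kernels <- lapply(seq_along(types), function(j) {
      k <- response_kernel(matrix(t_out, n_cells, length(t_out), byrow = TRUE),
                           lat[, j], wid[, j])
      k * matrix(ifelse(half, late_w, early_w), n_cells, length(t_out),
                 byrow = TRUE)
    })
    names(kernels) <- types
    cue_lat <- runif(n_cells, 0.1, cfg$cue_duration_s - 0.2)
    cue_kernel <- response_kernel(
      matrix(t_cue, n_cells, length(t_cue), byrow = TRUE), cue_lat, 0.15)
    cue_amp_v <- amp * runif(n_cells, 0.2, 0.7) *
      ifelse(ori_selective, ifelse(pref_vertical, 1.5, 0.3), 1) * cue_responsive
    cue_amp_h <- amp * runif(n_cells, 0.2, 0.7) *
      ifelse(ori_selective, ifelse(pref_vertical, 0.3, 1.5), 1) * cue_responsive

    # frame-level shot noise (truncated-at-zero Gaussian)
    activity <- matrix(pmax(rnorm(n_cells * n_frames, 0, preset$frame_noise_sd), 0),
                       n_cells, n_frames)

    g <- if (decay) {
      preset$decay[["a"]] * seq_len(n_trials)^preset$decay[["b"]] +
        preset$decay[["c"]]
    } else rep(1, n_trials)

    cue_onset <- round(session$onset_s * frame_rate) + 1L
    out_onset <- round(session$outcome_onset_s * frame_rate) + 1L
    epoch_chr <- as.character(session$epoch)
    mult_of <- function(mult, ep) if (ep == "excluded") mult[["ES"]] else mult[[ep]]

    for (i in seq_len(n_trials)) {
      ep <- epoch_chr[i]
      gains <- 1
      if (!is.null(gain_traj)) {
        gains <- 1 + linked_gain *
          gain_traj[i, ifelse(is.na(linked_param), 1L, match(linked_param,
                                                             colnames(gain_traj)))]
        gains[!linked] <- 1
      }
      # cue response
      a_cue <- if (session$cue[i] == "vertical") cue_amp_v else cue_amp_h
      a_cue <- pmax(a_cue * mult_of(preset$cue_mult, ep) * g[i] *
                      (1 + rnorm(n_cells, 0, preset$trial_noise_sd)), 0)
      fr <- cue_onset[i] + cue_win - 1L
      activity[, fr] <- activity[, fr] + a_cue * cue_kernel
      # outcome response (aversive only; omitted draws no response)
      if (session$outcome[i] == "aversive") {
        ty <- session$aversive_type[i]
        a_out <- amp * rel[, ty] * responsive *
          mult_of(preset$aversive_mult, ep) * g[i] * gains
        a_out <- pmax(a_out * (1 + rnorm(n_cells, 0, preset$trial_noise_sd)), 0)
        fr <- out_onset[i] + out_win - 1L
        activity[, fr] <- activity[, fr] + a_out * kernels[[ty]]
      }
    }

    excursion <- abs(rnorm(n_trials, 0.05, 0.03))
    bump <- runif(n_trials) < preset$excursion_frac
    excursion[bump] <- runif(sum(bump), 0.26, 0.6)

    ground_truth <- tibble(
      cell = seq_len(n_cells),
      responsive = responsive,
      cue_responsive = cue_responsive,
      ori_selective = ori_selective,
      pref_vertical = pref_vertical,
      amp = amp,
      linked = linked,
      linked_param = linked_param,
      linked_gain = linked_gain
    )

    events <- session |>
      as_tibble() |>
      dplyr::mutate(cue_onset_frame = cue_onset, outcome_onset_frame = out_onset)

    structure(
      list(activity = activity, frame_rate = frame_rate, events = events,
           excursion = excursion, ground_truth = ground_truth,
           preset = preset, seed = seed, session = session),
      class = "recording"
    )
  })
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d cells x %d frames at %.1f Hz (preset %s, seed %d)\n",
              nrow(x$activity), ncol(x$activity), x$frame_rate,
              x$preset$name, x$seed))
  invisible(x)
}

# Alpha-function transient, peak 1 at t = tau.
alpha_bump <- function(t, tau) {
  ifelse(t < 0, 0, (t / tau) * exp(1 - t / tau))
}

#' Simulate a raw pupil-diameter trace
#'
#' Produces a per-frame long-axis pupil diameter series (pixels, 30 Hz) for
#' a session: a preset baseline area, a constriction transient at each cue
#' onset, a dilation transient at each aversive outcome whose magnitude
#' follows the preset's per-epoch dilation profile, and additive smooth
#' (low-pass) noise. Mutant presets carry a smaller baseline area than
#' wild-type presets.
#'
#' @inheritParams simulate_recording
#' @param frame_rate Eye-camera frame rate in Hz (default 30).
#' @param calibration Pixel-squared per mm-squared constant (default 6e3).
#' @return An object of class `pupil_raw`: list with `diameter_px`,
#'   `frame_rate`, `calibration`, `events` and the session.
#' @export
simulate_pupil <- function(session, preset = cohort_preset("WT_SC"), seed = 1,
                           frame_rate = 30, calibration = 6e3) {
  if (is.character(preset)) preset <- cohort_preset(preset)
  if (!inherits(preset, "cohort_preset")) abort("unknown preset")
  cfg <- attr(session, "config")
  trial_dur <- cfg$cue_duration_s + cfg$isi_s + cfg$outcome_duration_s + cfg$iti_s
  n_frames <- ceiling(nrow(session) * trial_dur * frame_rate) +
    round(5 * frame_rate)
  t_grid <- (seq_len(n_frames) - 1) / frame_rate

  with_seed(seed, {
    m <- rep(1, n_frames)  # proportional area modulation
    epoch_chr <- as.character(session$epoch)
    for (i in seq_len(nrow(session))) {
      ep <- if (epoch_chr[i] == "excluded") "ES" else epoch_chr[i]
      rel <- t_grid - session$onset_s[i]
      m <- m - preset$pupil_constriction * alpha_bump(rel, 0.4) *
        (rel < 3) * (rel >= 0)
      if (session$outcome[i] == "aversive") {
        rel_o <- t_grid - session$outcome_onset_s[i]
        m <- m + preset$pupil_dilation[[ep]] * alpha_bump(rel_o, 0.8) *
          (rel_o < 4) * (rel_o >= 0)
      }
    }
    smooth_noise <- stats::filter(rnorm(n_frames, 0, preset$pupil_noise_sd),
                                  rep(1 / 15, 15), sides = 2, circular = TRUE)
    m <- pmax(m + as.numeric(smooth_noise), 0.2)
    area_px2 <- preset$pupil_area_mm2 * calibration * m
    diameter_px <- 2 * sqrt(area_px2 / pi)

    events <- session |>
      as_tibble() |>
      dplyr::mutate(
        cue_onset_frame = round(.data$onset_s * frame_rate) + 1L,
        outcome_onset_frame = round(.data$outcome_onset_s * frame_rate) + 1L
      )
    structure(
      list(diameter_px = diameter_px, frame_rate = frame_rate,
           calibration = calibration, events = events, session = session,
           preset = preset, seed = seed),
      class = "pupil_raw"
    )
  })
}

#' Simulate a linear-Gaussian receptive-field unit
#'
#' Returns the activity trace of a unit whose response is a spatially
#' Gaussian-weighted, temporally filtered linear function of a checkerboard
#' stimulus, plus optional Gaussian noise. Used as the ground-truth fixture
#' for the reverse-correlation receptive-field estimator.
#'
#' @param rf_center Numeric length-2 `(x, y)` field coordinates of the RF
#'   center (1-based, may be fractional).
#' @param rf_sd Spatial standard deviation in fields (scalar for isotropic,
#'   or length-2 `(sd_x, sd_y)`).
#' @param stimulus A [checkerboard()] stimulus.
#' @param gain Response gain (default 1; 0 gives a stimulus-independent unit).
#' @param latency_s Peak temporal latency of the response filter in seconds.
#' @param noise_sd Additive Gaussian noise SD (default 0, noiseless).
#' @param seed Seed for the noise draw.
#' @return List of class `rf_unit`: `activity` on the stimulus bin clock,
#'   `bin_s`, and the ground truth (`rf_center`, `rf_sd`, `latency_s`).
#' @export
simulate_rf_unit <- function(rf_center, rf_sd, stimulus, gain = 1,
                             latency_s = 0.05, noise_sd = 0, seed = 1) {
  if (!inherits(stimulus, "checker_stimulus")) abort("`stimulus` must be a checkerboard()")
  nx <- stimulus$nx; ny <- stimulus$ny
  if (length(rf_sd) == 1L) rf_sd <- c(rf_sd, rf_sd)
  if (rf_center[1] < 1 || rf_center[1] > nx ||
      rf_center[2] < 1 || rf_center[2] > ny) {
    abort("`rf_center` lies outside the stimulus grid")
  }
  gx <- rep(seq_len(nx), times = ny)
  gy <- rep(seq_len(ny), each = nx)
  w <- exp(-((gx - rf_center[1])^2 / (2 * rf_sd[1]^2) +
               (gy - rf_center[2])^2 / (2 * rf_sd[2]^2)))
  s <- stimulus_bins(stimulus)           # fields x bins, values 0/1
  drive <- as.numeric(crossprod(w, s - 0.5))
  lags <- seq_len(round(0.5 / stimulus$bin_s))
  tfilt <- alpha_bump((lags - 1) * stimulus$bin_s, latency_s)
  tfilt <- tfilt / sum(tfilt)
  act <- gain * as.numeric(stats::filter(drive, tfilt, sides = 1))
  act[is.na(act)] <- 0
  if (noise_sd > 0) act <- act + with_seed(seed, rnorm(length(act), 0, noise_sd))
  structure(list(activity = act, bin_s = stimulus$bin_s,
                 rf_center = rf_center, rf_sd = rf_sd, latency_s = latency_s),
            class = "rf_unit")
}
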