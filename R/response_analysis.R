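#' Epoch-wise z-scoring of a recording
#'
#' Extracts the frames spanned by one analysis epoch's trials and converts
#' each cell's activity to z-scores within that epoch (mean 0, SD 1 over the
#' epoch's frames). Cells with zero variance in the epoch are flagged and
#' returned as `NA` rows. Optionally (`scope = "session"`) the z-scoring
#' moments are taken over the whole recording instead.
#'
#' @param recording A [simulate_recording()] result (or a compatible list
#'   with `activity`, `frame_rate`, `events`).
#' @param epoch One of `"ES"`, `"LS"`, `"VL"`.
#' @param scope `"epoch"` (default) or `"session"`: frames used for the
#'   z-scoring moments.
#' @return Cells x epoch-frames matrix with attributes `frames` (the frame
#'   indices in the recording) and `zero_variance` (logical per cell).
#' @export
zscore_epoch <- function(recording, epoch, scope = c("epoch", "session")) {
  scope <- match.arg(scope)
  ev <- recording$events |> dplyr::filter(.data$epoch == !!epoch)
  if (nrow(ev) == 0L) abort(sprintf("no trials in epoch '%s'", epoch))
  cfg <- attr(recording$session, "config")
  trial_len <- round((cfg$cue_duration_s + cfg$isi_s + cfg$outcome_duration_s +
                        cfg$iti_s) * recording$frame_rate)
  frames <- seq.int(min(ev$cue_onset_frame),
                    min(max(ev$cue_onset_frame) + trial_len - 1L,
                        ncol(recording$activity)))
  base <- if (scope == "epoch") recording$activity[, frames, drop = FALSE] else
    recording$activity
  mu <- rowMeans(base)
  sigma <- apply(base, 1, sd)
  zero_var <- sigma == 0 | !is.finite(sigma)
  z <- (recording$activity[, frames, drop = FALSE] - mu) / sigma
  z[zero_var, ] <- NA_real_
  attr(z, "frames") <- frames
  attr(z, "zero_variance") <- zero_var
  z
}

#' Trial-averaged aligned response with excursion filtering
#'
#' Averages aligned windows of a z-scored matrix over trials, excluding
#' trials whose mean vertical platform excursion exceeds the threshold.
#'
#' @param Z Cells x frames z-scored matrix (frame indexing local to `Z`).
#' @param onsets Integer vector of alignment frames (local to `Z`), one per
#'   trial.
#' @param window Integer number of frames from each onset.
#' @param excursion Per-trial mean excursion in mm (default all 0).
#' @param threshold_mm Exclusion threshold (default 0.25 mm).
#' @return Cells x window matrix `z(t)` with attributes `n_used` and
#'   `n_excluded`. All trials excluded yields an all-`NA` matrix with a
#'   warning.
#' @export
trial_average <- function(Z, onsets, window, excursion = rep(0, length(onsets)),
                          threshold_mm = 0.25) {
  if (length(excursion) != length(onsets)) {
    abort("`excursion` must have one value per trial")
  }
  keep <- excursion <= threshold_mm
  out <- matrix(NA_real_, nrow(Z), window)
  if (!any(keep)) {
    warn("all trials excluded by the excursion filter")
    attr(out, "n_used") <- 0L
    attr(out, "n_excluded") <- length(onsets)
    return(out)
  }
  acc <- matrix(0, nrow(Z), window)
  for (on in onsets[keep]) {
    acc <- acc + Z[, seq.int(on, on + window - 1L), drop = FALSE]
  }
  out <- acc / sum(keep)
  attr(out, "n_used") <- sum(keep)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

# Aligned per-epoch outcome (or cue) averages for every cell:
# returns list(epoch -> z(t) matrix) plus the window frame count.
epoch_aligned_averages <- function(recording, align = c("outcome", "cue"),
                                   trials = c("aversive", "omitted", "vertical",
                                              "horizontal", "all"),
                                   scope = "epoch") {
  align <- match.arg(align)
  trials <- match.arg(trials)
  cfg <- attr(recording$session, "config")
  window <- round(switch(align, outcome = cfg$outcome_duration_s,
                         cue = cfg$cue_duration_s) * recording$frame_rate)
  onset_col <- switch(align, outcome = "outcome_onset_frame",
                      cue = "cue_onset_frame")
  out <- list()
  for (ep in c("ES", "LS", "VL")) {
    Z <- zscore_epoch(recording, ep, scope = scope)
    frames <- attr(Z, "frames")
    ev <- recording$events |> dplyr::filter(.data$epoch == !!ep)
    ev <- switch(trials,
                 aversive = ev |> dplyr::filter(.data$outcome == "aversive"),
                 omitted = ev |> dplyr::filter(.data$outcome == "omitted"),
                 vertical = ev |> dplyr::filter(.data$cue == "vertical"),
                 horizontal = ev |> dplyr::filter(.data$cue == "horizontal"),
                 all = ev)
    onsets <- ev[[onset_col]] - frames[1] + 1L
    exc <- recording$excursion[ev$trial]
    out[[ep]] <- trial_average(Z, onsets, window, exc)
  }
  attr(out, "window") <- window
  out
}

#' Responsive-cell mask
#'
#' A cell is responsive when its trial-averaged z-scored response `z(t)`
#' exceeds a predetermined threshold in at least one analysis epoch
#' (1 for collicular somata; 0.75 for RGC or V1 axon terminals).
#'
#' @param z_by_epoch List of cells x frames `z(t)` matrices (one per epoch),
#'   e.g. the internal per-epoch aligned averages; or a `recording`, in
#'   which case outcome-aligned aversive-trial averages are computed.
#' @param threshold Responsiveness threshold (default 1).
#' @return Logical vector per cell (`FALSE` for zero-variance cells).
#' @export
responsive_mask <- function(z_by_epoch, threshold = 1) {
  if (inherits(z_by_epoch, "recording")) {
    z_by_epoch <- epoch_aligned_averages(z_by_epoch, "outcome", "aversive")
  }
  peak <- do.call(pmax, c(lapply(z_by_epoch, function(m) {
    apply(m, 1, function(r) if (all(is.na(r))) -Inf else max(r, na.rm = TRUE))
  }), na.rm = TRUE))
  peak > threshold
}

#' Epoch-normalized contextual modulation
#'
#' For each responsive cell and epoch, computes the time-averaged response
#' over the outcome window, `zbar = <z(t)>_t`, and the across-epoch
#' normalization `dz = zbar - <zbar>_epochs` (zero-sum per cell). The
#' early/late halves of the outcome window are summarized separately.
#'
#' @param recording A [simulate_recording()] result.
#' @param threshold Responsiveness threshold passed to [responsive_mask()].
#' @param trials Trial class to average (default `"aversive"`).
#' @return A tibble with one row per responsive cell and epoch: `cell`,
#'   `epoch`, `zbar`, `dz`, `zbar_early`, `zbar_late`, `dz_early`,
#'   `dz_late`.
#' @examples
#' sess <- generate_session(design_config())
#' rec <- simulate_recording(sess, cohort_preset("WT_SC"), n_cells = 20, seed = 1)
#' mod <- epoch_modulation(rec)
#' dplyr::summarise(dplyr::group_by(mod, epoch), mean_dz = mean(dz))
#' @export
epoch_modulation <- function(recording, threshold = 1, trials = "aversive") {
  zs <- epoch_aligned_averages(recording, "outcome", trials)
  window <- attr(zs, "window")
  half <- seq_len(window) > window / 2
  resp <- responsive_mask(zs, threshold)
  rows <- purrr::imap(zs, function(m, ep) {
    tibble(cell = seq_len(nrow(m)), epoch = ep,
           zbar = rowMeans(m),
           zbar_early = rowMeans(m[, !half, drop = FALSE]),
           zbar_late = rowMeans(m[, half, drop = FALSE]))
  })
  dplyr::bind_rows(rows) |>
    dplyr::filter(resp[.data$cell], !is.na(.data$zbar)) |>
    dplyr::group_by(.data$cell) |>
    dplyr::filter(dplyr::n() == length(zs)) |>
    dplyr::mutate(dz = .data$zbar - mean(.data$zbar),
                  dz_early = .data$zbar_early - mean(.data$zbar_early),
                  dz_late = .data$zbar_late - mean(.data$zbar_late)) |>
    dplyr::ungroup() |>
    dplyr::mutate(epoch = factor(.data$epoch, levels = c("ES", "LS", "VL")))
}

#' Group statistics for epoch modulation
#'
#' Fits the nested ANOVA of the response summaries — value ~ Group * Epoch
#' + Mouse within Group — then performs Tukey-Kramer pairwise comparisons
#' of epochs within each group (via estimated marginal means).
#'
#' With the default `unit = "mouse"`, cells are first aggregated to
#' mouse-by-epoch means, so the Group x Epoch interaction is tested against
#' mouse-level variation (the split-plot error stratum). This keeps the
#' test's type-I error at its nominal level: cells within an animal share
#' trial-level variation (the same trial sequence and excursion exclusions),
#' so treating them as independent replicates (`unit = "cell"`) is
#' anticonservative for group-level inferences.
#'
#' @param data Tibble with columns `mouse`, `group`, `epoch`, and the
#'   response column named by `value` (per cell per epoch).
#' @param value Name of the response column (default `"zbar"`; use `"dz"`
#'   for pairwise contrasts on the normalized modulation).
#' @param unit `"mouse"` (default): aggregate cells to mouse-by-epoch means
#'   before fitting; `"cell"`: use cells as replicates.
#' @return An object of class `epoch_comparison`: list with `anova`
#'   (omnibus table as a tibble), `pairwise` (Tukey-Kramer contrasts per
#'   group), and the fitted `aov` model. `tidy()` returns the pairwise
#'   table; `glance()` the omnibus interaction row.
#' @export
compare_epochs <- function(data, value = "zbar", unit = c("mouse", "cell")) {
  unit <- match.arg(unit)
  need <- c("mouse", "group", "epoch", value)
  if (!all(need %in% names(data))) {
    abort(paste("`data` must contain columns:", paste(need, collapse = ", ")))
  }
  df <- data |>
    dplyr::mutate(mouse = factor(.data$mouse), group = factor(.data$group),
                  epoch = factor(.data$epoch),
                  .value = .data[[value]])
  if (unit == "mouse") {
    df <- df |>
      dplyr::group_by(.data$mouse, .data$group, .data$epoch) |>
      dplyr::summarise(.value = mean(.data$.value), .groups = "drop")
  }
  multi_group <- nlevels(df$group) > 1L
  multi_mouse <- nlevels(df$mouse) > 1L
  form <- if (multi_group && multi_mouse) {
    .value ~ group * epoch + group:mouse
  } else if (multi_group) {
    .value ~ group * epoch
  } else if (multi_mouse) {
    .value ~ epoch + mouse
  } else {
    .value ~ epoch
  }
  fit <- stats::aov(form, data = df)
  if (stats::df.residual(fit) < 1) {
    abort("singular design: no residual degrees of freedom (need more mice per group)")
  }
  an <- summary(fit)[[1]]
  if (any(!is.finite(an[-nrow(an), "F value"]))) {
    abort("singular design: some ANOVA terms have no estimable variance")
  }
  anova_tbl <- tibble(
    term = trimws(rownames(an)),
    df = an[["Df"]], sumsq = an[["Sum Sq"]],
    statistic = an[["F value"]], p.value = an[["Pr(>F)"]]
  )
  em <- if (multi_group) emmeans::emmeans(fit, ~ epoch | group) else
    emmeans::emmeans(fit, ~ epoch)
  pw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey")) |> as_tibble()
  structure(list(anova = anova_tbl, pairwise = pw, model = fit,
                 value = value, unit = unit),
            class = "epoch_comparison")
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat("<epoch_comparison> on", x$value, "\n\nOmnibus ANOVA:\n")
  print(as.data.frame(x$anova))
  cat("\nTukey-Kramer pairwise epochs:\n")
  print(as.data.frame(x$pairwise))
  invisible(x)
}

#' @rdname compare_epochs
#' @param x An `epoch_comparison` object.
#' @param ... Unused.
#' @export
tidy.epoch_comparison <- function(x, ...) x$pairwise

#' @rdname compare_epochs
#' @export
glance.epoch_comparison <- function(x, ...) {
  inter <- x$anova |> dplyr::filter(grepl("group:epoch", .data$term))
  tibble(
    interaction_p = if (nrow(inter)) inter$p.value[1] else NA_real_,
    epoch_p = (x$anova |> dplyr::filter(.data$term == "epoch"))$p.value[1],
    n_terms = nrow(x$anova)
  )
}

#' Orientation bias of baseline cue responses
#'
#' For every cue-responsive cell (peak early-stable vertical or horizontal
#' cue response above `threshold`), computes the time-averaged difference
#' between vertical- and horizontal-cue responses during the early-stable
#' epoch; summarizes each animal by the median difference across its cells;
#' compares the per-animal medians between the two groups with a two-sample
#' Kolmogorov-Smirnov test; and tests each animal's vertical/horizontal
#' preference counts against 50:50 with a chi-squared test, Bonferroni
#' corrected across animals. A per-cell two-sided Wilcoxon rank-sum test
#' between vertical- and horizontal-cue trial responses (alpha = 0.05)
#' defines orientation-selective cells.
#'
#' @param recordings Named list of recordings, one per animal.
#' @param groups Character vector assigning each animal to a group (same
#'   length/order as `recordings`).
#' @param threshold Cue responsiveness threshold (default 1).
#' @param min_cells Minimum responsive cells per animal (default 2); animals
#'   below it are excluded.
#' @return List of class `orientation_bias`: `cells` (per-cell tibble),
#'   `animals` (per-animal medians, chi-squared p and Bonferroni-corrected
#'   p, orientation-selective fraction), and `ks` (the group KS test as a
#'   tibble, `NULL` with fewer than two groups).
#' @export
orientation_bias <- function(recordings, groups, threshold = 1,
                             min_cells = 2L) {
  if (is.null(names(recordings))) {
    names(recordings) <- paste0("animal", seq_along(recordings))
  }
  per_animal <- purrr::imap(recordings, function(rec, id) {
    Z <- zscore_epoch(rec, "ES")
    frames <- attr(Z, "frames")
    cfg <- attr(rec$session, "config")
    window <- round(cfg$cue_duration_s * rec$frame_rate)
    ev <- rec$events |> dplyr::filter(.data$epoch == "ES")
    resp_by_cue <- function(which_cue) {
      sel <- ev |> dplyr::filter(.data$cue == which_cue)
      ons <- sel$cue_onset_frame - frames[1] + 1L
      trial_average(Z, ons, window, rec$excursion[sel$trial])
    }
    zv <- resp_by_cue("vertical"); zh <- resp_by_cue("horizontal")
    peak <- pmax(apply(zv, 1, max), apply(zh, 1, max))
    keep <- !is.na(peak) & peak > threshold
    # per-trial window means for the per-cell rank test
    trial_means <- function(which_cue) {
      sel <- ev |> dplyr::filter(.data$cue == which_cue)
      ons <- sel$cue_onset_frame - frames[1] + 1L
      vapply(ons, function(on) {
        rowMeans(Z[, seq.int(on, on + window - 1L), drop = FALSE])
      }, numeric(nrow(Z)))
    }
    tv <- trial_means("vertical"); th <- trial_means("horizontal")
    sel_p <- vapply(seq_len(nrow(Z)), function(i) {
      if (!keep[i]) return(NA_real_)
      suppressWarnings(stats::wilcox.test(tv[i, ], th[i, ])$p.value)
    }, numeric(1))
    tibble(animal = id, cell = seq_len(nrow(Z)),
           responsive = keep,
           diff = rowMeans(zv) - rowMeans(zh),
           selective = !is.na(sel_p) & sel_p < 0.05)
  })
  cells <- dplyr::bind_rows(per_animal) |>
    dplyr::left_join(tibble(animal = names(recordings), group = groups),
                     by = "animal")
  animals <- cells |>
    dplyr::filter(.data$responsive) |>
    dplyr::group_by(.data$animal, .data$group) |>
    dplyr::filter(dplyr::n() >= min_cells) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      median_diff = median(.data$diff),
      n_vertical = sum(.data$diff > 0),
      selective_frac = mean(.data$selective),
      chisq_p = stats::chisq.test(
        c(n_vertical, dplyr::n() - n_vertical))$p.value,
      .groups = "drop"
    ) |>
    dplyr::mutate(chisq_p_bonf = pmin(.data$chisq_p * dplyr::n(), 1))
  ks <- NULL
  if (length(unique(groups)) == 2L) {
    gs <- split(animals$median_diff, animals$group)
    if (all(lengths(gs) >= 1L)) {
      kt <- suppressWarnings(stats::ks.test(gs[[1]], gs[[2]]))
      ks <- tibble(statistic = unname(kt$statistic), p.value = kt$p.value,
                   group1 = names(gs)[1], group2 = names(gs)[2])
    }
  }
  structure(list(cells = cells, animals = animals, ks = ks),
            class = "orientation_bias")
}
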