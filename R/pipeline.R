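#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Run the full analysis pipeline on synthetic cohorts
#'
#' End-to-end orchestration: generates the task session, forward-simulates
#' the HGF observer, simulates one recording and pupil trace per animal for
#' each requested cohort preset, computes epoch modulation with group
#' statistics, builds stimulus-normalized decay-corrected neuronal
#' trajectories, correlates them with the aversive-subset HGF parameter
#' trajectories (with polarity shuffle tests and per-level summaries),
#' analyses evoked pupillometry, and optionally maps synthetic receptive
#' fields. Every stochastic stage receives a seed derived from `seed`, so
#' rerunning with the same configuration reproduces all outputs.
#'
#' @param presets Character vector of [cohort_preset()] names, one cohort
#'   per preset.
#' @param n_mice Animals per cohort (default 4).
#' @param n_cells Cells per animal (default 100).
#' @param seed Master seed.
#' @param design A [design_config()].
#' @param hgf_cfg An [hgf_config()].
#' @param n_shuffles Polarity-test repetitions (default 2000 here; raise to
#'   10000 for final inference).
#' @param include_pupil,include_rf Stage switches.
#' @param rf_units,rf_duration_s Receptive-field stage size (default 5
#'   noiseless units on a 2-minute checkerboard).
#' @return An object of class `pipeline_run`: list with `session`, `hgf`,
#'   `cohorts` (per-preset list: recordings, modulation, trajectories,
#'   decay fit, correlation table, polarity test, level summary, pupil),
#'   `modulation_stats` (cross-group [compare_epochs()] when more than one
#'   preset), `pupil_stats`, `rf` and `report` (seeds, parameters, headline
#'   statistics).
#' @export
run_pipeline <- function(presets = "WT_SC", n_mice = 4, n_cells = 100,
                         seed = 1, design = design_config(),
                         hgf_cfg = hgf_config(), n_shuffles = 2000,
                         include_pupil = TRUE, include_rf = FALSE,
                         rf_units = 5, rf_duration_s = 120) {
  t0 <- Sys.time()
  session <- generate_session(design)
  hgf <- run_hgf(contingency_vector(session), hgf_cfg, session = session)
  hgf_av <- subset_aversive(hgf)

  cohorts <- list()
  all_mod <- list()
  all_pupil <- list()
  for (gi in seq_along(presets)) {
    preset <- cohort_preset(presets[gi])
    recs <- list(); mods <- list(); pupils <- list()
    trajs <- list()
    for (mi in seq_len(n_mice)) {
      mouse_seed <- seed * 10000L + gi * 100L + mi
      rec <- simulate_recording(session, preset, n_cells = n_cells,
                                seed = mouse_seed, hgf = hgf)
      recs[[mi]] <- rec
      mods[[mi]] <- epoch_modulation(rec) |>
        dplyr::mutate(mouse = paste0(preset$name, "_m", mi),
                      group = preset$name)
      tr <- aversive_trial_responses(rec) |>
        stimulus_normalized_trajectory(session) |>
        dplyr::mutate(cell = .data$cell + (mi - 1L) * n_cells)
      trajs[[mi]] <- tr
      if (include_pupil) {
        pup <- simulate_pupil(session, preset, seed = mouse_seed)
        resp <- evoked_trace(pup)
        pupils[[mi]] <- resp$summary |>
          dplyr::mutate(mouse = paste0(preset$name, "_m", mi),
                        group = preset$name,
                        median_area = resp$median_area)
      }
    }
    traj <- dplyr::bind_rows(trajs)
    decay <- fit_decay(traj)
    rd <- remove_decay(traj, decay)
    corr <- correlate_trajectories(rd$trajectories, hgf_av)
    pol <- polarity_shuffle_test(rd$trajectories, hgf_av,
                                 n_shuffles = n_shuffles,
                                 seed = seed + gi)
    cohorts[[preset$name]] <- list(
      recordings = recs,
      modulation = dplyr::bind_rows(mods),
      trajectories = rd$trajectories,
      d = rd$d,
      decay_fit = decay,
      correlations = corr,
      polarity = pol,
      levels = level_cumsum(corr),
      pupil = if (include_pupil) dplyr::bind_rows(pupils)
    )
    all_mod[[preset$name]] <- cohorts[[preset$name]]$modulation
    if (include_pupil) all_pupil[[preset$name]] <- cohorts[[preset$name]]$pupil
  }

  modulation <- dplyr::bind_rows(all_mod)
  modulation_stats <- tryCatch(
    compare_epochs(modulation, value = "zbar"),
    error = function(e) {
      warn(paste("epoch comparison skipped:", conditionMessage(e)))
      NULL
    })
  pupil_stats <- NULL
  if (include_pupil && length(presets) > 1L) {
    pupil_stats <- pupil_group_stats(dplyr::bind_rows(all_pupil))
  }

  rf <- NULL
  if (include_rf) {
    stim <- checkerboard(duration_s = rf_duration_s, seed = seed + 77L)
    rf <- with_seed(seed + 78L, {
      purrr::map(seq_len(rf_units), function(i) {
        ctr <- c(runif(1, 4, stim$nx - 3), runif(1, 4, stim$ny - 3))
        sdv <- runif(1, 1, 2.5)
        unit <- simulate_rf_unit(ctr, sdv, stim)
        fit <- fit_rf(reverse_correlation(unit, stim))
        dplyr::mutate(tidy(fit), true_x = ctr[1], true_y = ctr[2],
                      true_sd = sdv)
      }) |> dplyr::bind_rows()
    })
  }

  report <- list(
    seed = seed,
    presets = presets,
    n_mice = n_mice,
    n_cells = n_cells,
    design = unclass(design),
    hgf_config = unclass(hgf_cfg),
    decay_coefficients = purrr::map(cohorts, ~ .x$decay_fit$coefficients),
    interaction_p = if (is.null(modulation_stats)) NA_real_ else
      glance(modulation_stats)$interaction_p,
    level_summaries = purrr::map(cohorts, ~ .x$levels$levels),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(session = session, hgf = hgf, cohorts = cohorts,
                 modulation = modulation,
                 modulation_stats = modulation_stats,
                 pupil_stats = pupil_stats, rf = rf, report = report),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> presets: %s | %d mice x %d cells | seed %d | %.1f s\n",
              paste(x$report$presets, collapse = ", "), x$report$n_mice,
              x$report$n_cells, x$report$seed, x$report$elapsed_s))
  cat(sprintf("epoch x group interaction p = %.4g\n", x$report$interaction_p))
  invisible(x)
}
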