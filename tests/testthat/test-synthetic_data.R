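test_that("recordings are reproducible, finite, non-negative and aligned", {
  rec <- fx_recording(n_cells = 10, seed = 3)
  rec2 <- fx_recording(n_cells = 10, seed = 3)
  expect_identical(rec$activity, rec2$activity)
  expect_true(all(is.finite(rec$activity)) && all(rec$activity >= 0))
  expect_true(all(rec$events$outcome_onset_frame <= ncol(rec$activity)))
  expect_true(all(rec$excursion >= 0))
  expect_equal(nrow(rec$ground_truth), 10)
  rec3 <- fx_recording(n_cells = 10, seed = 4)
  expect_false(identical(rec$activity, rec3$activity))
})

test_that("a noiseless no-decay cell reproduces its kernel exactly", {
  preset <- cohort_preset("WT_SC",
                          responsive_frac = 1, cue_responsive_frac = 0,
                          linked_frac = 0, trial_noise_sd = 0,
                          frame_noise_sd = 0, excursion_frac = 0)
  rec <- simulate_recording(fx_session, preset, n_cells = 1, seed = 1,
                            frame_rate = 15.5, decay = FALSE)
  ev <- rec$events[rec$events$outcome == "aversive" & rec$events$epoch == "LS", ]
  win <- round(2 * rec$frame_rate)
  ty <- ev$aversive_type[1]
  same_type <- ev[ev$aversive_type == ty, ]
  segs <- sapply(same_type$outcome_onset_frame,
                 function(on) rec$activity[1, on:(on + win - 1)])
  # identical amplitude and shape across trials of the same type and epoch
  expect_true(all(abs(segs - segs[, 1]) < 1e-12))
  # LS epoch scales the ES response by the preset multiplier
  ev_es <- rec$events[rec$events$outcome == "aversive" &
                        rec$events$epoch == "ES" &
                        rec$events$aversive_type == ty, ]
  seg_es <- rec$activity[1, ev_es$outcome_onset_frame[1] +
                           seq_len(win) - 1]
  expect_equal(segs[, 1] / seg_es,
               rep(0.6, win), tolerance = 1e-10)
})

test_that("the excursion fraction and threshold behave as configured", {
  rec <- fx_recording(n_cells = 2, seed = 5)
  frac <- mean(rec$excursion > 0.25)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.15)
})

test_that("responsive cells are recovered from the ground truth", {
  # balanced accuracy of the z-threshold detector against the labels
  accs <- sapply(1:3, function(s) {
    rec <- fx_recording(n_cells = 60, seed = s)
    mask <- responsive_mask(rec)
    truth <- rec$ground_truth$responsive
    (mean(mask[truth]) + mean(!mask[!truth])) / 2
  })
  expect_gte(mean(accs), 0.95)
})

test_that("presets enforce their validity invariants", {
  expect_error(cohort_preset("nope"))
  expect_error(cohort_preset("WT_SC", responsive_frac = 1.2), "fractions")
  expect_error(cohort_preset("WT_SC",
                             aversive_mult = c(ES = -1, LS = 1, VL = 1)),
               "non-negative")
  p <- cohort_preset("SCN2A_SC")
  expect_lt(p$pupil_area_mm2, cohort_preset("WT_SC")$pupil_area_mm2)
})

test_that("pupil traces carry the preset baseline and epoch dynamics", {
  r_wt <- evoked_trace(simulate_pupil(fx_session, cohort_preset("WT_SC"),
                                      seed = 2))
  expect_equal(r_wt$median_area, 0.79, tolerance = 0.05)
  s <- r_wt$summary
  expect_lt(s$da[s$epoch == "VL"], s$da[s$epoch == "ES"])
  expect_lt(s$da[s$epoch == "VL"], s$da[s$epoch == "LS"])
  r_mut <- evoked_trace(simulate_pupil(fx_session, cohort_preset("SCN2A_SC"),
                                       seed = 2))
  expect_lt(r_mut$median_area, r_wt$median_area)
})

test_that("a flat zero-noise pupil preset gives a(t) = 1 throughout", {
  preset <- cohort_preset("flat", pupil_constriction = 0,
                          pupil_dilation = c(ES = 0, LS = 0, VL = 0),
                          pupil_noise_sd = 0)
  r <- evoked_trace(simulate_pupil(fx_session, preset, seed = 1))
  expect_equal(r$trace$a, rep(1, nrow(r$trace)), tolerance = 1e-12)
  expect_equal(r$summary$da, rep(0, 3), tolerance = 1e-12)
})

test_that("rf units respond at their ground-truth location and a zero-gain unit is flat", {
  stim <- checkerboard(duration_s = 60, seed = 9)
  unit <- simulate_rf_unit(c(10, 8), 1.5, stim)
  k <- reverse_correlation(unit, stim)
  peak_field <- which.max(abs(k$kernel[, which.max(colSums(abs(k$kernel)))]))
  px <- (peak_field - 1) %% stim$nx + 1
  py <- (peak_field - 1) %/% stim$nx + 1
  expect_lte(abs(px - 10), 1)
  expect_lte(abs(py - 8), 1)
  expect_error(simulate_rf_unit(c(50, 8), 1.5, stim), "outside")
  flat <- simulate_rf_unit(c(10, 8), 1.5, stim, gain = 0, noise_sd = 0.1,
                           seed = 2)
  kf <- reverse_correlation(flat, stim)
  expect_lt(max(abs(kf$kernel)), 0.1)
})
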