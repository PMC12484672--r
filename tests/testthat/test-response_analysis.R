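test_that("epoch z-scoring gives mean 0, SD 1 and flags constant cells", {
  rec <- fx_recording(n_cells = 8, seed = 11)
  rec$activity[3, ] <- 5  # constant cell
  Z <- zscore_epoch(rec, "ES")
  zv <- attr(Z, "zero_variance")
  expect_true(zv[3])
  expect_false(any(zv[-3]))
  expect_true(all(is.na(Z[3, ])))
  expect_equal(rowMeans(Z[-3, ]), rep(0, 7), tolerance = 1e-12)
  expect_equal(apply(Z[-3, ], 1, sd), rep(1, 7), tolerance = 1e-12)
  # repeated call is deterministic
  expect_identical(Z, zscore_epoch(rec, "ES"))
})

test_that("trial averaging applies the excursion filter", {
  Z <- matrix(rep(1:10, each = 5), nrow = 5) * 1.0  # 5 cells x 10 frames
  onsets <- c(1L, 3L, 5L, 7L)
  # no excursion: plain mean of the aligned columns
  plain <- trial_average(Z, onsets, window = 2)
  expect_equal(attr(plain, "n_used"), 4L)
  expect_equal(plain[1, ], c(mean(c(1, 3, 5, 7)), mean(c(2, 4, 6, 8))))
  # two trials above threshold are dropped
  filt <- trial_average(Z, onsets, window = 2,
                        excursion = c(0, 0.3, 0, 0.26))
  expect_equal(attr(filt, "n_excluded"), 2L)
  expect_equal(filt[1, ], c(mean(c(1, 5)), mean(c(2, 6))))
  # single surviving trial equals that trial
  one <- trial_average(Z, onsets, window = 2,
                       excursion = c(0, 1, 1, 1))
  expect_equal(one[1, ], c(1, 2))
  expect_warning(out <- trial_average(Z, onsets, 2, excursion = rep(1, 4)),
                 "all trials excluded")
  expect_true(all(is.na(out)))
  expect_error(trial_average(Z, onsets, 2, excursion = 0), "one value")
})

test_that("responsiveness thresholds behave and are monotone", {
  z_by_epoch <- list(ES = rbind(c(0.2, 1.2, 0.1), c(0.1, 0.8, 0.2)),
                     LS = rbind(c(0.0, 0.5, 0.1), c(0.1, 0.6, 0.1)))
  expect_equal(responsive_mask(z_by_epoch, threshold = 1), c(TRUE, FALSE))
  expect_equal(responsive_mask(z_by_epoch, threshold = 0.75), c(TRUE, TRUE))
  rec <- fx_recording(n_cells = 25, seed = 12)
  m1 <- responsive_mask(rec, threshold = 0.75)
  m2 <- responsive_mask(rec, threshold = 1)
  m3 <- responsive_mask(rec, threshold = 1.5)
  expect_true(all(m2 >= m3) && all(m1 >= m2))
})

test_that("epoch modulation is the across-epoch-centered mean and sums to zero", {
  # arithmetic on a known zbar triple via direct centering
  zbar <- c(1, 0.4, 1)
  expect_equal(zbar - mean(zbar), c(0.2, -0.4, 0.2))
  mod <- epoch_modulation(fx_recording(n_cells = 30, seed = 13))
  sums <- mod |> dplyr::group_by(cell) |> dplyr::summarise(s = sum(dz))
  expect_true(all(abs(sums$s) < 1e-12))
  sums_l <- mod |> dplyr::group_by(cell) |> dplyr::summarise(s = sum(dz_late))
  expect_true(all(abs(sums_l$s) < 1e-12))
  # every retained cell contributes all three epochs
  expect_true(all(table(mod$cell) == 3))
})

test_that("the WT_SC cohort shows the late-stable response dip", {
  mod <- epoch_modulation(fx_recording("WT_SC", n_cells = 60, seed = 14))
  m <- tapply(mod$dz, mod$epoch, mean)
  expect_lt(m[["LS"]], 0)
  expect_gt(m[["ES"]], m[["LS"]])
  expect_gt(m[["VL"]], m[["LS"]])
})

test_that("compare_epochs reports the nested ANOVA and Tukey contrasts", {
  mods <- purrr::map(1:2, function(mi) {
    epoch_modulation(fx_recording("WT_SC", n_cells = 25, seed = 20 + mi)) |>
      dplyr::mutate(mouse = paste0("wt_m", mi), group = "WT_SC")
  })
  mods_f <- purrr::map(1:2, function(mi) {
    epoch_modulation(fx_recording("flat", n_cells = 25, seed = 30 + mi)) |>
      dplyr::mutate(mouse = paste0("fl_m", mi), group = "flat")
  })
  cmp <- compare_epochs(dplyr::bind_rows(c(mods, mods_f)), value = "zbar")
  expect_s3_class(cmp, "epoch_comparison")
  expect_true(any(grepl("group:epoch", cmp$anova$term)))
  pw <- tidy(cmp)
  expect_equal(nrow(pw), 6)  # 3 contrasts x 2 groups
  # the WT dip is detected within the WT group, not the flat group
  wt <- pw[pw$group == "WT_SC", ]
  expect_lt(wt$p.value[wt$contrast == "ES - LS"], 0.05)
  expect_lt(wt$p.value[wt$contrast == "LS - VL"], 0.05)
  expect_true(is.finite(glance(cmp)$interaction_p))
  expect_error(compare_epochs(dplyr::tibble(a = 1)), "must contain")
})

test_that("orientation bias recovers a constructed vertical preference", {
  mk <- function(bias, seed) {
    simulate_recording(fx_session,
                       cohort_preset("WT_SC", ori_selective_frac = 1,
                                     ori_bias = bias, cue_responsive_frac = 1),
                       n_cells = 25, seed = seed, frame_rate = 15.5)
  }
  recs <- list(a1 = mk(0.5, 41), a2 = mk(0.5, 42),
               b1 = mk(0, 43), b2 = mk(0, 44))
  ob <- orientation_bias(recs, groups = c("V", "V", "N", "N"))
  an <- ob$animals
  expect_true(all(an$median_diff[an$group == "V"] > 0))
  # all-vertical animals show a significant per-animal chi-squared bias
  expect_true(all(an$chisq_p_bonf[an$group == "V"] < 0.05))
  expect_true(all(an$selective_frac > 0.5))
  expect_s3_class(ob$ks, "tbl_df")
})
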