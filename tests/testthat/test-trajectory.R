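test_that("stimulus-type normalization matches the hand oracle", {
  toy <- dplyr::tibble(cell = 1L, k_av = 1:4, j = 1:4,
                       type = c("A", "A", "B", "B"),
                       zbar = c(3, 1, 5, 1))
  out <- stimulus_normalized_trajectory(toy)
  expect_equal(out$dz, c(1, -1, 2, -2))
  # per-type means of the output are exactly zero
  means <- tapply(out$dz, out$type, mean)
  expect_equal(as.numeric(means), c(0, 0))
  # constant responses within type give the all-zero trajectory
  const <- dplyr::mutate(toy, zbar = c(2, 2, 7, 7))
  expect_equal(stimulus_normalized_trajectory(const)$dz, rep(0, 4))
})

test_that("aversive responses carry 18 balanced trials per type", {
  rec <- fx_recording(n_cells = 5, seed = 51)
  resp <- aversive_trial_responses(rec)
  expect_equal(nrow(resp), 5 * 108)
  counts <- resp |> dplyr::count(cell, type)
  expect_true(all(counts$n == 18))
  per_epoch <- resp |> dplyr::filter(cell == 1) |> dplyr::count(epoch)
  expect_true(all(per_epoch$n == 36))
  expect_equal(resp$j[resp$cell == 1], rep(1:36, 3))
  tr <- stimulus_normalized_trajectory(resp, fx_session)
  sums <- tr |> dplyr::group_by(cell, type) |> dplyr::summarise(s = sum(dz), .groups = "drop")
  expect_true(all(abs(sums$s) < 1e-12))
  bad <- dplyr::filter(resp, type != "fast-loom")
  expect_error(stimulus_normalized_trajectory(bad, fx_session), "fast-loom")
})

test_that("power-decay fitting recovers known parameters and signs", {
  j <- 1:36
  mk_traj <- function(y) {
    dplyr::bind_rows(
      dplyr::tibble(cell = 1L, k_av = j, j = j, dz = y),
      dplyr::tibble(cell = 2L, k_av = j, j = j, dz = y))
  }
  exact <- fit_decay(mk_traj(2 * j^-0.5 + 0.1))
  expect_equal(unname(exact$coefficients),
               c(2, -0.5, 0.1), tolerance = 1e-6)
  expect_lt(exact$residual_sd, 1e-8)
  flat <- fit_decay(mk_traj(rep(0.7, 36)))
  expect_equal(flat$coefficients[["a"]], 0, tolerance = 1e-4)
  expect_equal(flat$coefficients[["c"]] +
                 flat$coefficients[["a"]] * mean(j^flat$coefficients[["b"]]),
               0.7, tolerance = 1e-3)
  rising <- fit_decay(mk_traj(0.1 * log(j)))
  expect_gt(rising$coefficients[["b"]], 0)
  expect_error(fit_decay(dplyr::tibble(cell = 1L, j = j, dz = j)), "two cells")
})

test_that("decay removal zeroes the residual correlation with a shared scalar", {
  fitlike <- structure(
    list(coefficients = c(a = 2, b = -0.5, c = 0.1)), class = "decay_fit")
  f <- decay_curve(fitlike, rep(1:36, 3))
  # trajectory that is exactly twice the tiled curve
  traj <- dplyr::tibble(cell = 1L, k_av = 1:108, j = rep(1:36, 3),
                        dz = 2 * f)
  out <- remove_decay(traj, fitlike)
  expect_equal(out$d$d, 2, tolerance = 1e-12)
  expect_equal(out$trajectories$dz_res, rep(0, 108), tolerance = 1e-12)
  # orthogonal trajectory is untouched
  set.seed(1)
  noise <- rnorm(108)
  orth <- stats::residuals(stats::lm(noise ~ f))
  traj2 <- dplyr::mutate(traj, dz = orth)
  out2 <- remove_decay(traj2, fitlike)
  expect_equal(out2$d$d, 0, tolerance = 1e-10)
  expect_equal(out2$trajectories$dz_res, orth, tolerance = 1e-10)
  # idempotence: removing again finds d ~ 0
  again <- remove_decay(
    dplyr::mutate(out$trajectories, dz = dz_res), fitlike)
  expect_equal(again$d$d, 0, tolerance = 1e-10)
})

test_that("decay removal preserves epoch contrasts and bounds all residual correlations", {
  rec <- fx_recording("WT_SC", n_cells = 40, seed = 52)
  tr <- stimulus_normalized_trajectory(aversive_trial_responses(rec),
                                       fx_session)
  fit <- fit_decay(tr)
  out <- remove_decay(tr, fit)
  rho <- out$trajectories |>
    dplyr::group_by(cell) |>
    dplyr::summarise(r = cor(dz_res, f)) |>
    dplyr::pull(r)
  expect_lte(max(abs(rho)), 0.05)
  # epoch ordering survives the decay subtraction
  m_pre <- tapply(tr$dz, tr$epoch, mean)
  m_post <- tapply(out$trajectories$dz_res, out$trajectories$epoch, mean)
  expect_equal(order(m_pre), order(m_post))
  # constant decay curve falls back to d = 0 with a warning
  cfit <- structure(list(coefficients = c(a = 0, b = -0.5, c = 0.3)),
                    class = "decay_fit")
  expect_warning(cz <- remove_decay(tr, cfit), "constant")
  expect_true(all(cz$d$d == 0))
})
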