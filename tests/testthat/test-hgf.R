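# Straight-line re-evaluation of the three-level binary HGF update
# equations, kept deliberately free of the package's abstractions: plain
# scalars, one assignment per printed formula.
hgf_oracle <- function(u, omega2 = -2, omega3 = -6, mu2 = 0, mu3 = 1,
                       sigma2 = 1, sigma3 = 1) {
  s <- function(x) 1 / (1 + exp(-x))
  out <- NULL
  for (k in seq_along(u)) {
    mu2_prev <- mu2; mu3_prev <- mu3
    sigma2_prev <- sigma2; sigma3_prev <- sigma3
    mu_hat1 <- s(mu2_prev)
    mu_hat2 <- mu2_prev
    mu_hat3 <- mu3_prev
    sigma_hat1 <- mu_hat1 * (1 - mu_hat1)
    sigma_hat2 <- sigma2_prev + exp(mu3_prev + omega2)
    sigma_hat3 <- sigma3_prev + exp(omega3)
    mu1 <- u[k]
    sigma2 <- 1 / (sigma_hat1 + 1 / sigma_hat2)
    delta1 <- mu1 - s(mu2_prev)
    mu2 <- mu2_prev + sigma2 * delta1
    w2 <- exp(mu3_prev + omega2) / (sigma2_prev + exp(mu3_prev + omega2))
    r2 <- (exp(mu3_prev + omega2) - sigma2_prev) /
      (sigma2_prev + exp(mu3_prev + omega2))
    delta2 <- (sigma2 + (mu2 - mu2_prev)^2) /
      (sigma2_prev + exp(mu3_prev + omega2)) - 1
    sigma3 <- sigma_hat3 / (1 + sigma_hat3 * w2 * (w2 + r2 * delta2) / 2)
    mu3 <- mu3_prev + sigma3 * w2 * delta2 / 2
    delta3 <- (sigma3 + (mu3 - mu_hat3)^2) / sigma_hat3 - 1
    epsilon2 <- sigma2 * delta1
    epsilon3 <- sigma_hat2 * delta3 / sigma3
    unc1 <- sigma_hat1
    unc2 <- s(mu2) * (1 - s(mu2)) * sigma2
    unc3 <- exp(mu3_prev + omega2)
    alpha1 <- (s(mu2) - s(mu2_prev)) / (u[k] - s(mu2_prev))
    alpha2 <- sigma2
    alpha3 <- sigma3 * exp(mu3_prev + omega2) / (2 * sigma_hat2)
    out <- rbind(out, c(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                        mu_hat1 = mu_hat1, mu_hat2 = mu_hat2,
                        mu_hat3 = mu_hat3, sigma_hat2 = sigma_hat2,
                        sigma_hat3 = sigma_hat3, unc1 = unc1, unc2 = unc2,
                        unc3 = unc3, epsilon2 = epsilon2,
                        epsilon3 = epsilon3))
  }
  out
}

test_that("sigmoid is the symmetric logistic link", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1e3), 1)
  x <- seq(-5, 5, 0.5)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(diff(sigmoid(x)) > 0))
})

test_that("one update step matches the hand-computed values", {
  cfg <- hgf_config(omega2 = -2, mu2_0 = 0, sigma2_0 = 1, mu3_0 = 1,
                    sigma3_0 = 1)
  st <- list(mu2 = 0, mu3 = 1, sigma2 = 1, sigma3 = 1, k = 0L)
  step <- hgf_step(st, 1, cfg)
  r <- step$record
  expect_equal(r$mu_hat1, 0.5, tolerance = 1e-10)
  expect_equal(r$unc1, 0.25, tolerance = 1e-10)
  expect_equal(r$sigma_hat2, 1 + exp(-1), tolerance = 1e-10)
  expect_equal(r$sigma2, 1.019307, tolerance = 1e-6)
  expect_equal(step$state$mu2, 0.509654, tolerance = 1e-6)
})

test_that("the pipeline matches a straight-line oracle on random sequences", {
  set.seed(7)
  for (rep in 1:10) {
    u <- rbinom(20, 1, runif(1, 0.2, 0.8))
    got <- run_hgf(u)
    want <- hgf_oracle(u)
    for (pn in hgf_parameter_names()) {
      g <- got[[pn]]; w <- want[, pn]
      # alpha1 may be guarded to NA only where the oracle divides by ~0
      ok <- !is.na(g)
      expect_true(all(abs(g[ok] - w[ok]) <=
                        1e-10 * pmax(abs(w[ok]), 1)),
                  label = paste("parameter", pn, "rep", rep))
    }
  }
})

test_that("a run emits exactly the 13 named parameters per trial", {
  traj <- run_hgf(contingency_vector(fx_session), session = fx_session)
  expect_equal(nrow(traj), 216)
  expect_length(hgf_parameter_names(), 13)
  expect_true(all(hgf_parameter_names() %in% names(traj)))
  expect_equal(sort(unname(hgf_parameter_levels())), sort(c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L)))
})

test_that("trajectory invariants hold on the default task", {
  traj <- run_hgf(contingency_vector(fx_session))
  expect_true(all(traj$mu_hat1 > 0 & traj$mu_hat1 < 1))
  expect_equal(traj$unc1, traj$mu_hat1 * (1 - traj$mu_hat1))
  expect_true(all(traj$sigma2 > 0 & traj$sigma2 <= traj$sigma_hat2))
  # sigma_hat3 is the previous sigma3 plus the constant exp(omega3)
  cfg <- hgf_config()
  expect_equal(traj$sigma_hat3[-1],
               traj$sigma3[-nrow(traj)] + exp(cfg$omega3))
})

test_that("an all-expected sequence strengthens the contingency belief", {
  traj <- run_hgf(rep(0, 50))
  expect_true(all(diff(traj$mu2) < 0))
  expect_identical(run_hgf(rep(0, 50)), run_hgf(rep(0, 50)))
})

test_that("the canonical epsilon3 switch changes only epsilon3", {
  u <- contingency_vector(fx_session)
  a <- run_hgf(u, hgf_config())
  b <- run_hgf(u, hgf_config(epsilon3_canonical = TRUE))
  expect_false(isTRUE(all.equal(a$epsilon3, b$epsilon3)))
  for (pn in setdiff(hgf_parameter_names(), "epsilon3")) {
    expect_equal(a[[pn]], b[[pn]])
  }
})

test_that("aversive subsetting keeps 108 trials in order", {
  traj <- run_hgf(contingency_vector(fx_session), session = fx_session)
  av <- subset_aversive(traj)
  expect_equal(nrow(av), 108)
  at <- analyzed_trials(fx_session)
  expect_equal(av$k, at$k[at$outcome == "aversive"])
  all_av <- traj
  all_av$outcome <- "aversive"
  expect_equal(nrow(subset_aversive(all_av)), nrow(traj))
  expect_error(run_hgf(integer(0)), "non-empty")
  expect_error(run_hgf(c(0, 2)), "binary")
})
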