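# Brute-force Storey computation at a fixed lambda, written independently
# of the package's vectorized implementation.
storey_brute <- function(p, lambda) {
  m <- length(p)
  pi0 <- sum(p > lambda) / (m * (1 - lambda))
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(sapply(which(p >= p[i]), function(j) {
      pi0 * m * p[j] / sum(p <= p[j])
    }))
  }
  pmin(q, 1)
}

fx_hgf_av <- subset_aversive(
  run_hgf(contingency_vector(fx_session), session = fx_session))

fx_traj_from_matrix <- function(m) {
  # cells x trials matrix -> trajectory tibble
  dplyr::tibble(
    cell = rep(seq_len(nrow(m)), times = ncol(m)),
    k_av = rep(seq_len(ncol(m)), each = nrow(m)),
    dz_res = as.numeric(m)
  )
}

test_that("Storey q-values match the brute-force oracle at fixed lambda", {
  p <- c(0.01, 0.02, 0.5, 0.9)
  q <- storey_qvalues(p, fixed_lambda = 0.5)
  expect_equal(as.numeric(q), storey_brute(p, 0.5))
  expect_equal(as.numeric(q), c(0.02, 0.02, 1 / 3, 0.45))
  expect_equal(attr(q, "pi0"), 0.5)
  set.seed(2)
  p2 <- runif(300)
  expect_equal(as.numeric(storey_qvalues(p2, fixed_lambda = 0.4)),
               storey_brute(p2, 0.4))
})

test_that("Storey pi0 is ~1 on uniform nulls and q-values stay ordered", {
  set.seed(10)
  p <- runif(1e4)
  q <- storey_qvalues(p)
  expect_equal(attr(q, "pi0"), 1, tolerance = 0.05)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-14))
  expect_true(all(q <= 1 & q >= 0))
  strong <- storey_qvalues(rep(1e-9, 100))
  expect_true(all(strong < 0.05))
  expect_error(storey_qvalues(numeric(0)), "no p-values")
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("perfectly coupled trajectories give rho of exactly +/-1", {
  base <- matrix(rnorm(20 * 108), 20, 108)
  base[1, ] <- fx_hgf_av$mu_hat2
  base[2, ] <- -fx_hgf_av$mu_hat2
  co <- correlate_trajectories(fx_traj_from_matrix(base), fx_hgf_av)
  r1 <- co$rho[co$cell == 1 & co$parameter == "mu_hat2"]
  r2 <- co$rho[co$cell == 2 & co$parameter == "mu_hat2"]
  expect_equal(r1, 1, tolerance = 1e-12)
  expect_equal(r2, -1, tolerance = 1e-12)
  expect_true(all(abs(co$rho) <= 1 + 1e-12))
  expect_equal(nrow(co), 20 * 13)
  # parameter collinearity matrix is reported
  pc <- attr(co, "parameter_cor")
  expect_equal(dim(pc), c(13, 13))
})

test_that("null cohorts keep the significant fraction near the FDR target", {
  set.seed(3)
  m <- matrix(rnorm(300 * 108), 300, 108)
  co <- correlate_trajectories(fx_traj_from_matrix(m), fx_hgf_av)
  # under a global null with pi0 ~ 1, q < 0.05 flags almost nothing
  expect_lt(mean(co$significant), 0.01)
  expect_warning(
    correlate_trajectories(
      fx_traj_from_matrix(rbind(m[1:5, ], 0)), fx_hgf_av),
    "zero-variance")
})

test_that("level summaries add up parameter percentages", {
  set.seed(4)
  m <- matrix(rnorm(40 * 108), 40, 108)
  m[1:10, ] <- m[1:10, ] + outer(rep(1, 10), as.numeric(scale(fx_hgf_av$mu_hat3))) * 2
  co <- correlate_trajectories(fx_traj_from_matrix(m), fx_hgf_av)
  ls <- level_cumsum(co)
  by_level <- tapply(ls$parameters$pct_significant, ls$parameters$level, sum)
  expect_equal(as.numeric(by_level),
               ls$levels$pct_cumsum[match(names(by_level), ls$levels$level)])
  expect_equal(ls$parameters$pct_significant,
               ls$parameters$pct_positive + ls$parameters$pct_negative)
  # the level-3 coupled cells dominate the level-3 cumulative sum
  expect_gt(ls$levels$pct_cumsum[ls$levels$level == 3], 0)
})

test_that("the polarity shuffle test flags constructed bias and not nulls", {
  set.seed(5)
  m <- matrix(rnorm(30 * 108, sd = 0.5), 30, 108)
  m[1:12, ] <- m[1:12, ] + outer(rep(1, 12), as.numeric(scale(fx_hgf_av$mu_hat3)))
  pol <- polarity_shuffle_test(fx_traj_from_matrix(m), fx_hgf_av,
                               n_shuffles = 400, seed = 6)
  expect_equal(nrow(pol), 13)
  row <- pol[pol$parameter == "mu_hat3", ]
  expect_gt(row$observed, 0)
  expect_lt(row$q, 0.05)
  # a parameter with no significant cells reports p = 1
  null_m <- matrix(rnorm(10 * 108), 10, 108)
  pol0 <- polarity_shuffle_test(fx_traj_from_matrix(null_m), fx_hgf_av,
                                n_shuffles = 100, seed = 7)
  expect_true(all(pol0$p[pol0$n_positive + pol0$n_negative == 0] == 1))
  # determinism under a fixed seed
  pol0b <- polarity_shuffle_test(fx_traj_from_matrix(null_m), fx_hgf_av,
                                 n_shuffles = 100, seed = 7)
  expect_identical(pol0, pol0b)
})

test_that("group chi-squared matches the hand formula and its symmetries", {
  same <- group_chi2(50, 1000, 50, 1000)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  res <- group_chi2(200, 1000, 50, 1000)
  # brute force: sum over the 2x2 table of (O - E)^2 / E
  tab <- rbind(c(200, 800), c(50, 950))
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chisq, sum((tab - expd)^2 / expd))
  swapped <- group_chi2(50, 1000, 200, 1000)
  expect_equal(swapped$chisq, res$chisq)
  expect_error(group_chi2(0, 10, 0, 10), "zero expected")
  fam <- group_chi2(c(200, 60), c(1000, 1000), c(50, 50), c(1000, 1000),
                    labels = c("a", "b"))
  expect_equal(fam$q, stats::p.adjust(fam$p, "BH"))
})
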