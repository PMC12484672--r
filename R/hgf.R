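#' Hierarchical Gaussian filter configuration
#'
#' Settings for the three-level binary hierarchical Gaussian filter (HGF)
#' ideal observer. Level 1 tracks the trial outcome (the contingency bit u),
#' level 2 the contingency probability (on a logit scale), and level 3 the
#' environmental volatility. `omega2` and `omega3` are the tonic
#' (log-volatility) constants of levels 2 and 3; the remaining fields set
#' the initial posterior means and variances.
#'
#' Defaults are the canonical binary-HGF priors (mu2 = 0, sigma2 = 1,
#' mu3 = 1, sigma3 = 1, omega2 = -2, omega3 = -6). Downstream correlation
#' analyses are insensitive to affine rescaling of the trajectories, so the
#' exact choice mainly shapes, not reorders, the dynamics.
#'
#' @param omega2,omega3 Tonic volatility constants of levels 2 and 3.
#' @param mu2_0,mu3_0 Initial posterior means of levels 2 and 3.
#' @param sigma2_0,sigma3_0 Initial posterior variances (> 0).
#' @param alpha1_guard Tolerance below which the level-1 learning-rate
#'   denominator is treated as singular; the trial's `alpha1` is then
#'   returned as `NA` (carried as missing downstream).
#' @param epsilon3_canonical Use the canonical level-3 precision-weighted
#'   prediction error built from the level-2 prediction error delta2
#'   (`sigma_hat2 * delta2 / (2 * sigma3)`) instead of the default form
#'   `sigma_hat2 * delta3 / sigma3`. Off by default.
#' @return A list of class `hgf_config`.
#' @export
hgf_config <- function(omega2 = -2, omega3 = -6,
                       mu2_0 = 0, mu3_0 = 1,
                       sigma2_0 = 1, sigma3_0 = 1,
                       alpha1_guard = 1e-12,
                       epsilon3_canonical = FALSE) {
  if (sigma2_0 <= 0 || sigma3_0 <= 0) abort("initial variances must be positive")
  if (alpha1_guard <= 0) abort("`alpha1_guard` must be positive")
  structure(
    list(omega2 = omega2, omega3 = omega3, mu2_0 = mu2_0, mu3_0 = mu3_0,
         sigma2_0 = sigma2_0, sigma3_0 = sigma3_0,
         alpha1_guard = alpha1_guard,
         epsilon3_canonical = isTRUE(epsilon3_canonical)),
    class = "hgf_config"
  )
}

#' Logistic sigmoid
#'
#' The link function of the binary HGF, `s(x) = 1 / (1 + exp(-x))`, mapping
#' the level-2 logit belief to an outcome probability.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

#' The 13 HGF parameter trajectories
#'
#' Names of the five parameter classes across the three levels: learning
#' rates `alpha1..3`, prior predictions `mu_hat1..3`, belief variances
#' `sigma_hat2..3`, uncertainties `unc1..3` (outcome, informational,
#' environmental), and precision-weighted prediction errors `epsilon2..3`.
#'
#' @return Character vector of length 13.
#' @export
hgf_parameter_names <- function() {
  c("alpha1", "alpha2", "alpha3",
    "mu_hat1", "mu_hat2", "mu_hat3",
    "sigma_hat2", "sigma_hat3",
    "unc1", "unc2", "unc3",
    "epsilon2", "epsilon3")
}

#' Hierarchical level of each HGF parameter
#'
#' @return Named integer vector mapping each of the 13 parameter names to
#'   its level (1, 2 or 3).
#' @export
hgf_parameter_levels <- function() {
  c(alpha1 = 1L, alpha2 = 2L, alpha3 = 3L,
    mu_hat1 = 1L, mu_hat2 = 2L, mu_hat3 = 3L,
    sigma_hat2 = 2L, sigma_hat3 = 3L,
    unc1 = 1L, unc2 = 2L, unc3 = 3L,
    epsilon2 = 2L, epsilon3 = 3L)
}

#' Single HGF update step
#'
#' Advances the observer by one trial given the contingency bit `u_k`.
#' Priors are the previous posteriors pushed through the model: mu_hat1 =
#' s(mu2), mu_hat2 = mu2, mu_hat3 = mu3; belief variances sigma_hat2 =
#' sigma2 + exp(mu3 + omega2) and sigma_hat3 = sigma3 + exp(omega3). The
#' level-2 posterior moves by the precision-weighted level-1 prediction
#' error, and the level-3 posterior by the volatility-weighted level-2
#' prediction error.
#'
#' @param state Named list with `mu2`, `mu3`, `sigma2`, `sigma3`, `k`.
#' @param u_k Contingency bit (0 or 1).
#' @param config An [hgf_config()].
#' @return List with `state` (updated) and `record` (one-row tibble with the
#'   13 parameters plus the intermediates `delta1..3`, `w2`, `r2`, `mu2`,
#'   `mu3`, `sigma2`, `sigma3`).
#' @export
hgf_step <- function(state, u_k, config = hgf_config()) {
  if (state$sigma2 <= 0 || state$sigma3 <= 0) {
    abort(sprintf("invalid HGF state before trial %d: nonpositive variance",
                  state$k + 1L))
  }
  mu2_p <- state$mu2; mu3_p <- state$mu3
  s2_p <- state$sigma2; s3_p <- state$sigma3
  w2_exp <- exp(mu3_p + config$omega2)

  # priors
  mu_hat1 <- sigmoid(mu2_p)
  mu_hat2 <- mu2_p
  mu_hat3 <- mu3_p
  sigma_hat1 <- mu_hat1 * (1 - mu_hat1)
  sigma_hat2 <- s2_p + w2_exp
  sigma_hat3 <- s3_p + exp(config$omega3)

  # level-1 / level-2 posteriors
  mu1 <- u_k
  sigma2 <- 1 / (sigma_hat1 + 1 / sigma_hat2)
  delta1 <- mu1 - sigmoid(mu2_p)
  mu2 <- mu2_p + sigma2 * delta1

  # level-3 posterior
  w2 <- w2_exp / (s2_p + w2_exp)
  r2 <- (w2_exp - s2_p) / (s2_p + w2_exp)
  delta2 <- (sigma2 + (mu2 - mu2_p)^2) / (s2_p + w2_exp) - 1
  sigma3 <- sigma_hat3 / (1 + sigma_hat3 * w2 * (w2 + r2 * delta2) / 2)
  if (!is.finite(sigma3) || sigma3 <= 0) {
    abort(sprintf("HGF trajectory invalid at trial %d: sigma3 = %g",
                  state$k + 1L, sigma3))
  }
  mu3 <- mu3_p + sigma3 * w2 * delta2 / 2

  # generic prediction errors (delta2 above already equals the generic form
  # at level 2 since mu_hat2 = mu2_p and sigma_hat2 = s2_p + w2_exp)
  delta3 <- (sigma3 + (mu3 - mu_hat3)^2) / sigma_hat3 - 1

  # precision-weighted prediction errors
  epsilon2 <- sigma2 * delta1
  epsilon3 <- if (config$epsilon3_canonical) {
    sigma_hat2 * delta2 / (2 * sigma3)
  } else {
    sigma_hat2 * delta3 / sigma3
  }

  # uncertainties
  unc1 <- sigma_hat1
  unc2 <- sigmoid(mu2) * (1 - sigmoid(mu2)) * sigma2
  unc3 <- w2_exp

  # learning rates
  alpha1 <- if (abs(delta1) < config$alpha1_guard) NA_real_ else {
    (sigmoid(mu2) - sigmoid(mu2_p)) / delta1
  }
  alpha2 <- sigma2
  alpha3 <- sigma3 * w2_exp / (2 * sigma_hat2)

  record <- tibble(
    alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
    mu_hat1 = mu_hat1, mu_hat2 = mu_hat2, mu_hat3 = mu_hat3,
    sigma_hat2 = sigma_hat2, sigma_hat3 = sigma_hat3,
    unc1 = unc1, unc2 = unc2, unc3 = unc3,
    epsilon2 = epsilon2, epsilon3 = epsilon3,
    delta1 = delta1, delta2 = delta2, delta3 = delta3,
    w2 = w2, r2 = r2,
    mu2 = mu2, mu3 = mu3, sigma2 = sigma2, sigma3 = sigma3
  )
  list(
    state = list(mu2 = mu2, mu3 = mu3, sigma2 = sigma2, sigma3 = sigma3,
                 k = state$k + 1L),
    record = record
  )
}

#' Forward-simulate the HGF over a contingency vector
#'
#' Folds [hgf_step()] over the binary input sequence and returns the full
#' per-trial trajectory table. The first trial's priors come from the
#' configured initial state (no burn-in).
#'
#' @param u Binary vector (the contingency sequence), or a `session_design`
#'   whose [contingency_vector()] is used.
#' @param config An [hgf_config()].
#' @param session Optional [generate_session()] result supplying per-trial
#'   `outcome` and `epoch` metadata columns.
#' @return An `hgf_trajectories` tibble: one row per trial with columns `k`,
#'   the 13 parameters of [hgf_parameter_names()], the intermediates, and
#'   (when a session is supplied) `outcome` and `epoch`.
#' @examples
#' sess <- generate_session(design_config())
#' traj <- run_hgf(contingency_vector(sess), session = sess)
#' dim(traj)
#' @export
run_hgf <- function(u, config = hgf_config(), session = NULL) {
  if (inherits(u, "session_design")) {
    session <- session %||% u
    u <- contingency_vector(u)
  }
  if (length(u) == 0L) abort("`u` must be non-empty")
  if (!all(u %in% c(0, 1))) abort("`u` must be binary (0/1)")
  state <- list(mu2 = config$mu2_0, mu3 = config$mu3_0,
                sigma2 = config$sigma2_0, sigma3 = config$sigma3_0, k = 0L)
  records <- vector("list", length(u))
  for (k in seq_along(u)) {
    step <- hgf_step(state, u[k], config)
    state <- step$state
    records[[k]] <- step$record
  }
  traj <- dplyr::bind_rows(records) |>
    dplyr::mutate(k = seq_along(u), u = u, .before = 1)
  if (!is.null(session)) {
    at <- analyzed_trials(session)
    if (nrow(at) != nrow(traj)) {
      abort("session length does not match contingency vector length")
    }
    traj$outcome <- at$outcome
    traj$epoch <- at$epoch
    traj$aversive_type <- at$aversive_type
  }
  structure(traj, class = c("hgf_trajectories", class(traj)), config = config)
}

#' Restrict HGF trajectories to aversive-outcome trials
#'
#' Non-aversive (omitted-outcome) trials are dropped so model trajectories
#' can be compared with neuronal trajectories, which only contain responses
#' to the aversive outcomes. Order is preserved.
#'
#' @param traj An `hgf_trajectories` tibble carrying an `outcome` column, or
#'   one without it if `session` is supplied.
#' @param session Optional session used to look up outcomes.
#' @return The aversive-trial subset, same class.
#' @export
subset_aversive <- function(traj, session = NULL) {
  if (!is.null(session)) {
    at <- analyzed_trials(session)
    if (nrow(at) != nrow(traj)) abort("trajectory/session length mismatch")
    keep <- at$outcome == "aversive"
  } else {
    if (is.null(traj$outcome)) abort("`traj` has no outcome column; supply `session`")
    keep <- traj$outcome == "aversive"
  }
  out <- traj[keep, , drop = FALSE]
  attr(out, "config") <- attr(traj, "config")
  out
}
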