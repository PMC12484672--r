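# Pearson correlations of every column pair with two-sided t-test p-values,
# pairwise-complete over missing values.
cor_with_p <- function(x, y) {
  rho <- suppressWarnings(cor(x, y, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(x), !is.na(y))
  tt <- rho * sqrt(pmax(n - 2, 0) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tt), pmax(n - 2, 1), lower.tail = FALSE)
  list(rho = rho, p = p, n = n)
}

#' Storey q-values
#'
#' Converts a collection of p-values to q-values with Storey's positive
#' false-discovery-rate method: the null proportion pi0 is estimated on a
#' lambda grid as `#{p > lambda} / (m * (1 - lambda))` and smoothed with a
#' natural cubic smoothing spline, taking the estimate at the largest
#' lambda (clamped to (0, 1]); q-values are the pi0-scaled step-up ordered
#' p-values, monotone in p.
#'
#' @param p Numeric p-values in [0, 1] (`NA`s preserved).
#' @param lambda Grid for pi0 estimation (default `seq(0.05, 0.95, 0.05)`).
#' @param fixed_lambda If supplied, skip smoothing and use the single-point
#'   pi0 estimate at this lambda.
#' @return Numeric q-values, same length as `p`, with attribute `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05),
                           fixed_lambda = NULL) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) abort("no p-values supplied")
  if (any(pv < 0 | pv > 1)) abort("p-values must lie in [0, 1]")
  if (!is.null(fixed_lambda)) {
    pi0 <- mean(pv > fixed_lambda) / (1 - fixed_lambda)
  } else if (m < 100L) {
    # small collections: the spline estimate is unstable; fall back to the
    # conservative BH choice pi0 = 1
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(sp, x = max(lambda))$y
  }
  pi0 <- min(max(pi0, .Machine$double.eps), 1)
  # step-up from the largest p
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * pv[o] * m / (m:1)
  q <- pmin(cummin(q), 1)[ro]
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Correlate neuronal trajectories with HGF parameter trajectories
#'
#' Computes, for every (cell, parameter) pair, the Pearson correlation
#' between the cell's residual trajectory and the aversive-subset HGF
#' parameter trajectory, the two-sided p-value, and Storey q-values with
#' significance at `q < q_threshold`. Trials where a parameter carries a
#' missing (guarded) value are dropped pairwise. The population-level
#' correlation of the cell-averaged trajectory with each parameter is also
#' computed.
#'
#' @param trajectories Tibble with `cell`, `k_av` and the column named by
#'   `value` (default `dz_res`), e.g. from [remove_decay()].
#' @param hgf Aversive-subset HGF trajectories ([subset_aversive()]); its
#'   row count must match the per-cell trial count.
#' @param value Trajectory column to correlate (default `"dz_res"`).
#' @param q_threshold Significance threshold on q (default 0.05).
#' @param pool `"all"` (default) pools p-values across cells and parameters
#'   before the Storey conversion; `"parameter"` converts within each
#'   parameter separately.
#' @return An object of class `correlation_table`: tibble with `cell`,
#'   `parameter`, `level`, `rho`, `p`, `q`, `significant`, `polarity`, and
#'   attributes `population` (per-parameter population-level correlations),
#'   `pi0`, `n_trials`, `parameter_cor` (the 13 x 13 parameter correlation
#'   matrix, reporting collinearity among parameters).
#' @export
correlate_trajectories <- function(trajectories, hgf, value = "dz_res",
                                   q_threshold = 0.05, pool = c("all", "parameter")) {
  pool <- match.arg(pool)
  params <- hgf_parameter_names()
  if (!all(params %in% names(hgf))) {
    abort("`hgf` must contain the 13 HGF parameter columns")
  }
  neural <- t(trajectory_matrix(trajectories, value))  # trials x cells
  H <- as.matrix(as_tibble(hgf)[, params])
  if (nrow(H) != nrow(neural)) {
    abort(sprintf("trajectory length (%d) does not match HGF subset length (%d)",
                  nrow(neural), nrow(H)))
  }
  zero_var <- apply(neural, 2, function(v) var(v, na.rm = TRUE)) <= 0
  if (any(zero_var)) {
    warn(sprintf("%d zero-variance trajectories skipped", sum(zero_var)))
    neural <- neural[, !zero_var, drop = FALSE]
  }
  cp <- cor_with_p(neural, H)
  cell_ids <- as.integer(colnames(neural)) %||% seq_len(ncol(neural))
  tbl <- tibble(
    cell = rep(cell_ids, times = length(params)),
    parameter = rep(params, each = ncol(neural)),
    rho = as.numeric(cp$rho),
    p = as.numeric(cp$p)
  )
  tbl$level <- unname(hgf_parameter_levels()[tbl$parameter])
  if (pool == "all") {
    qv <- storey_qvalues(tbl$p)
    tbl$q <- as.numeric(qv)
    pi0 <- attr(qv, "pi0")
  } else {
    tbl <- tbl |>
      dplyr::group_by(.data$parameter) |>
      dplyr::mutate(q = as.numeric(storey_qvalues(.data$p))) |>
      dplyr::ungroup()
    pi0 <- NA_real_
  }
  tbl <- tbl |>
    dplyr::mutate(
      significant = !is.na(.data$q) & .data$q < q_threshold,
      polarity = dplyr::case_when(
        !.data$significant ~ "none",
        .data$rho > 0 ~ "positive",
        TRUE ~ "negative")
    ) |>
    dplyr::select("cell", "parameter", "level", "rho", "p", "q",
                  "significant", "polarity")
  pop_traj <- rowMeans(neural, na.rm = TRUE)
  pop_cp <- cor_with_p(matrix(pop_traj, ncol = 1), H)
  population <- tibble(parameter = params,
                       level = unname(hgf_parameter_levels()[params]),
                       rho = as.numeric(pop_cp$rho),
                       p = as.numeric(pop_cp$p))
  structure(tbl,
            class = c("correlation_table", class(tbl)),
            population = population,
            pi0 = pi0,
            n_trials = nrow(H),
            q_threshold = q_threshold,
            parameter_cor = suppressWarnings(
              cor(H, use = "pairwise.complete.obs")))
}

#' Per-parameter and per-level significance summaries
#'
#' Summarizes a correlation table as the percentage of cells significantly
#' correlated with each parameter (split by polarity), and the cumulative
#' sum of those percentages at each hierarchical level.
#'
#' @param corr A [correlate_trajectories()] result.
#' @return List with `parameters` (tibble: parameter, level, pct_positive,
#'   pct_negative, pct_significant) and `levels` (tibble: level,
#'   pct_cumsum, n_significant_cells).
#' @export
level_cumsum <- function(corr) {
  if (is.null(corr$parameter) || is.null(corr$level)) {
    abort("`corr` must be a correlation table with parameter and level columns")
  }
  n_cells <- dplyr::n_distinct(corr$cell)
  params <- corr |>
    dplyr::group_by(.data$parameter, .data$level) |>
    dplyr::summarise(
      pct_positive = 100 * sum(.data$polarity == "positive") / n_cells,
      pct_negative = 100 * sum(.data$polarity == "negative") / n_cells,
      pct_significant = 100 * sum(.data$significant) / n_cells,
      .groups = "drop"
    )
  levels_tbl <- params |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(pct_cumsum = sum(.data$pct_significant),
                     .groups = "drop")
  sig_cells <- corr |>
    dplyr::filter(.data$significant) |>
    dplyr::distinct(.data$cell, .data$level) |>
    dplyr::count(.data$level, name = "n_significant_cells")
  levels_tbl <- levels_tbl |>
    dplyr::left_join(sig_cells, by = "level") |>
    dplyr::mutate(n_significant_cells =
                    dplyr::coalesce(.data$n_significant_cells, 0L))
  list(parameters = params, levels = levels_tbl)
}

#' Shuffling test for correlation-polarity bias
#'
#' Tests, per HGF parameter, whether significantly correlated cells are
#' biased towards one correlation polarity. The observed statistic is the
#' count of positive-significant minus negative-significant cells. The null
#' distribution is built by independently permuting each cell's trajectory
#' across trials and recomputing the full correlation-significance pipeline
#' (Pearson, Storey q, threshold) per repetition. Two-sided p-values are
#' null exceedances; q-values apply Benjamini-Hochberg FDR across the 13
#' parameters.
#'
#' @param trajectories Tibble with `cell`, `k_av` and the `value` column.
#' @param hgf Aversive-subset HGF trajectories.
#' @param n_shuffles Number of permutation repetitions (default 10000).
#' @param seed Integer seed for the permutations.
#' @inheritParams correlate_trajectories
#' @return Tibble with `parameter`, `level`, `observed` (signed count),
#'   `n_positive`, `n_negative`, `p`, `q`.
#' @export
polarity_shuffle_test <- function(trajectories, hgf, n_shuffles = 10000,
                                  seed = 1, value = "dz_res",
                                  q_threshold = 0.05) {
  params <- hgf_parameter_names()
  neural <- t(trajectory_matrix(trajectories, value))  # trials x cells
  H <- as.matrix(as_tibble(hgf)[, params])
  n_tr <- nrow(neural); n_cells <- ncol(neural)
  if (nrow(H) != n_tr) abort("trajectory/HGF length mismatch")

  polarity_counts <- function(x) {
    cp <- cor_with_p(x, H)
    q <- storey_qvalues(as.numeric(cp$p))
    sig <- matrix(!is.na(q) & q < q_threshold, n_cells, length(params))
    pos <- colSums(sig & cp$rho > 0)
    neg <- colSums(sig & cp$rho < 0)
    list(stat = pos - neg, pos = pos, neg = neg)
  }
  obs <- polarity_counts(neural)

  null_stats <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(r) {
      perm <- vapply(seq_len(n_cells),
                     function(i) neural[sample.int(n_tr), i],
                     numeric(n_tr))
      polarity_counts(perm)$stat
    }, numeric(length(params)))
  })  # params x n_shuffles

  p <- vapply(seq_along(params), function(j) {
    if (obs$pos[j] + obs$neg[j] == 0) return(1)
    (1 + sum(abs(null_stats[j, ]) >= abs(obs$stat[j]))) / (n_shuffles + 1)
  }, numeric(1))
  tibble(parameter = params,
         level = unname(hgf_parameter_levels()[params]),
         observed = obs$stat,
         n_positive = obs$pos,
         n_negative = obs$neg,
         p = p,
         q = stats::p.adjust(p, method = "BH"))
}

#' Chi-squared comparison of significant-cell counts between groups
#'
#' Pearson chi-squared test (without continuity correction) on the 2 x 2
#' table of (significant, not significant) cells in two groups, optionally
#' over a family of comparisons with Benjamini-Hochberg FDR correction.
#'
#' @param sig_a,n_a Significant count and total cells in group A (vectors
#'   for a family of comparisons).
#' @param sig_b,n_b Same for group B.
#' @param labels Optional comparison labels.
#' @return Tibble with `comparison`, `chisq`, `df`, `p`, `q`.
#' @export
group_chi2 <- function(sig_a, n_a, sig_b, n_b, labels = NULL) {
  m <- length(sig_a)
  if (length(n_a) != m || length(sig_b) != m || length(n_b) != m) {
    abort("count vectors must share a length")
  }
  res <- purrr::map(seq_len(m), function(i) {
    tab <- rbind(c(sig_a[i], n_a[i] - sig_a[i]),
                 c(sig_b[i], n_b[i] - sig_b[i]))
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd == 0)) {
      abort("a cell has zero expected count; use an exact test instead")
    }
    chisq <- sum((tab - expd)^2 / expd)
    tibble(chisq = chisq, df = 1,
           p = pchisq(chisq, 1, lower.tail = FALSE))
  }) |> dplyr::bind_rows()
  res |>
    dplyr::mutate(comparison = labels %||% paste0("comparison", seq_len(m)),
                  .before = 1) |>
    dplyr::mutate(q = stats::p.adjust(.data$p, method = "BH"))
}
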