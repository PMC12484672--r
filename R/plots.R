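#' Plot the trial structure of a session
#'
#' Raster of the presented trials: cue identity, outcome, and the
#' contingency bit, with epoch boundaries marked.
#'
#' @param session A [generate_session()] result.
#' @return A ggplot object.
#' @export
plot_session <- function(session) {
  df <- as_tibble(session)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_tile(ggplot2::aes(y = "cue", fill = .data$cue), height = 0.9) +
    ggplot2::geom_tile(ggplot2::aes(y = "outcome", fill = .data$outcome),
                       height = 0.9) +
    ggplot2::geom_point(
      data = df |> dplyr::filter(.data$u == 1),
      ggplot2::aes(y = "unexpected"), shape = 124, size = 2) +
    ggplot2::geom_vline(
      xintercept = df |>
        dplyr::group_by(.data$block) |>
        dplyr::summarise(b = min(.data$trial)) |>
        dplyr::pull(.data$b) - 0.5,
      linetype = "dashed", colour = "grey40") +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = "presented trial", y = NULL, fill = NULL,
                  title = "Cue-outcome sequence") +
    ggplot2::theme_minimal()
}

#' Plot HGF parameter trajectories
#'
#' One facet per parameter, over the trial index of the (possibly
#' aversive-subset) trajectory table.
#'
#' @param object An `hgf_trajectories` tibble from [run_hgf()].
#' @param parameters Which parameters to show (default all 13).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hgf_trajectories <- function(object, parameters = hgf_parameter_names(),
                                      ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(.trial = dplyr::row_number()) |>
    dplyr::select(".trial", dplyr::all_of(parameters)) |>
    tidyr::pivot_longer(-".trial", names_to = "parameter") |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = parameters))
  ggplot2::ggplot(df, ggplot2::aes(.data$.trial, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 3) +
    ggplot2::labs(x = "trial", y = NULL,
                  title = "HGF observer trajectories") +
    ggplot2::theme_minimal()
}

#' Plot epoch-normalized contextual modulation
#'
#' Distribution of the per-cell modulation `dz` by epoch, optionally
#' faceted by group.
#'
#' @param modulation Tibble from [epoch_modulation()] (optionally with a
#'   `group` column).
#' @return A ggplot object.
#' @export
plot_epoch_modulation <- function(modulation) {
  p <- ggplot2::ggplot(modulation,
                       ggplot2::aes(.data$epoch, .data$dz, fill = .data$epoch)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2,
                          show.legend = FALSE) +
    ggplot2::scale_fill_brewer(palette = "Dark2") +
    ggplot2::labs(x = "epoch", y = expression(Delta * z),
                  title = "Contextual modulation by epoch") +
    ggplot2::theme_minimal()
  if ("group" %in% names(modulation)) p <- p + ggplot2::facet_wrap(~group)
  p
}

#' Bubble plot of HGF parameter representation
#'
#' Percentage of cells significantly correlated with each HGF parameter,
#' split by polarity (circle area = percentage), with the per-level
#' cumulative sums alongside.
#'
#' @param object A `correlation_table` from [correlate_trajectories()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_table <- function(object, ...) {
  ls <- level_cumsum(object)
  df <- ls$parameters |>
    tidyr::pivot_longer(c("pct_positive", "pct_negative"),
                        names_to = "polarity", values_to = "pct") |>
    dplyr::mutate(polarity = ifelse(.data$polarity == "pct_positive",
                                    "positive", "negative"),
                  parameter = factor(.data$parameter,
                                     levels = hgf_parameter_names()))
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$polarity)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$pct, colour = .data$polarity),
                        alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::scale_colour_manual(values = c(positive = "#c0392b",
                                            negative = "#2980b9")) +
    ggplot2::facet_grid(~level, scales = "free_x", space = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = NULL, size = "% cells",
                  title = "Neural representation of HGF parameters") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a fitted decay curve
#'
#' Observed epoch-averaged population trajectory and the fitted power
#' function.
#'
#' @param object A `decay_fit` from [fit_decay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  cf <- object$coefficients
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$j, .data$mean_dz)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#c0392b") +
    ggplot2::labs(
      x = "within-epoch aversive trial",
      y = expression(bar(Delta * z)),
      title = sprintf("f(j) = %.3g j^%.3g + %.3g", cf[["a"]], cf[["b"]],
                      cf[["c"]])) +
    ggplot2::theme_minimal()
}

#' Plot evoked pupil traces
#'
#' Trial-averaged proportional pupil change around the aversive outcome,
#' one line per epoch.
#'
#' @param response A `pupil_response` from [evoked_trace()].
#' @return A ggplot object.
#' @export
plot_evoked_pupil <- function(response) {
  ggplot2::ggplot(response$trace,
                  ggplot2::aes(.data$t, .data$a, colour = .data$epoch)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::scale_colour_brewer(palette = "Dark2") +
    ggplot2::labs(x = "time from outcome onset (s)",
                  y = expression(a(t) == A(t) / A[0]),
                  title = "Evoked pupil response") +
    ggplot2::theme_minimal()
}

#' Plot a reverse-correlation kernel slice
#'
#' Spatial map of the response-weighted average at its peak latency, with
#' the fitted Gaussian center marked when a fit is supplied.
#'
#' @param kernel An `rf_kernel` from [reverse_correlation()].
#' @param fit Optional `rf_fit` overlay.
#' @return A ggplot object.
#' @export
plot_rf <- function(kernel, fit = NULL) {
  power <- colSums(abs(kernel$kernel))
  slice <- kernel$kernel[, which.max(power)]
  df <- tibble(
    x = rep(seq_len(kernel$nx), times = kernel$ny),
    y = rep(seq_len(kernel$ny), each = kernel$nx),
    w = slice
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "field x", y = "field y", fill = "RWA",
                  title = "Receptive field (peak-latency slice)") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    p <- p + ggplot2::annotate("point", x = fit$center[1], y = fit$center[2],
                               shape = 3, size = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
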