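#' Task-design configuration for the implicit visual learning task
#'
#' The task pairs oriented-grating cues (vertical or horizontal) with either
#' an aversive visual outcome or an omitted (gray-screen) outcome. A stable
#' environment of `stable_blocks` 72-trial blocks with a fixed expected
#' cue-outcome contingency probability is followed by a volatile environment
#' in which the expected-contingency probability changes every
#' `volatile_block_len` trials. Expected pairings are vertical-aversive and
#' horizontal-omitted; the complementary pairings are unexpected.
#'
#' Counts are realized exactly: each block contains `round(p * n)` expected
#' trials, and cues, outcomes and aversive subtypes are balanced within each
#' analysis epoch, so every subject sees identical contingency totals. The
#' within-block order is a seeded permutation of the fixed label multiset
#' (one seed per block), never i.i.d. draws.
#'
#' @param stable_blocks Number of presented 72-trial stable blocks (default 3;
#'   the first is flagged `excluded` when `exclude_first_stable_block` is on,
#'   leaving early-stable and late-stable analysis epochs).
#' @param trials_per_block Trials per stable block and per analysis epoch
#'   (default 72). Must be divisible by `2 * n_aversive_types`.
#' @param volatile_block_len Trials per volatile sub-block (default 24).
#' @param volatile_probs Expected-contingency probability of each volatile
#'   sub-block (default `c(1/6, 1/2, 5/6)`); lengths must satisfy
#'   `length(volatile_probs) * volatile_block_len == trials_per_block`.
#' @param stable_expected_prob Expected-contingency probability in the stable
#'   environment (default 5/6, i.e. 83.4%). Use 1 for the training-day
#'   deterministic session.
#' @param n_aversive_types Number of distinct aversive outcome stimuli
#'   (default 6: sweep-left, sweep-right, sweep-left-loom, sweep-right-loom,
#'   slow-loom, fast-loom).
#' @param cue_duration_s,isi_s,outcome_duration_s,iti_s Trial timing in
#'   seconds (defaults 1.0, 0.5, 2.0, 1.0).
#' @param seeds Integer vector with one seed per block (stable blocks plus
#'   one for the volatile epoch). Defaults to a fixed sequence so that every
#'   simulated subject sees the same sequences.
#' @param exclude_first_stable_block Flag (default `TRUE`): label all but the
#'   last two stable blocks as `excluded`, restricting the analyzed view to
#'   the ES/LS/VL epochs.
#' @param balance_unexpected_across_cues Flag (default `TRUE`): split the
#'   unexpected-contingency trials of a block evenly between the two cue
#'   types (requires even expected counts).
#'
#' @return A list of class `design_config`.
#' @seealso [generate_session()]
#' @export
design_config <- function(stable_blocks = 3L,
                          trials_per_block = 72L,
                          volatile_block_len = 24L,
                          volatile_probs = c(1 / 6, 1 / 2, 5 / 6),
                          stable_expected_prob = 5 / 6,
                          n_aversive_types = 6L,
                          cue_duration_s = 1.0,
                          isi_s = 0.5,
                          outcome_duration_s = 2.0,
                          iti_s = 1.0,
                          seeds = NULL,
                          exclude_first_stable_block = TRUE,
                          balance_unexpected_across_cues = TRUE) {
  stable_blocks <- stopifnot_scalar_count(stable_blocks, "stable_blocks")
  trials_per_block <- stopifnot_scalar_count(trials_per_block, "trials_per_block")
  volatile_block_len <- stopifnot_scalar_count(volatile_block_len, "volatile_block_len")
  n_aversive_types <- stopifnot_scalar_count(n_aversive_types, "n_aversive_types")
  if (trials_per_block %% (2L * n_aversive_types) != 0L) {
    abort("`trials_per_block` must be divisible by 2 * n_aversive_types")
  }
  if (length(volatile_probs) * volatile_block_len != trials_per_block) {
    abort("length(volatile_probs) * volatile_block_len must equal trials_per_block")
  }
  if (any(volatile_probs < 0 | volatile_probs > 1) ||
      stable_expected_prob < 0 || stable_expected_prob > 1) {
    abort("contingency probabilities must lie in [0, 1]")
  }
  n_blocks <- stable_blocks + 1L
  if (is.null(seeds)) seeds <- 2000L + seq_len(n_blocks)
  if (length(seeds) != n_blocks) {
    abort(sprintf("`seeds` must supply one seed per block (%d needed)", n_blocks))
  }
  if (anyDuplicated(seeds)) warn("duplicate block seeds supplied")
  structure(
    list(stable_blocks = stable_blocks,
         trials_per_block = trials_per_block,
         volatile_block_len = volatile_block_len,
         volatile_probs = volatile_probs,
         stable_expected_prob = stable_expected_prob,
         n_aversive_types = n_aversive_types,
         cue_duration_s = cue_duration_s,
         isi_s = isi_s,
         outcome_duration_s = outcome_duration_s,
         iti_s = iti_s,
         seeds = as.integer(seeds),
         exclude_first_stable_block = isTRUE(exclude_first_stable_block),
         balance_unexpected_across_cues = isTRUE(balance_unexpected_across_cues)),
    class = "design_config"
  )
}

aversive_type_names <- function(n) {
  canonical <- c("sweep-left", "sweep-right", "sweep-left-loom",
                 "sweep-right-loom", "slow-loom", "fast-loom")
  if (n <= length(canonical)) canonical[seq_len(n)] else
    c(canonical, paste0("aversive-", seq_len(n - length(canonical))))
}

# Balanced (cue, outcome) label multiset for one block of n trials at
# expected-contingency probability p, as a two-column tibble in fixed order.
block_label_multiset <- function(n, p, balance) {
  e <- round(p * n)
  x <- n - e
  if (balance) {
    if (e %% 2L != 0L || x %% 2L != 0L) {
      abort(sprintf(
        "cannot balance unexpected trials across cues: round(p * n) = %d is odd", e))
    }
    cue <- c(rep("vertical", e / 2), rep("horizontal", x / 2),
             rep("horizontal", e / 2), rep("vertical", x / 2))
    outcome <- c(rep("aversive", e / 2 + x / 2), rep("omitted", e / 2 + x / 2))
  } else {
    # expected trials split as evenly as possible; remainder to vertical-aversive
    ev <- ceiling(e / 2); eh <- e - ev
    xa <- n / 2 - ev  # horizontal-aversive count
    xo <- n / 2 - eh  # vertical-omitted count
    if (xa < 0 || xo < 0) abort("expected count exceeds per-cue capacity")
    cue <- c(rep("vertical", ev), rep("horizontal", xa),
             rep("horizontal", eh), rep("vertical", xo))
    outcome <- c(rep("aversive", ev + xa), rep("omitted", eh + xo))
  }
  tibble(cue = cue, outcome = outcome)
}

contingency_bit <- function(cue, outcome) {
  as.integer(!((cue == "vertical" & outcome == "aversive") |
                 (cue == "horizontal" & outcome == "omitted")))
}

#' Generate the presented trial sequence of a session
#'
#' Builds the full presented trial table: `stable_blocks` stable blocks at
#' `stable_expected_prob`, followed by one volatile epoch whose sub-blocks
#' follow `volatile_probs`. Within every block the (cue, outcome) labels are
#' a seeded permutation of the exact balanced multiset; aversive subtypes are
#' a seeded permutation of the balanced subtype multiset over each analysis
#' epoch's aversive slots. Identical configurations therefore yield
#' bit-identical sequences.
#'
#' @param config A [design_config()].
#' @return An object of class `session_design`: a tibble with one row per
#'   presented trial and columns `trial` (presented index), `k` (1-based
#'   index within the analyzed task, `NA` for excluded trials), `block`,
#'   `epoch` (`excluded`, `ES`, `LS` or `VL`), `cue`, `outcome`,
#'   `aversive_type`, `u` (contingency bit: 0 = expected pairing), `onset_s`
#'   and `outcome_onset_s`. The configuration is attached as attribute
#'   `config`.
#' @examples
#' sess <- generate_session(design_config())
#' table(analyzed_trials(sess)$epoch)
#' @export
generate_session <- function(config = design_config()) {
  if (!inherits(config, "design_config")) abort("`config` must be a design_config")
  nb <- config$stable_blocks
  n <- config$trials_per_block

  blocks <- vector("list", nb + 1L)
  for (b in seq_len(nb)) {
    labels <- block_label_multiset(n, config$stable_expected_prob,
                                   config$balance_unexpected_across_cues)
    idx <- shuffle(seq_len(n), config$seeds[b])
    blocks[[b]] <- labels[idx, ] |> dplyr::mutate(block = b)
  }
  # volatile epoch: sub-blocks shuffled from a single per-epoch seed stream
  vol <- with_seed(config$seeds[nb + 1L], {
    purrr::map(config$volatile_probs, function(p) {
      labels <- block_label_multiset(config$volatile_block_len, p,
                                     config$balance_unexpected_across_cues)
      labels[sample(nrow(labels)), ]
    }) |> dplyr::bind_rows()
  }) |> dplyr::mutate(block = nb + 1L)
  blocks[[nb + 1L]] <- vol

  trials <- dplyr::bind_rows(blocks)
  n_excluded <- if (config$exclude_first_stable_block) max(nb - 2L, 0L) else 0L
  epoch_of_block <- c(rep("excluded", n_excluded),
                      rep(c("ES", "LS"), length.out = nb - n_excluded),
                      "VL")
  if (nb - n_excluded > 2L) {
    warn("more than two analyzed stable blocks; extra blocks labeled ES/LS cyclically")
  }
  trials <- trials |>
    dplyr::mutate(
      trial = dplyr::row_number(),
      epoch = factor(epoch_of_block[.data$block],
                     levels = c("excluded", "ES", "LS", "VL")),
      u = contingency_bit(.data$cue, .data$outcome)
    )
  analyzed <- trials$epoch != "excluded"
  trials$k <- NA_integer_
  trials$k[analyzed] <- seq_len(sum(analyzed))

  # aversive subtypes: balanced multiset permuted per analysis epoch
  # (excluded block gets its own permutation so presented stimuli are defined)
  types <- aversive_type_names(config$n_aversive_types)
  trials$aversive_type <- "none"
  with_seed(sum(config$seeds) + 1L, {
    for (ep in split(seq_len(nrow(trials)),
                     list(trials$epoch, trials$block), drop = TRUE)) {
      slots <- ep[trials$outcome[ep] == "aversive"]
      if (length(slots) == 0L) next
      reps <- ceiling(length(slots) / length(types))
      multiset <- rep(types, reps)[seq_along(slots)]
      trials$aversive_type[slots] <- sample(multiset)
    }
  })

  dur <- config$cue_duration_s + config$isi_s + config$outcome_duration_s +
    config$iti_s
  trials <- trials |>
    dplyr::mutate(
      onset_s = (.data$trial - 1) * dur,
      outcome_onset_s = .data$onset_s + config$cue_duration_s + config$isi_s
    ) |>
    dplyr::select("trial", "k", "block", "epoch", "cue", "outcome",
                  "aversive_type", "u", "onset_s", "outcome_onset_s")
  structure(trials, class = c("session_design", class(trials)), config = config)
}

#' Analyzed view of a session (ES/LS/VL epochs only)
#'
#' @param session A [generate_session()] result.
#' @return Tibble of the analyzed trials, ordered by `k`.
#' @export
analyzed_trials <- function(session) {
  session |>
    dplyr::filter(.data$epoch != "excluded") |>
    dplyr::arrange(.data$k) |>
    as_tibble()
}

#' Binary contingency vector of the analyzed trials
#'
#' Element `k` is 0 when trial `k` showed an expected cue-outcome pairing
#' (vertical-aversive or horizontal-omitted) and 1 otherwise. This vector is
#' the sensory input `u` of the hierarchical Gaussian filter.
#'
#' @inheritParams analyzed_trials
#' @return Integer vector over the analyzed trials.
#' @export
contingency_vector <- function(session) {
  analyzed_trials(session)$u
}

#' Analyzed-trial indices of one epoch
#'
#' @inheritParams analyzed_trials
#' @param epoch One of `"ES"`, `"LS"`, `"VL"`.
#' @return Integer vector of `k` indices.
#' @export
epoch_index <- function(session, epoch) {
  epoch <- match.arg(epoch, c("ES", "LS", "VL"))
  at <- analyzed_trials(session)
  at$k[at$epoch == epoch]
}

#' Write a session design to a tab-separated file
#'
#' @inheritParams analyzed_trials
#' @param path Output file path.
#' @export
write_session <- function(session, path) {
  utils::write.table(as.data.frame(session), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
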