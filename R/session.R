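#' Session configuration for a simulated oddball recording
#'
#' Describes one recording session of the conveyor-belt oddball experiment:
#' blocks of fixed-duration trials in which a travelling box either passes
#' normally (control) or is interrupted by one of two rare deviant events
#' (explosion, burning). Deviants occur with a fixed overall fraction,
#' realized as exact per-session counts split equally between the two deviant
#' conditions.
#'
#' @param n_blocks number of blocks (default 8).
#' @param trials_per_block trials per block (default 30).
#' @param trial_duration trial length in seconds (default 6).
#' @param deviant_fraction fraction of deviant trials (default 1/3).
#' @param sampling_rate sampling rate in Hz (default 250).
#' @param inter_trial_gap length-2 numeric, uniform range of the inter-trial
#'   rest gap in seconds (default c(1.3, 2)).
#' @param stimulus_delay seconds from trial start to the stimulus onset
#'   marker (the box reaches the event position 1 s after entering the
#'   scene).
#' @param seed optional default seed used when none is passed to
#'   [build_schedule()].
#' @return object of class `session_config`.
#' @export
session_config <- function(n_blocks = 8, trials_per_block = 30,
                           trial_duration = 6, deviant_fraction = 1 / 3,
                           sampling_rate = 250,
                           inter_trial_gap = c(1.3, 2),
                           stimulus_delay = 1.0,
                           seed = NULL) {
  assert_scalar_num(n_blocks, "n_blocks", 1)
  assert_scalar_num(trials_per_block, "trials_per_block", 1)
  assert_scalar_num(trial_duration, "trial_duration", 1e-3)
  assert_scalar_num(deviant_fraction, "deviant_fraction", 0, 1)
  assert_scalar_num(sampling_rate, "sampling_rate", 1e-3)
  assert_scalar_num(stimulus_delay, "stimulus_delay", 0)
  if (length(inter_trial_gap) != 2 || any(inter_trial_gap < 0) ||
      inter_trial_gap[1] > inter_trial_gap[2])
    stop("'inter_trial_gap' must be an increasing non-negative range", call. = FALSE)
  n_trials <- n_blocks * trials_per_block
  n_dev <- round(deviant_fraction * n_trials)
  if (n_dev %% 2 != 0)
    stop(sprintf(
      "deviant_fraction %.4f of %d trials gives %d deviants, not splittable equally between the explosion and burning conditions",
      deviant_fraction, n_trials, n_dev), call. = FALSE)
  structure(list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    trial_duration = trial_duration,
    deviant_fraction = deviant_fraction,
    sampling_rate = sampling_rate,
    inter_trial_gap = inter_trial_gap,
    stimulus_delay = stimulus_delay,
    seed = seed
  ), class = "session_config")
}

#' Build a randomized trial schedule
#'
#' Draws a randomized ordering of conditions with exact per-condition counts
#' (`round(deviant_fraction * n_trials)` deviants split equally between
#' explosion and burning; the remainder control) and stimulus-onset times that
#' respect the trial duration and a uniformly drawn inter-trial gap.
#'
#' @param cfg a [session_config()].
#' @param seed integer seed; falls back to `cfg$seed`.
#' @return data.frame of class `oddball_schedule` with columns `trial`,
#'   `block`, `condition`, `trial_start_s`, `onset_s`, `onset_sample`
#'   (1-based), plus attributes `config`.
#' @export
build_schedule <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "session_config"))
  if (is.null(seed)) stop("a seed is required for a reproducible schedule", call. = FALSE)
  n_trials <- cfg$n_blocks * cfg$trials_per_block
  n_dev <- round(cfg$deviant_fraction * n_trials)
  conds <- c(rep("explosion", n_dev / 2), rep("burning", n_dev / 2),
             rep("control", n_trials - n_dev))
  sds <- derive_seeds(seed, 2)
  order_cond <- with_seed(sds[1], sample(conds))
  gaps <- with_seed(sds[2], stats::runif(n_trials, cfg$inter_trial_gap[1],
                                         cfg$inter_trial_gap[2]))
  # trial i starts after i-1 full trials and i-1 gaps; 2 s lead-in so that a
  # pre-stimulus epoch window always fits
  starts <- 2 + c(0, cumsum(cfg$trial_duration + gaps))[seq_len(n_trials)]
  onsets <- starts + cfg$stimulus_delay
  sched <- data.frame(
    trial = seq_len(n_trials),
    block = rep(seq_len(cfg$n_blocks), each = cfg$trials_per_block),
    condition = order_cond,
    trial_start_s = starts,
    onset_s = onsets,
    onset_sample = as.integer(round(onsets * cfg$sampling_rate)) + 1L,
    stringsAsFactors = FALSE
  )
  stopifnot(all(diff(sched$onset_s) > 0))
  attr(sched, "config") <- cfg
  class(sched) <- c("oddball_schedule", "data.frame")
  sched
}

#' Per-condition trial counts of a schedule
#' @param schedule an `oddball_schedule`.
#' @return named integer vector over explosion/burning/control.
#' @export
schedule_counts <- function(schedule) {
  out <- c(explosion = 0L, burning = 0L, control = 0L)
  tab <- table(schedule$condition)
  out[names(tab)] <- as.integer(tab)
  out
}
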