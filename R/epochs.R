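#' Segment a recording into stimulus-locked epochs
#'
#' One epoch per event, covering `window[1] <= t < window[2]` seconds
#' relative to the stimulus onset under a half-open sampling convention
#' (375 samples for the default -0.5..+1 s window at 250 Hz). Events whose
#' window falls outside the recording are skipped and logged.
#'
#' @param rec a `continuous_recording` with events.
#' @param window length-2 numeric, epoch window in seconds around onset.
#' @return object of class `epoch_set`: list with `data` (trials x channels x
#'   samples array), `channels`, `sampling_rate`, `window`, `conditions`,
#'   `kept` (logical), `reject_reason`, `skipped` (data.frame of dropped
#'   events), `subject_id`.
#' @export
segment_epochs <- function(rec, window = c(-0.5, 1.0)) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (nrow(rec$events) == 0)
    stop("recording has no events to epoch", call. = FALSE)
  if (window[1] > 0 || window[2] <= 0)
    stop("epoch window must contain the onset", call. = FALSE)
  fs <- rec$sampling_rate
  n <- ncol(rec$data)
  off0 <- as.integer(round(window[1] * fs))
  n_samp <- as.integer(round((window[2] - window[1]) * fs))
  first <- rec$events$onset_sample + off0
  last <- first + n_samp - 1L
  ok <- first >= 1L & last <= n
  if (!any(ok))
    stop("no event has a fully interior epoch window", call. = FALSE)
  kept_ev <- which(ok)
  data <- array(0, dim = c(length(kept_ev), nrow(rec$data), n_samp),
                dimnames = list(NULL, rec$channel_names, NULL))
  for (k in seq_along(kept_ev)) {
    j <- kept_ev[k]
    data[k, , ] <- rec$data[, first[j]:last[j]]
  }
  skipped <- rec$events[!ok, , drop = FALSE]
  if (nrow(skipped)) skipped$reason <- "window outside recording"
  structure(list(
    data = data,
    channels = rec$channel_names,
    sampling_rate = fs,
    window = window,
    conditions = rec$events$condition[ok],
    kept = rep(TRUE, length(kept_ev)),
    reject_reason = rep(NA_character_, length(kept_ev)),
    skipped = skipped,
    baseline_corrected = FALSE,
    subject_id = rec$subject_id
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d kept) x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], sum(x$kept), dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate))
  invisible(x)
}

# time vector (s, relative to onset) of an epoch_set
epoch_times <- function(es) {
  es$window[1] + (seq_len(dim(es$data)[3]) - 1) / es$sampling_rate
}

#' Local baseline correction
#'
#' Subtracts, per epoch and channel, the mean over the full pre-onset window
#' (t < 0). Idempotent.
#'
#' @param es an `epoch_set`.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  pre <- epoch_times(es) < 0
  if (!any(pre)) stop("no pre-onset samples for baseline correction", call. = FALSE)
  bl <- apply(es$data[, , pre, drop = FALSE], c(1, 2), mean)
  es$data <- es$data - as.vector(bl)   # array recycling over dim 3
  es$baseline_corrected <- TRUE
  es
}

# excess kurtosis of a vector
excess_kurtosis <- function(x) {
  m <- mean(x); v <- mean((x - m)^2)
  if (v <= 0) return(0)
  mean((x - m)^4) / v^2 - 3
}

#' Automated variance/kurtosis trial rejection
#'
#' Flags epochs whose pooled per-epoch variance or excess kurtosis (mean over
#' the selected channels) lies more than `z_var` / `z_kurt` robust standard
#' deviations (scaled MAD) above the ensemble median. The ensemble statistics
#' are computed within each condition separately, so that genuine evoked
#' energy on rare deviant trials is not mistaken for an artifact against a
#' control-dominated ensemble. This is the automated replacement for visual
#' inspection of deviant trials.
#'
#' @param es an `epoch_set`.
#' @param z_var,z_kurt rejection thresholds in robust SDs (default 3).
#' @param channels channels pooled for the statistics (default: the feature
#'   channels present in the set).
#' @return the `epoch_set` with updated `kept` and `reject_reason`.
#' @export
reject_trials <- function(es, z_var = 3, z_kurt = 3,
                          channels = intersect(feature_channels(), es$channels)) {
  stopifnot(inherits(es, "epoch_set"))
  n_tr <- dim(es$data)[1]
  if (n_tr < 3) stop("need at least 3 epochs for ensemble rejection", call. = FALSE)
  ci <- match(channels, es$channels)
  if (anyNA(ci)) stop("unknown channel in 'channels'", call. = FALSE)
  v <- k <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    seg <- es$data[i, ci, , drop = FALSE]
    m <- array(seg, dim = dim(seg)[2:3])
    v[i] <- mean(apply(m, 1, stats::var))
    k[i] <- mean(apply(m, 1, excess_kurtosis))
  }
  # variance scored on the log scale (its sampling distribution is
  # right-skewed on the raw scale); medians per condition so evoked energy
  # on deviant trials is not mistaken for an artifact, scale pooled across
  # conditions for a stable estimate
  robust_z <- function(x) {
    med <- stats::ave(x, es$conditions, FUN = stats::median)
    resid <- x - med
    s <- stats::mad(resid)
    if (s <= 0) return(numeric(length(x)))
    resid / s
  }
  zv <- robust_z(log(pmax(v, .Machine$double.xmin)))
  zk <- robust_z(k)
  bad_v <- is.finite(z_var) & zv > z_var
  bad_k <- is.finite(z_kurt) & zk > z_kurt
  es$kept <- es$kept & !(bad_v | bad_k)
  es$reject_reason[bad_v] <- "variance"
  es$reject_reason[bad_k & !bad_v] <- "kurtosis"
  es$reject_reason[bad_k & bad_v] <- "variance+kurtosis"
  if (!any(es$kept))
    stop("all epochs rejected; relax z_var / z_kurt", call. = FALSE)
  es
}

#' Subset an epoch set by condition and/or kept status
#'
#' @param es an `epoch_set`.
#' @param condition optional condition label.
#' @param kept_only drop rejected epochs (default TRUE).
#' @return the subset `epoch_set`.
#' @export
subset_epochs <- function(es, condition = NULL, kept_only = TRUE) {
  sel <- rep(TRUE, dim(es$data)[1])
  if (!is.null(condition)) sel <- sel & es$conditions %in% condition
  if (kept_only) sel <- sel & es$kept
  es$data <- es$data[sel, , , drop = FALSE]
  es$conditions <- es$conditions[sel]
  es$kept <- es$kept[sel]
  es$reject_reason <- es$reject_reason[sel]
  es
}
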