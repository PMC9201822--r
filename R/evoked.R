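# unit-amplitude time course of one component on a ms grid
component_timecourse <- function(comp, t_ms) {
  if (comp$plateau > 0) {
    lo <- comp$latency
    hi <- comp$latency + comp$plateau
    out <- numeric(length(t_ms))
    out[t_ms < lo] <- exp(-(t_ms[t_ms < lo] - lo)^2 / (2 * comp$width^2))
    out[t_ms >= lo & t_ms <= hi] <- 1
    out[t_ms > hi] <- exp(-(t_ms[t_ms > hi] - hi)^2 / (2 * comp$fall_width^2))
    out
  } else {
    exp(-(t_ms - comp$latency)^2 / (2 * comp$width^2))
  }
}

component_weights <- function(comp, channels) {
  if (!is.null(comp$topography)) {
    w <- stats::setNames(numeric(length(channels)), channels)
    hit <- intersect(channels, names(comp$topography))
    w[hit] <- comp$topography[hit]
    w
  } else {
    topography_weights(comp$focal, comp$sigma)[channels]
  }
}

#' Evoked scalp waveform for one condition preset
#'
#' Superposes the preset's component templates across channels. At a
#' component's focal channel and peak latency the value equals
#' `amplitude_scale * amplitude` when no other component overlaps; channels
#' with topography weight 0 receive exactly zero contribution; the control
#' preset yields an all-zero array.
#'
#' @param preset a [condition_preset()].
#' @param profile a [subject_profile()] (its `amplitude_scale` and
#'   `latency_shift` are applied; per-trial jitter is added via `jitter_ms`).
#' @param time_grid time points in seconds relative to stimulus onset; must
#'   cover each (shifted) component latency.
#' @param channels channel labels (default: full montage).
#' @param jitter_ms additional latency shift in ms (per-trial jitter).
#' @return numeric matrix, channels x samples, with `dimnames` set.
#' @export
evoked_waveform <- function(preset, profile = subject_profile(),
                            time_grid, channels = default_montage()$channel,
                            jitter_ms = 0) {
  stopifnot(inherits(preset, "condition_preset"),
            inherits(profile, "subject_profile"))
  t_ms <- time_grid * 1000
  out <- matrix(0, nrow = length(channels), ncol = length(time_grid),
                dimnames = list(channels, NULL))
  for (comp in preset$components) {
    lat <- comp$latency + profile$latency_shift + jitter_ms
    if (lat < min(t_ms) || lat > max(t_ms))
      stop(sprintf("component %s latency %.1f ms falls outside the time grid [%.1f, %.1f] ms",
                   comp$name, lat, min(t_ms), max(t_ms)), call. = FALSE)
    shifted <- comp
    shifted$latency <- lat
    tc <- component_timecourse(shifted, t_ms) *
      comp$amplitude * profile$amplitude_scale
    w <- component_weights(comp, channels)
    out <- out + outer(unname(w), tc)
  }
  out
}
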