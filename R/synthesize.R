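#' Background-noise configuration for the session synthesizer
#'
#' Parameterizes the additive background model: 1/f ("pink") broadband
#' activity, occipital alpha rhythm, 50/100 Hz line components, slow drift,
#' and stereotyped blink transients dominant at Fp1/Fp2. All amplitudes are
#' stated at the reference broadband level (`reference_level`); a subject's
#' `noise_level` rescales every background component proportionally, so a
#' `noise_level` of 0 yields a noise-free recording.
#'
#' @param pink_exponent spectral exponent of the broadband background
#'   (power ~ 1/f^exponent, default 1).
#' @param alpha_freq alpha-rhythm centre frequency in Hz.
#' @param alpha_bw alpha bandwidth (Gaussian SD, Hz).
#' @param alpha_rms alpha RMS in a.u. at the occipital focus.
#' @param alpha_sigma spatial falloff of the alpha topography.
#' @param line_freqs mains frequencies in Hz.
#' @param line_amps sinusoid amplitudes (a.u.) at the listed frequencies.
#' @param drift_rms RMS of the sub-0.2 Hz drift component (a.u.).
#' @param blink_amplitude blink-template peak (a.u.) at the frontal focus.
#' @param blink_width blink-template temporal spread (Gaussian SD, ms).
#' @param blink_sigma spatial falloff of the blink topography around Fp1/Fp2.
#' @param trial_amp_sd SD of the per-trial multiplicative evoked-amplitude
#'   factor (mean 1).
#' @param reference_level broadband RMS at which the other amplitudes are
#'   stated.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(pink_exponent = 1, alpha_freq = 10, alpha_bw = 1,
                         alpha_rms = 4, alpha_sigma = 0.6,
                         line_freqs = c(50, 100), line_amps = c(5, 2),
                         drift_rms = 20, blink_amplitude = 80,
                         blink_width = 60, blink_sigma = 0.4,
                         trial_amp_sd = 0.1, reference_level = 12) {
  structure(as.list(environment()), class = "noise_config")
}

# smallest 2-3-5-smooth FFT length >= n
good_fft_length <- function(n) stats::nextn(n, c(2L, 3L, 5L))

# one realization of zero-mean noise as a sum of spectrally shaped
# components; each entry of `components` is list(var = target variance,
# fun = relative power profile over f in Hz). Each shape is normalized on
# the discrete grid so the component contributes its target variance in
# expectation.
shaped_noise <- function(n, fs, components) {
  n2 <- good_fft_length(n)
  f <- c(seq(0, floor(n2 / 2)), seq(ceiling(n2 / 2) - 1, 1)) * fs / n2
  p <- numeric(n2)
  for (comp in components) {
    if (comp$var <= 0) next
    shape <- comp$fun(f)
    p <- p + comp$var * shape / mean(shape)
  }
  x <- stats::rnorm(n2)
  sx <- stats::fft(x) * sqrt(p)
  out <- Re(stats::fft(sx, inverse = TRUE)) / n2
  out[seq_len(n)]
}

# blink template: positive Gaussian transient, unit peak
blink_template <- function(width_ms, fs) {
  half <- ms_to_samples(4 * width_ms, fs)
  t_ms <- (seq(-half, half)) / fs * 1000
  exp(-t_ms^2 / (2 * width_ms^2))
}

#' Synthesize a continuous multichannel recording
#'
#' Inserts the per-condition evoked templates at the scheduled stimulus
#' onsets (with per-trial latency jitter and amplitude variability from the
#' subject profile and noise configuration) on top of the additive background
#' model. A fixed seed makes the output fully reproducible.
#'
#' @param schedule an `oddball_schedule` from [build_schedule()].
#' @param presets named list mapping each condition in the schedule to a
#'   [condition_preset()]; by default the packaged presets for `modality`.
#' @param profile a [subject_profile()].
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @param modality used only when `presets` is NULL.
#' @return object of class `continuous_recording`: list with `channel_names`,
#'   `sampling_rate`, `data` (channels x samples), `events` (data.frame
#'   `onset_sample`, `onset_s`, `condition`) and `montage`.
#' @export
synthesize_recording <- function(schedule, presets = NULL,
                                 profile = subject_profile(),
                                 noise = noise_config(), seed,
                                 modality = c("visual_only", "audio_visual")) {
  stopifnot(inherits(schedule, "oddball_schedule"))
  modality <- match.arg(modality)
  cfg <- attr(schedule, "config")
  fs <- cfg$sampling_rate
  if (is.null(presets)) {
    presets <- lapply(stats::setNames(nm = unique(schedule$condition)),
                      condition_presets, modality = modality)
  }
  missing_p <- setdiff(unique(schedule$condition), names(presets))
  if (length(missing_p))
    stop("no preset for condition(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  montage <- default_montage()
  ch <- montage$channel
  n_ch <- length(ch)
  dur <- max(schedule$onset_s) + cfg$trial_duration + 2
  n <- as.integer(ceiling(dur * fs))
  if (max(schedule$onset_sample) + ceiling(1.2 * fs) > n)
    stop("schedule does not fit the recording duration", call. = FALSE)

  scale <- profile$noise_level / noise$reference_level
  sds <- derive_seeds(seed, 4)
  data <- matrix(0, n_ch, n, dimnames = list(ch, NULL))

  if (scale > 0) {
    # broadband + alpha + drift in one spectral-shaping pass per channel
    alpha_w <- pmax(topography_weights("O1", noise$alpha_sigma)[ch],
                    topography_weights("O2", noise$alpha_sigma)[ch])
    pink_rms <- profile$noise_level
    expn <- noise$pink_exponent
    a0 <- noise$alpha_freq; abw <- noise$alpha_bw
    with_seed(sds[1], {
      for (i in seq_len(n_ch)) {
        comps <- list(
          list(var = pink_rms^2,
               fun = function(f) 1 / pmax(f, 0.5)^expn),
          list(var = (noise$alpha_rms * scale * alpha_w[i])^2,
               fun = function(f) exp(-(f - a0)^2 / (2 * abw^2))),
          list(var = (noise$drift_rms * scale)^2,
               fun = function(f) exp(-(f / 0.15)^2)))
        data[i, ] <- shaped_noise(n, fs, comps)
      }
    })
    # line noise: common phase per frequency, slight per-channel amplitude spread
    with_seed(sds[2], {
      tt <- seq_len(n) / fs
      for (k in seq_along(noise$line_freqs)) {
        ph <- stats::runif(1, 0, 2 * pi)
        gains <- stats::runif(n_ch, 0.8, 1.2)
        s <- sin(2 * pi * noise$line_freqs[k] * tt + ph)
        data <- data + (noise$line_amps[k] * scale) * outer(gains, s)
      }
    })
    # blinks: Poisson train at the profile's blink rate, frontal topography
    if (profile$blink_rate > 0 && noise$blink_amplitude > 0) {
      with_seed(sds[3], {
        n_blinks <- stats::rpois(1, profile$blink_rate * (n / fs) / 60)
        if (n_blinks > 0) {
          tmpl <- blink_template(noise$blink_width, fs)
          half <- (length(tmpl) - 1) / 2
          centers <- sort(sample.int(n, n_blinks))
          bw <- pmax(topography_weights("Fp1", noise$blink_sigma)[ch],
                     topography_weights("Fp2", noise$blink_sigma)[ch])
          amps <- noise$blink_amplitude * scale * stats::runif(n_blinks, 0.7, 1.3)
          for (b in seq_len(n_blinks)) {
            idx <- (centers[b] - half):(centers[b] + half)
            keep <- idx >= 1 & idx <= n
            data[, idx[keep]] <- data[, idx[keep]] +
              outer(bw * amps[b], tmpl[keep])
          }
        }
      })
    }
  }

  # evoked responses at the scheduled onsets
  ev_grid <- seq(0, 1.2, by = 1 / fs)
  n_ev <- length(ev_grid)
  with_seed(sds[4], {
    for (j in seq_len(nrow(schedule))) {
      preset <- presets[[schedule$condition[j]]]
      if (length(preset$components) == 0) next
      jit <- if (profile$latency_jitter_sd > 0)
        stats::rnorm(1, 0, profile$latency_jitter_sd) else 0
      amp_f <- if (noise$trial_amp_sd > 0 && scale > 0)
        max(0, stats::rnorm(1, 1, noise$trial_amp_sd)) else 1
      wav <- evoked_waveform(preset, profile, ev_grid, ch, jitter_ms = jit) * amp_f
      i0 <- schedule$onset_sample[j]
      idx <- i0:(i0 + n_ev - 1)
      keep <- idx <= n
      data[, idx[keep]] <- data[, idx[keep]] + wav[, keep, drop = FALSE]
    }
  })

  structure(list(
    channel_names = ch,
    sampling_rate = fs,
    data = data,
    events = data.frame(onset_sample = schedule$onset_sample,
                        onset_s = schedule$onset_s,
                        condition = schedule$condition,
                        stringsAsFactors = FALSE),
    montage = montage,
    subject_id = profile$subject_id
  ), class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Simulate one full session for one subject
#'
#' Convenience wrapper: builds the schedule and synthesizes the recording
#' with seeds fanned out from one master seed.
#'
#' @inheritParams synthesize_recording
#' @param cfg a [session_config()].
#' @return a `continuous_recording`.
#' @export
simulate_session <- function(cfg = session_config(),
                             modality = c("visual_only", "audio_visual"),
                             profile = subject_profile(),
                             noise = noise_config(), seed) {
  modality <- match.arg(modality)
  sds <- derive_seeds(seed, 2)
  sched <- build_schedule(cfg, sds[1])
  synthesize_recording(sched, profile = profile, noise = noise,
                       seed = sds[2], modality = modality)
}
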