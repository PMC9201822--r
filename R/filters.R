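#' Filter specification for the preprocessing front end
#'
#' Notch filters at the mains frequency and its second harmonic plus a
#' band-pass, all realized as linear-phase (symmetric) windowed FIR filters
#' applied with group-delay compensation, i.e. zero phase: peak latencies are
#' not shifted. Orders are stated in taps at 250 Hz; the Hamming design gives
#' > 50 dB stop-band attenuation and < 1% pass-band ripple.
#'
#' @param notch_freqs notch centre frequencies in Hz.
#' @param notch_halfwidth half-width of each stop band in Hz.
#' @param bp_low,bp_high band-pass edges in Hz.
#' @param bp_order band-pass FIR order (even).
#' @param notch_order notch FIR order (even).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(notch_freqs = c(50, 100), notch_halfwidth = 2,
                        bp_low = 0.5, bp_high = 40,
                        bp_order = 1000, notch_order = 500) {
  stopifnot(bp_low > 0, bp_low < bp_high,
            bp_order %% 2 == 0, notch_order %% 2 == 0)
  structure(list(notch_freqs = notch_freqs, notch_halfwidth = notch_halfwidth,
                 bp_low = bp_low, bp_high = bp_high,
                 bp_order = bp_order, notch_order = notch_order),
            class = "filter_spec")
}

# combined impulse response of notch cascade + band-pass at rate fs
design_filter_kernel <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$bp_high >= nyq || any(spec$notch_freqs >= nyq))
    stop("filter edges must lie below the Nyquist frequency", call. = FALSE)
  h <- signal::fir1(spec$bp_order, c(spec$bp_low, spec$bp_high) / nyq,
                    type = "pass")
  for (f0 in spec$notch_freqs) {
    hn <- signal::fir1(spec$notch_order,
                       c(f0 - spec$notch_halfwidth, f0 + spec$notch_halfwidth) / nyq,
                       type = "stop")
    h <- stats::convolve(h, rev(hn), type = "open")
  }
  as.numeric(h)
}

# zero-phase FIR filtering of each row by FFT convolution, compensating the
# (integer) group delay of the symmetric kernel
fft_filter_rows <- function(x, h) {
  n <- ncol(x)
  d <- (length(h) - 1) / 2
  nfft <- good_fft_length(n + length(h) - 1)
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  out <- x
  for (i in seq_len(nrow(x))) {
    X <- stats::fft(c(x[i, ], numeric(nfft - n)))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
    out[i, ] <- y[(d + 1):(d + n)]
  }
  out
}

#' Apply the notch + band-pass front end to a recording
#'
#' @param rec a `continuous_recording`.
#' @param spec a [filter_spec()].
#' @return the filtered `continuous_recording`.
#' @export
apply_filters <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "continuous_recording"), inherits(spec, "filter_spec"))
  h <- design_filter_kernel(spec, rec$sampling_rate)
  if (ncol(rec$data) <= length(h))
    stop(sprintf("recording (%d samples) is shorter than the filter kernel (%d taps)",
                 ncol(rec$data), length(h)), call. = FALSE)
  rec$data <- fft_filter_rows(rec$data, h)
  rec
}

#' Drop channels from a recording
#'
#' Used for the bad-channel exclusion step; the shipped profile excludes O1
#' and PO7.
#'
#' @param rec a `continuous_recording`.
#' @param channels labels to drop.
#' @return the reduced recording.
#' @export
exclude_channels <- function(rec, channels = c("O1", "PO7")) {
  keep <- !rec$channel_names %in% channels
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$channel_names <- rec$channel_names[keep]
  rec
}
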