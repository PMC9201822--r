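#' Feature-extraction configuration
#'
#' Defines the channels, analysis window and per-method parameters for
#' single-trial feature extraction on the 0-660 ms post-onset window.
#'
#' Two shipped profiles differ only in dimensional conventions:
#' * `"paper-dims"` pins the Welch FFT grid (segment 82, overlap 41, nfft
#'   210) so exactly 25 bins fall in 1-30 Hz, and truncates the level-3
#'   approximation from 33 to its central 31 coefficients, reproducing the
#'   published 44/275/341/660 feature dimensionalities.
#' * `"natural"` uses a single full-window Welch segment (nfft 256) and the
#'   untruncated 33 approximation coefficients.
#'
#' @param profile `"paper-dims"` (default) or `"natural"`.
#' @param channels ordered channel list (default [feature_channels()]).
#' @param window analysis window in seconds post-onset.
#' @param var_windows list of variance windows in ms.
#' @param psd_band retained frequency band in Hz.
#' @param psd_seg,psd_overlap,psd_nfft Welch segmentation (samples).
#' @param dwt_level decomposition depth.
#' @param dwt_keep number of approximation coefficients kept (`NA` = all).
#' @return object of class `feature_config`.
#' @export
feature_config <- function(profile = c("paper-dims", "natural"),
                           channels = feature_channels(),
                           window = c(0, 0.66),
                           var_windows = list(c(0, 660), c(0, 220),
                                              c(220, 440), c(440, 660)),
                           psd_band = c(1, 30),
                           psd_seg = NULL, psd_overlap = NULL, psd_nfft = NULL,
                           dwt_level = 3, dwt_keep = NULL) {
  profile <- match.arg(profile)
  if (anyDuplicated(channels)) stop("channels must be unique", call. = FALSE)
  if (profile == "paper-dims") {
    psd_seg <- psd_seg %||% 82L
    psd_overlap <- psd_overlap %||% 41L
    psd_nfft <- psd_nfft %||% 210L
    dwt_keep <- dwt_keep %||% 31L
  } else {
    psd_seg <- psd_seg %||% 165L
    psd_overlap <- psd_overlap %||% 0L
    psd_nfft <- psd_nfft %||% 256L
    dwt_keep <- dwt_keep %||% NA_integer_
  }
  structure(list(profile = profile, channels = channels, window = window,
                 var_windows = var_windows, psd_band = psd_band,
                 psd_seg = psd_seg, psd_overlap = psd_overlap,
                 psd_nfft = psd_nfft, dwt_level = dwt_level,
                 dwt_keep = dwt_keep),
            class = "feature_config")
}

# trials x channels x samples sub-array over cfg window/channels
feature_window_data <- function(es, cfg) {
  stopifnot(inherits(es, "epoch_set"), inherits(cfg, "feature_config"))
  missing_ch <- setdiff(cfg$channels, es$channels)
  if (length(missing_ch))
    stop("epoch set is missing feature channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  t_s <- epoch_times(es)
  sel <- which(t_s >= cfg$window[1] - 1e-9 & t_s < cfg$window[2] - 1e-9)
  if (!length(sel)) stop("analysis window outside the epochs", call. = FALSE)
  es$data[, match(cfg$channels, es$channels), sel, drop = FALSE]
}

new_feature_matrix <- function(mat, names, labels, method) {
  colnames(mat) <- names
  structure(list(matrix = mat, feature_names = names, labels = labels,
                 method = method, normalization = "none"),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%s, normalization: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$method, x$normalization))
  invisible(x)
}

#' Windowed-variance features
#'
#' Per trial and channel, the sample variance in each configured window
#' (default: the full 0-660 ms window plus three successive 220 ms
#' segments), ordered channel-major / window-minor: 4 x 11 = 44 features in
#' the shipped profile.
#'
#' @param es an `epoch_set` covering 0-660 ms.
#' @param cfg a [feature_config()].
#' @return a `feature_matrix`.
#' @export
var_features <- function(es, cfg = feature_config()) {
  x <- feature_window_data(es, cfg)
  fs <- es$sampling_rate
  n_tr <- dim(x)[1]; n_ch <- dim(x)[2]; n_s <- dim(x)[3]
  t_ms <- (seq_len(n_s) - 1) / fs * 1000
  win_idx <- lapply(cfg$var_windows, function(w)
    which(t_ms >= w[1] - 1e-9 & t_ms < w[2] - 1e-9))
  n_w <- length(win_idx)
  mat <- matrix(0, n_tr, n_ch * n_w)
  names_ <- character(n_ch * n_w)
  col <- 0
  for (ci in seq_len(n_ch)) {
    for (wi in seq_len(n_w)) {
      col <- col + 1
      seg <- x[, ci, win_idx[[wi]], drop = FALSE]
      mat[, col] <- apply(array(seg, dim = dim(seg)[c(1, 3)]), 1, stats::var)
      names_[col] <- sprintf("var.%s.w%d_%g-%gms", cfg$channels[ci], wi,
                             cfg$var_windows[[wi]][1], cfg$var_windows[[wi]][2])
    }
  }
  new_feature_matrix(mat, names_, es$conditions, "VAR")
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram (Hamming window, 50%-style overlap set by
#' `overlap`) with one-sided density scaling, so that the sum of the
#' estimate times the bin width approximates the signal variance.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param seg segment length in samples.
#' @param overlap overlap in samples.
#' @param nfft FFT length (zero-padded if > `seg`).
#' @return list with `freq` (Hz) and `power` (a.u.^2 / Hz).
#' @export
welch_psd <- function(x, fs, seg = length(x), overlap = 0, nfft = seg) {
  n <- length(x)
  if (seg > n) stop("signal shorter than one Welch segment", call. = FALSE)
  step <- seg - overlap
  starts <- seq(1, n - seg + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, seg - 1) / (seg - 1))
  u <- sum(w^2)
  acc <- numeric(nfft)
  for (s0 in starts) {
    segx <- x[s0:(s0 + seg - 1)]
    segx <- (segx - mean(segx)) * w
    X <- stats::fft(c(segx, numeric(nfft - seg)))
    acc <- acc + Mod(X)^2
  }
  p <- acc / (length(starts) * u * fs)
  half <- floor(nfft / 2) + 1
  p1 <- p[seq_len(half)]
  p1[2:(half - 1)] <- 2 * p1[2:(half - 1)]
  list(freq = (seq_len(half) - 1) * fs / nfft, power = p1)
}

#' Band-limited Welch PSD features
#'
#' Welch periodogram per channel on the analysis window, keeping bins with
#' `psd_band[1] <= f <= psd_band[2]` (1-30 Hz: 25 bins per channel under the
#' paper-dims grid, 275 features over the 11 channels).
#'
#' @inheritParams var_features
#' @return a `feature_matrix`.
#' @export
psd_features <- function(es, cfg = feature_config()) {
  x <- feature_window_data(es, cfg)
  fs <- es$sampling_rate
  probe <- welch_psd(x[1, 1, ], fs, cfg$psd_seg, cfg$psd_overlap, cfg$psd_nfft)
  keep <- which(probe$freq >= cfg$psd_band[1] - 1e-9 &
                probe$freq <= cfg$psd_band[2] + 1e-9)
  if (!length(keep))
    stop("no frequency bins inside the configured band", call. = FALSE)
  n_tr <- dim(x)[1]; n_ch <- dim(x)[2]
  mat <- matrix(0, n_tr, n_ch * length(keep))
  names_ <- character(ncol(mat))
  col0 <- 0
  for (ci in seq_len(n_ch)) {
    for (ti in seq_len(n_tr)) {
      pw <- welch_psd(x[ti, ci, ], fs, cfg$psd_seg, cfg$psd_overlap, cfg$psd_nfft)
      mat[ti, col0 + seq_along(keep)] <- pw$power[keep]
    }
    names_[col0 + seq_along(keep)] <-
      sprintf("psd.%s.%.3fHz", cfg$channels[ci], probe$freq[keep])
    col0 <- col0 + length(keep)
  }
  new_feature_matrix(mat, names_, es$conditions, "PSD")
}

#' DWT approximation-coefficient features
#'
#' Level-`dwt_level` db8 approximation coefficients per channel (symmetric
#' boundary extension: 33 coefficients for the 165-sample window; the
#' paper-dims profile keeps the central 31).
#'
#' @inheritParams var_features
#' @return a `feature_matrix`; the attribute `coef_info` documents the mode,
#'   the full coefficient length and any truncation.
#' @export
dwt_features <- function(es, cfg = feature_config()) {
  x <- feature_window_data(es, cfg)
  n_tr <- dim(x)[1]; n_ch <- dim(x)[2]; n_s <- dim(x)[3]
  full_len <- dwt_approx_length(n_s, cfg$dwt_level)
  keep <- if (is.na(cfg$dwt_keep)) seq_len(full_len) else {
    if (cfg$dwt_keep > full_len)
      stop("dwt_keep exceeds the available coefficient count", call. = FALSE)
    drop0 <- (full_len - cfg$dwt_keep) %/% 2
    drop0 + seq_len(cfg$dwt_keep)
  }
  mat <- matrix(0, n_tr, n_ch * length(keep))
  names_ <- character(ncol(mat))
  col0 <- 0
  for (ci in seq_len(n_ch)) {
    for (ti in seq_len(n_tr)) {
      dec <- dwt_decompose(x[ti, ci, ], cfg$dwt_level)
      mat[ti, col0 + seq_along(keep)] <- dec$approx[keep]
    }
    names_[col0 + seq_along(keep)] <-
      sprintf("dwt.%s.a%d_c%d", cfg$channels[ci], cfg$dwt_level, keep)
    col0 <- col0 + length(keep)
  }
  fm <- new_feature_matrix(mat, names_, es$conditions, "DWT")
  fm$coef_info <- list(mode = "symmetric", full_length = full_len,
                       kept = length(keep), level = cfg$dwt_level)
  fm
}

#' Fit / apply the [-1, 1] min-max normalizer
#'
#' `fit_normalizer()` learns per-feature affine maps sending the training
#' minimum to -1 and maximum to +1 (constant features map to 0, with a
#' warning). `apply_normalizer()` applies the learned bounds unchanged, so
#' test-set values may land outside [-1, 1].
#'
#' @param fm a `feature_matrix` (training data).
#' @return `fit_normalizer()`: object of class `feature_normalizer`.
#' @export
fit_normalizer <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"), nrow(fm$matrix) > 0)
  lo <- apply(fm$matrix, 2, min)
  hi <- apply(fm$matrix, 2, max)
  flat <- hi - lo <= 0
  if (any(flat))
    warning(sprintf("%d constant feature(s) mapped to 0", sum(flat)))
  structure(list(min = lo, max = hi, flat = flat,
                 feature_names = fm$feature_names),
            class = "feature_normalizer")
}

#' @rdname fit_normalizer
#' @param norm a `feature_normalizer`.
#' @export
apply_normalizer <- function(norm, fm) {
  stopifnot(inherits(norm, "feature_normalizer"),
            inherits(fm, "feature_matrix"))
  if (!identical(norm$feature_names, fm$feature_names))
    stop("normalizer was fitted on different features", call. = FALSE)
  rng <- norm$max - norm$min
  rng[norm$flat] <- 1
  out <- sweep(sweep(fm$matrix, 2, (norm$min + norm$max) / 2), 2, rng / 2, "/")
  out[, norm$flat] <- 0
  fm$matrix <- out
  fm$normalization <- "fitted[-1,1]"
  fm
}

#' Concatenate feature matrices (feature fusion)
#'
#' Column-binds matrices over the same trials in the given order (the DVP
#' fusion is VAR, PSD, DWT: 44 + 275 + 341 = 660 columns under the
#' paper-dims profile).
#'
#' @param fms list of `feature_matrix` objects with equal row counts and
#'   labels.
#' @return the fused `feature_matrix`.
#' @export
fuse_features <- function(fms) {
  stopifnot(length(fms) >= 1, all(vapply(fms, inherits, TRUE, "feature_matrix")))
  n <- unique(vapply(fms, function(f) nrow(f$matrix), 0L))
  if (length(n) != 1)
    stop("feature matrices have mismatched trial counts", call. = FALSE)
  for (f in fms[-1])
    if (!identical(f$labels, fms[[1]]$labels))
      stop("feature matrices have mismatched labels", call. = FALSE)
  out <- new_feature_matrix(
    do.call(cbind, lapply(fms, `[[`, "matrix")),
    unlist(lapply(fms, `[[`, "feature_names")),
    fms[[1]]$labels,
    paste(vapply(fms, `[[`, "", "method"), collapse = "+"))
  out
}
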