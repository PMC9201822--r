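#' Default component search windows (ms post-onset)
#'
#' Windows for extremum search on averages: P1 50-180 ms, N2c 200-400 ms,
#' P3b 400-660 ms.
#' @return named list of length-2 numeric vectors.
#' @export
peak_windows <- function() {
  list(P1 = c(50, 180), N2c = c(200, 400), P3b = c(400, 660))
}

#' Measure a component peak on an average
#'
#' Finds the extremum of the requested polarity inside a latency window on
#' one channel of a subject or grand average. Ties are broken toward the
#' earliest latency; the latency is reported at the extremum sample (no
#' sub-sample interpolation unless `interpolate = TRUE`, which fits a
#' parabola through the extremum and its neighbours).
#'
#' @param avg an `erp_average` or `grand_average`.
#' @param channel channel label (typically "O2").
#' @param window length-2 numeric, search window in ms post-onset.
#' @param polarity `"positive"` (maximum) or `"negative"` (minimum).
#' @param interpolate logical, parabolic sub-sample refinement (default
#'   FALSE).
#' @return object of class `peak_measure`: list with `component` fields
#'   `amplitude`, `latency_ms`, `channel`, `window`, `polarity`.
#' @export
peak_measure <- function(avg, channel = "O2", window = c(50, 180),
                         polarity = c("positive", "negative"),
                         interpolate = FALSE) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(avg, c("erp_average", "grand_average")))
  ci <- match(channel, avg$channels)
  if (is.na(ci)) stop(sprintf("channel '%s' not present", channel), call. = FALSE)
  t_ms <- (avg$window[1] + (seq_len(ncol(avg$mean)) - 1) / avg$sampling_rate) * 1000
  if (window[1] < min(t_ms) || window[2] > max(t_ms))
    stop("search window outside the epoch", call. = FALSE)
  sel <- which(t_ms >= window[1] & t_ms <= window[2])
  y <- avg$mean[ci, sel]
  i <- if (polarity == "positive") which.max(y) else which.min(y)  # earliest tie wins
  amp <- y[i]
  lat <- t_ms[sel[i]]
  if (interpolate && i > 1 && i < length(y)) {
    a <- y[i - 1]; b <- y[i]; c <- y[i + 1]
    den <- a - 2 * b + c
    if (abs(den) > 0) {
      delta <- 0.5 * (a - c) / den
      lat <- lat + delta * 1000 / avg$sampling_rate
      amp <- b - 0.25 * (a - c) * delta
    }
  }
  structure(list(amplitude = unname(amp), latency_ms = unname(lat),
                 channel = channel, window = window, polarity = polarity),
            class = "peak_measure")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value. Degenerate inputs are defined rather than
#' rejected: two zero-variance samples with equal means give `t = 0, p = 1`;
#' with different means the result is flagged `degenerate` (infinite t,
#' p = 0).
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return object of class `welch_test`: `t`, `df`, `p`, group means, SDs and
#'   sizes, and a `degenerate` flag.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      t <- 0; df <- na + nb - 2; p <- 1
    } else {
      t <- sign(ma - mb) * Inf; df <- na + nb - 2; p <- 0; degenerate <- TRUE
    }
  } else {
    se2 <- va / na + vb / nb
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p,
                 mean_a = ma, mean_b = mb, sd_a = sqrt(va), sd_b = sqrt(vb),
                 n_a = na, n_b = nb, degenerate = degenerate),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.2f, p = %.4g (means %.4g vs %.4g)\n",
              x$t, x$df, x$p, x$mean_a, x$mean_b))
  invisible(x)
}

#' Scalp amplitude snapshot at fixed latencies
#'
#' Nearest-sample per-channel amplitudes of a grand average at the requested
#' latencies (120/320/540 ms by default, bracketing P1, N2c and P3b).
#'
#' @param ga a `grand_average` (or `erp_average`).
#' @param times_ms latencies in ms post-onset.
#' @return numeric matrix channels x times, dimnames set to labels and
#'   latencies.
#' @export
scalp_snapshot <- function(ga, times_ms = c(120, 320, 540)) {
  stopifnot(inherits(ga, c("erp_average", "grand_average")))
  t_ms <- (ga$window[1] + (seq_len(ncol(ga$mean)) - 1) / ga$sampling_rate) * 1000
  if (any(times_ms < min(t_ms) | times_ms > max(t_ms)))
    stop("requested snapshot time outside the epoch window", call. = FALSE)
  idx <- vapply(times_ms, function(tm) which.min(abs(t_ms - tm)), 0L)
  out <- ga$mean[, idx, drop = FALSE]
  dimnames(out) <- list(ga$channels, sprintf("%g ms", times_ms))
  out
}

#' Peak table for a set of averages
#'
#' Convenience wrapper measuring P1 (positive), N2c (negative) and P3b
#' (positive) at one channel on each average in a list, using the default
#' search windows.
#'
#' @param avgs list of averages (subject or grand).
#' @param channel channel label.
#' @return data.frame with one row per average x component.
#' @export
peak_table <- function(avgs, channel = "O2") {
  wins <- peak_windows()
  pol <- c(P1 = "positive", N2c = "negative", P3b = "positive")
  do.call(rbind, lapply(seq_along(avgs), function(i) {
    do.call(rbind, lapply(names(wins), function(comp) {
      pm <- peak_measure(avgs[[i]], channel, wins[[comp]], pol[[comp]])
      data.frame(average = i, component = comp, channel = channel,
                 amplitude = pm$amplitude, latency_ms = pm$latency_ms,
                 stringsAsFactors = FALSE)
    }))
  }))
}
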