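# Daubechies-8 discrete wavelet transform (16-tap filter bank) with
# half-point symmetric boundary extension and decimation by 2, plus the
# inverse transform. The analysis convention matches the common
# symmetric-padding DWT: level output length is floor((n + 15) / 2).

# orthonormal db8 scaling (low-pass) filter taps
DB8_LO <- c(-0.00011747678412476953, 0.0006754494064505693,
            -0.00039174037337694705, -0.004870352993451574,
             0.008746094047405777,    0.013981027917398282,
            -0.044088253930794755,   -0.017369301001807547,
             0.12874742662047847,     0.0004724845739132828,
            -0.2840155429615469,     -0.015829105256349306,
             0.5853546836542067,      0.6756307362972898,
             0.31287159091429995,     0.05441584224310401)
# quadrature mirror high-pass
DB8_HI <- rev(DB8_LO) * rep(c(-1, 1), 8)

# half-point symmetric extension indices for positions (1-p)..(n+p)
symmetric_ext <- function(x, p) {
  n <- length(x)
  pattern <- c(seq_len(n), rev(seq_len(n)))
  j <- (1 - p):(n + p)
  m <- ((j - 1) %% (2 * n) + 2 * n) %% (2 * n) + 1
  x[pattern[m]]
}

# single-level analysis: list(a, d), each of length floor((n + L - 1) / 2)
dwt_step <- function(x, lo = DB8_LO, hi = DB8_HI) {
  n <- length(x)
  L <- length(lo)
  ext <- symmetric_ext(x, L - 1)
  conv_dec <- function(h) {
    z <- stats::convolve(ext, rev(h), type = "open")
    # z[k] = sum_j ext[j] h[k - j + 1]; keep every second sample of the
    # valid part so that output length is floor((n + L - 1) / 2)
    valid <- z[L:(L + n + L - 2)]
    valid[seq(2, length(valid), by = 2)][seq_len((n + L - 1) %/% 2)]
  }
  list(a = conv_dec(lo), d = conv_dec(hi))
}

# single-level synthesis back to length n
idwt_step <- function(a, d, n, lo = DB8_LO, hi = DB8_HI) {
  L <- length(lo)
  up <- function(c_) {
    u <- numeric(2 * length(c_))
    u[seq(1, length(u), by = 2)] <- c_
    u
  }
  # stats::convolve(x, y, "open") correlates x with rev(y), so passing the
  # analysis filters directly applies the time-reversed synthesis filters
  rec <- stats::convolve(up(a), lo, type = "open") +
         stats::convolve(up(d), hi, type = "open")
  rec[(L - 2) + seq_len(n)]
}

#' Multi-level db8 wavelet decomposition
#'
#' Decomposes a signal with the Daubechies-8 filter bank under half-point
#' symmetric boundary extension. Each level halves the length as
#' `len <- floor((len + 15) / 2)`; a 165-sample input yields approximation
#' lengths 90, 52 and 33 at levels 1-3.
#'
#' @param x numeric signal.
#' @param level decomposition depth.
#' @return object of class `dwt_decomposition`: list with `approx` (deepest
#'   approximation coefficients), `details` (list, level 1 first), `lengths`
#'   (input length at each level) and `level`.
#' @export
dwt_decompose <- function(x, level = 3) {
  stopifnot(level >= 1)
  lens <- integer(level)
  details <- vector("list", level)
  cur <- as.numeric(x)
  for (l in seq_len(level)) {
    if (length(cur) < length(DB8_LO))
      stop(sprintf("signal too short for a level-%d decomposition", level),
           call. = FALSE)
    lens[l] <- length(cur)
    s <- dwt_step(cur)
    details[[l]] <- s$d
    cur <- s$a
  }
  structure(list(approx = cur, details = details, lengths = lens,
                 level = level), class = "dwt_decomposition")
}

#' Reconstruct a signal from its db8 decomposition
#'
#' Inverse of [dwt_decompose()]; exact to numerical precision.
#'
#' @param dec a `dwt_decomposition`.
#' @return numeric signal of the original length.
#' @export
dwt_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "dwt_decomposition"))
  cur <- dec$approx
  for (l in rev(seq_len(dec$level)))
    cur <- idwt_step(cur, dec$details[[l]], dec$lengths[l])
  cur
}

# deepest-level approximation length for an input of length n
dwt_approx_length <- function(n, level = 3, filter_length = 16) {
  for (l in seq_len(level)) n <- (n + filter_length - 1) %/% 2
  n
}
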