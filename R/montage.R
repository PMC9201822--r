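#' 24-channel 10-20 montage
#'
#' Electrode labels and flattened 2-D scalp coordinates (unit head radius,
#' nose up) for the portable 24-channel cap the simulator emulates. The
#' montage covers mainly occipital and parietal sites, plus the frontal pair
#' Fp1/Fp2 used as ocular-artifact proxies. Coordinates are only used to
#' compute relative scalp distances for evoked-component topographies and the
#' spatial falloff of artifacts; no volume conduction is modelled.
#'
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
default_montage <- function() {
  data.frame(
    channel = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "C3", "Cz", "C4", "CP1", "CPz", "CP2",
                "P7", "P3", "Pz", "P4", "P8",
                "PO7", "PO3", "PO4", "PO8", "O1", "O2"),
    x = c(-0.31, 0.31, -0.81, -0.35, 0.00, 0.35, 0.81,
          -0.50, 0.00, 0.50, -0.20, 0.00, 0.20,
          -0.81, -0.35, 0.00, 0.35, 0.81,
          -0.59, -0.25, 0.25, 0.59, -0.31, 0.31),
    y = c(0.95, 0.95, 0.59, 0.50, 0.50, 0.50, 0.59,
          0.00, 0.00, 0.00, -0.25, -0.25, -0.25,
          -0.59, -0.50, -0.50, -0.50, -0.59,
          -0.73, -0.73, -0.73, -0.73, -0.95, -0.95),
    stringsAsFactors = FALSE
  )
}

#' Channels used for feature extraction
#'
#' The eleven parieto-occipital channels over which single-trial features are
#' computed.
#' @return character vector of channel labels.
#' @export
feature_channels <- function() {
  c("PO3", "PO4", "PO8", "O2", "Pz", "P3", "P4", "CPz", "CP1", "CP2", "Cz")
}

# Euclidean scalp distance between two labelled electrodes
scalp_distance <- function(a, b, montage = default_montage()) {
  ia <- match(a, montage$channel)
  ib <- match(b, montage$channel)
  if (anyNA(c(ia, ib))) stop("unknown channel label", call. = FALSE)
  sqrt((montage$x[ia] - montage$x[ib])^2 + (montage$y[ia] - montage$y[ib])^2)
}

#' Gaussian topography weights around a focal electrode
#'
#' Weight 1 at the focal channel, decaying as `exp(-d^2 / (2 sigma^2))` with
#' scalp distance `d`. This is the parametric stand-in for the posterior-focal
#' scalp distributions of the evoked components.
#'
#' @param focal focal channel label.
#' @param sigma spatial falloff (scalp-distance units, head radius = 1).
#' @param montage montage data.frame.
#' @return named numeric vector of weights in `[0, 1]`, one per channel.
#' @export
topography_weights <- function(focal, sigma = 0.5, montage = default_montage()) {
  assert_scalar_num(sigma, "sigma", lower = 1e-6)
  d <- sqrt((montage$x - montage$x[match(focal, montage$channel)])^2 +
            (montage$y - montage$y[match(focal, montage$channel)])^2)
  if (anyNA(d)) stop(sprintf("focal channel '%s' not in montage", focal), call. = FALSE)
  w <- exp(-d^2 / (2 * sigma^2))
  names(w) <- montage$channel
  w
}
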