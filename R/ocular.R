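# Ocular-artifact removal. Fp1/Fp2 serve as the ocular proxies; both an
# ICA-based method (infomax, components correlated with the proxy removed)
# and direct least-squares regression of the proxy out of every channel are
# provided. The regression method is the shipped pipeline default because it
# is exactly deterministic and fast; ica_corr replaces the visual component
# inspection of classical pipelines with an automated correlation criterion.

# plain infomax ICA (natural gradient, logistic nonlinearity) on whitened
# data; x is components x samples. Returns unmixing/mixing in input space.
infomax_ica <- function(x, n_comp = nrow(x), max_iter = 200, lr = 0.01,
                        tol = 1e-6, seed = 1) {
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > 1e-12 * eg$values[1])[seq_len(min(n_comp, sum(eg$values > 1e-12 * eg$values[1])))]
  wh <- diag(1 / sqrt(eg$values[keep]), length(keep)) %*% t(eg$vectors[, keep, drop = FALSE])
  dewh <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(eg$values[keep]), length(keep))
  z <- wh %*% xc
  k <- nrow(z)
  w <- with_seed(seed, matrix(stats::rnorm(k * k, sd = 0.1), k, k) + diag(k))
  converged <- TRUE
  block <- min(n, 512L)
  prev_change <- Inf
  for (it in seq_len(max_iter)) {
    idx <- (((it - 1) * block) %% max(1, n - block)) + seq_len(block)
    u <- w %*% z[, idx, drop = FALSE]
    y <- 1 / (1 + exp(-u))
    dw <- lr * (diag(k) + (1 - 2 * y) %*% t(u) / length(idx)) %*% w
    w <- w + dw
    change <- sqrt(sum(dw^2)) / sqrt(sum(w^2))
    if (!is.finite(change)) { converged <- FALSE; break }
    if (change < tol) break
    # anneal when the update grows; keeps the natural-gradient step stable
    if (change > prev_change) lr <- lr * 0.9
    prev_change <- change
  }
  unmix <- w %*% wh                  # sources = unmix %*% (x - mu)
  mix <- dewh %*% solve(w)           # x ~ mix %*% sources + mu
  list(unmix = unmix, mix = mix, mean = mu, converged = converged,
       sources = unmix %*% xc)
}

remove_ocular_matrix <- function(x, channels, method = c("regression", "ica_corr"),
                                 threshold = 0.8, seed = 1) {
  method <- match.arg(method)
  fp <- match(c("Fp1", "Fp2"), channels)
  if (anyNA(fp))
    stop("ocular cleaning requires the Fp1 and Fp2 proxy channels", call. = FALSE)
  proxy <- colMeans(x[fp, , drop = FALSE])
  proxy_c <- proxy - mean(proxy)
  if (method == "ica_corr") {
    dec <- infomax_ica(x, seed = seed)
    if (!dec$converged) {
      warning("infomax ICA did not converge; falling back to regression")
      return(remove_ocular_matrix(x, channels, "regression", threshold, seed))
    }
    cors <- apply(dec$sources, 1, function(s)
      if (stats::sd(s) > 0) abs(stats::cor(s, proxy)) else 0)
    bad <- which(cors > threshold)
    keep_src <- dec$sources
    keep_src[bad, ] <- 0
    cleaned <- dec$mix %*% keep_src + dec$mean
    dimnames(cleaned) <- dimnames(x)
    list(data = cleaned,
         report = list(method = "ica_corr", removed_components = bad,
                       correlations = cors, threshold = threshold))
  } else {
    denom <- sum(proxy_c^2)
    if (denom <= 0)
      return(list(data = x, report = list(method = "regression",
                                          coefficients = numeric(nrow(x)))))
    beta <- as.numeric((x %*% proxy_c) / denom)
    cleaned <- x - outer(beta, proxy_c)
    dimnames(cleaned) <- dimnames(x)
    list(data = cleaned,
         report = list(method = "regression", coefficients = beta))
  }
}

#' Remove ocular artifacts from a recording or epoch set
#'
#' `regression` projects the centred Fp1/Fp2 mean out of every channel by
#' least squares. `ica_corr` decomposes the data with infomax ICA, removes
#' components whose absolute correlation with the ocular proxy exceeds
#' `threshold`, and reconstructs; if ICA fails to converge it falls back to
#' regression with a warning. Both are deterministic given `seed`.
#'
#' @param x a `continuous_recording` or `epoch_set`.
#' @param method `"regression"` (default) or `"ica_corr"`.
#' @param threshold proxy-correlation threshold for component removal.
#' @param seed seed for the ICA initialization.
#' @return object of the same class as `x`, with an added
#'   `ocular_report` field.
#' @export
remove_ocular_artifacts <- function(x, method = c("regression", "ica_corr"),
                                    threshold = 0.8, seed = 1) {
  method <- match.arg(method)
  if (inherits(x, "continuous_recording")) {
    res <- remove_ocular_matrix(x$data, x$channel_names, method, threshold, seed)
    x$data <- res$data
    x$ocular_report <- res$report
    x
  } else if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    flat <- matrix(aperm(x$data, c(2, 3, 1)), nrow = d[2])  # ch x (samp*trial)
    res <- remove_ocular_matrix(flat, x$channels, method, threshold, seed)
    x$data <- aperm(array(res$data, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
    dimnames(x$data) <- list(NULL, x$channels, NULL)
    x$ocular_report <- res$report
    x
  } else stop("x must be a continuous_recording or epoch_set", call. = FALSE)
}
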