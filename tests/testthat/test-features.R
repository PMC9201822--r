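# epochs covering 0-660 ms only need the post-onset part; use the standard
# -0.5..1 s window so feature extraction slices it itself
feat_epochs <- function(n_trials, seed = 1, sd = 1, fill = NULL) {
  es <- noise_epochs(n_trials, seed = seed, sd = sd)
  if (!is.null(fill)) es$data[] <- fill
  es
}

test_that("the paper-dims profile yields the published feature dimensionalities", {
  es <- feat_epochs(3)
  cfg <- feature_config("paper-dims")
  v <- var_features(es, cfg)
  p <- psd_features(es, cfg)
  d <- dwt_features(es, cfg)
  expect_equal(ncol(v$matrix), 44L)     # 4 windows x 11 channels
  expect_equal(ncol(p$matrix), 275L)    # 25 bins x 11 channels
  expect_equal(ncol(d$matrix), 341L)    # 31 coefficients x 11 channels
  fused <- fuse_features(list(v, p, d))
  expect_equal(ncol(fused$matrix), 660L)
  expect_false(anyDuplicated(fused$feature_names) > 0)
  # natural profile reports the untruncated 33 coefficients
  d2 <- dwt_features(es, feature_config("natural"))
  expect_equal(ncol(d2$matrix), 33L * 11L)
  expect_equal(d2$coef_info$full_length, 33L)
})

test_that("constant epochs give all-zero variance features", {
  es <- feat_epochs(2, fill = 4)
  v <- var_features(es, feature_config())
  expect_true(all(v$matrix == 0))
})

test_that("variance features estimate unit variance on white noise", {
  es <- feat_epochs(1000, seed = 2)
  v <- var_features(es, feature_config())
  expect_true(all(abs(colMeans(v$matrix) - 1) < 0.1))
})

test_that("variance features are invariant to constant offsets", {
  es <- feat_epochs(5, seed = 3)
  v1 <- var_features(es, feature_config())
  es$data <- es$data + 11
  v2 <- var_features(es, feature_config())
  expect_equal(v1$matrix, v2$matrix, tolerance = 1e-9)
})

test_that("PSD features peak at the driving frequency and ignore DC", {
  es <- feat_epochs(2, fill = 0)
  tt <- (seq_len(dim(es$data)[3]) - 1) / 250 - 0.5
  for (ci in seq_len(dim(es$data)[2]))
    es$data[, ci, ] <- rep(sin(2 * pi * 10 * tt), each = 2)
  cfg <- feature_config("paper-dims")
  p <- psd_features(es, cfg)
  freqs <- as.numeric(sub("Hz$", "",
                          sub("^psd\\.[^.]+\\.", "", p$feature_names)))
  for (ch in feature_channels()) {
    cols <- grep(paste0("^psd\\.", ch, "\\."), p$feature_names)
    # argmax lands on one of the two bins bracketing 10 Hz
    expect_lt(abs(freqs[cols[which.max(p$matrix[1, cols])]] - 10),
              diff(freqs[cols][1:2]) + 1e-9)
  }
  # DC offsets do not change in-band features
  es2 <- es; es2$data <- es2$data + 5
  p2 <- psd_features(es2, cfg)
  expect_equal(p$matrix, p2$matrix, tolerance = 1e-9)
})

test_that("full-spectrum Welch estimates satisfy Parseval consistency", {
  set.seed(4)
  x <- rnorm(4096)
  pw <- welch_psd(x, fs = 250, seg = 256, overlap = 128, nfft = 256)
  df <- diff(pw$freq[1:2])
  expect_equal(sum(pw$power) * df, var(x), tolerance = 0.1)
})

test_that("dwt features carry coefficient provenance and match the transform", {
  es <- feat_epochs(2, seed = 5)
  d <- dwt_features(es, feature_config("natural"))
  dec <- dwt_decompose(es$data[1, match("PO3", es$channels),
                               which(epoch_times(es) >= 0 &
                                     epoch_times(es) < 0.66 - 1e-9)], 3)
  expect_equal(unname(d$matrix[1, 1:33]), dec$approx, tolerance = 1e-12)
})

test_that("the min-max normalizer maps train extrema to +-1", {
  fm <- structure(list(matrix = cbind(a = c(0, 5, 10), b = c(1, 1, 1)),
                       feature_names = c("a", "b"), labels = rep("x", 3),
                       method = "VAR", normalization = "none"),
                  class = "feature_matrix")
  expect_warning(norm <- fit_normalizer(fm), "constant")
  out <- apply_normalizer(norm, fm)
  expect_equal(unname(out$matrix[, 1]), c(-1, 0, 1))
  expect_true(all(out$matrix[, 2] == 0))
  # affine extrapolation beyond the training range is permitted
  fm_test <- fm; fm_test$matrix <- cbind(a = 12, b = 3)
  out2 <- apply_normalizer(norm, fm_test)
  expect_equal(unname(out2$matrix[1, 1]), 1.4)
})

test_that("fusion conserves widths, order and degenerates to identity", {
  es <- feat_epochs(4, seed = 6)
  cfg <- feature_config()
  v <- var_features(es, cfg); p <- psd_features(es, cfg)
  f1 <- fuse_features(list(v))
  expect_equal(f1$matrix, v$matrix)
  f2 <- fuse_features(list(v, p))
  expect_equal(ncol(f2$matrix), ncol(v$matrix) + ncol(p$matrix))
  expect_equal(f2$feature_names,
               c(v$feature_names, p$feature_names))
  bad <- p; bad$matrix <- bad$matrix[1:2, , drop = FALSE]
  bad$labels <- bad$labels[1:2]
  expect_error(fuse_features(list(v, bad)), "mismatch")
})

test_that("feature extraction is deterministic and permutation-consistent", {
  es <- feat_epochs(3, seed = 7)
  cfg <- feature_config()
  expect_identical(var_features(es, cfg)$matrix, var_features(es, cfg)$matrix)
  # permuting channels in both data and config permutes feature blocks
  perm <- rev(feature_channels())
  cfg2 <- feature_config(channels = perm)
  v1 <- var_features(es, cfg)
  v2 <- var_features(es, cfg2)
  for (ch in feature_channels()) {
    c1 <- grep(paste0("^var\\.", ch, "\\."), v1$feature_names)
    c2 <- grep(paste0("^var\\.", ch, "\\."), v2$feature_names)
    expect_equal(v1$matrix[, c1], v2$matrix[, c2])
  }
})

test_that("missing channels are reported by name", {
  es <- noise_epochs(2)
  es$channels[1] <- "XX"
  dimnames(es$data)[[2]] <- es$channels
  expect_error(var_features(es, feature_config()), "PO3")
})
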