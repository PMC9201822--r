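mk_avg <- function(y, fs = 250, window = c(-0.5, 1)) {
  structure(list(mean = rbind(O2 = y, Pz = -y), sd = NULL,
                 channels = c("O2", "Pz"), sampling_rate = fs,
                 window = window, condition = "explosion", n_trials = 38,
                 trials_used = 1:38, subject_id = "X"),
            class = "erp_average")
}

tms <- (-125:249) / 250 * 1000   # 375-sample epoch grid

test_that("peak_measure finds constructed extrema with the tie-break rule", {
  bump <- 5 * exp(-(tms - 300)^2 / (2 * 40^2))
  avg <- mk_avg(bump)
  pm <- peak_measure(avg, "O2", c(200, 400), "positive")
  expect_equal(pm$amplitude, 5, tolerance = 1e-6)
  expect_equal(pm$latency_ms, 300, tolerance = 2)
  # negative polarity on the same trace returns the in-window minimum
  pm2 <- peak_measure(avg, "O2", c(200, 400), "negative")
  expect_lt(pm2$amplitude, 5 * exp(-(100)^2 / (2 * 40^2)) + 1e-9)
  expect_true(pm2$latency_ms %in% c(200, 400))
  # two equal maxima: earliest wins
  y <- numeric(375)
  y[tms == 252] <- 3; y[tms == 352] <- 3
  pm3 <- peak_measure(mk_avg(y), "O2", c(200, 400), "positive")
  expect_equal(pm3$latency_ms, 252)
  expect_error(peak_measure(avg, "Oz", c(200, 400)), "not present")
  expect_error(peak_measure(avg, "O2", c(200, 2000)), "outside the epoch")
})

# independent oracle: direct formula with t-CDF by numerical integration
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  dens <- function(x) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  p <- 2 * integrate(dens, -Inf, -abs(t), rel.tol = 1e-12)$value
  list(t = t, df = df, p = p)
}

test_that("welch_ttest matches a numerical-integration oracle", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  got <- welch_ttest(a, b)
  ref <- welch_oracle(a, b)
  expect_equal(got$t, ref$t, tolerance = 1e-10)
  expect_equal(got$df, ref$df, tolerance = 1e-10)
  expect_equal(got$p, ref$p, tolerance = 1e-10)
  set.seed(5)
  for (rep in 1:5) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    got <- welch_ttest(a, b)
    ref <- welch_oracle(a, b)
    expect_equal(got$t, ref$t, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
})

test_that("welch_ttest degenerate and identity cases are defined", {
  x <- c(1, 1, 1)
  same <- welch_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  diffm <- welch_ttest(c(1, 1), c(2, 2))
  expect_true(diffm$degenerate)
  expect_equal(diffm$p, 0)
  # equal n, equal sample variance: df collapses to 2n - 2
  a <- c(0, 1, 2, 3); b <- c(10, 11, 12, 13)
  expect_equal(welch_ttest(a, b)$df, 6)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})

test_that("welch_ttest is antisymmetric and scale-invariant", {
  set.seed(6)
  a <- rnorm(8); b <- rnorm(10, 0.5)
  ab <- welch_ttest(a, b); ba <- welch_ttest(b, a)
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  sc <- welch_ttest(3 * a, 3 * b)
  expect_equal(sc$t, ab$t, tolerance = 1e-12)
  expect_equal(sc$df, ab$df, tolerance = 1e-12)
})

test_that("scalp snapshots read nearest-sample amplitudes", {
  avg <- mk_avg(rep(1, 375))
  snap <- scalp_snapshot(avg, c(120, 320, 540))
  expect_equal(dim(snap), c(2L, 3L))
  expect_true(all(snap["O2", ] == 1))
  expect_true(all(snap["Pz", ] == -1))
  expect_error(scalp_snapshot(avg, 1500), "outside")
})

test_that("a snapshot at the injected P1 latency peaks at the focal channel", {
  prof <- subject_profile()
  tg <- seq(-0.5, 1, by = 1 / 250)
  w <- evoked_waveform(condition_presets("explosion", "visual_only"), prof, tg)
  avg <- structure(list(mean = w, channels = rownames(w), sampling_rate = 250,
                        window = c(-0.5, 1), condition = "explosion",
                        n_trials = 1, trials_used = 1, subject_id = "X"),
                   class = "erp_average")
  snap <- scalp_snapshot(avg, 125)
  expect_equal(rownames(snap)[which.max(snap[, 1])], "O2")
})
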