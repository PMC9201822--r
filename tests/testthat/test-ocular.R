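# inject-and-measure: neural background plus stereotyped blink transients
# projected onto the montage with a frontal topography
blinky_recording <- function(seed = 1, n = 20000, fs = 250, n_blinks = 40) {
  chans <- c("Fp1", "Fp2", "Cz", "Pz", "O2")
  set.seed(seed)
  neural <- matrix(rnorm(length(chans) * n), length(chans))
  tmpl <- exp(-(seq(-250, 250) / fs * 1000)^2 / (2 * 60^2))
  w <- c(Fp1 = 1, Fp2 = 0.95, Cz = 0.25, Pz = 0.1, O2 = 0.02)
  blink <- numeric(n)
  centers <- sort(sample(300:(n - 300), n_blinks))
  for (cc in centers)
    blink[(cc - 250):(cc + 250)] <- blink[(cc - 250):(cc + 250)] + 40 * tmpl
  data <- neural + outer(unname(w), blink)
  list(rec = make_recording(data, fs = fs,
                            events = data.frame(onset_sample = 5000L,
                                                onset_s = 20,
                                                condition = "control"),
                            channels = chans),
       blink = blink, neural = neural)
}

test_that("regression cleaning removes the blink component from all channels", {
  bl <- blinky_recording(seed = 1)
  out <- remove_ocular_artifacts(bl$rec, method = "regression")
  for (i in seq_len(nrow(out$data)))
    expect_lt(abs(cor(out$data[i, ], bl$blink)), 0.2)
  expect_equal(out$ocular_report$method, "regression")
  expect_length(out$ocular_report$coefficients, 5)
})

test_that("ICA cleaning removes the blink component from all channels", {
  bl <- blinky_recording(seed = 2)
  out <- remove_ocular_artifacts(bl$rec, method = "ica_corr", seed = 9)
  for (i in seq_len(nrow(out$data)))
    expect_lt(abs(cor(out$data[i, ], bl$blink)), 0.2)
  expect_gte(length(out$ocular_report$removed_components), 1)
})

test_that("blink-free data passes through nearly unchanged", {
  chans <- c("Fp1", "Fp2", "Cz", "Pz", "O2")
  set.seed(3)
  data <- matrix(rnorm(5 * 20000), 5)
  rec <- make_recording(data, fs = 250,
                        events = data.frame(onset_sample = 5000L, onset_s = 20,
                                            condition = "control"),
                        channels = chans)
  out <- remove_ocular_artifacts(rec, method = "regression")
  # the proxy channels themselves are consumed by the regression; the
  # no-op bound applies to the analysis channels
  for (i in which(!chans %in% c("Fp1", "Fp2"))) {
    rel <- sd(out$data[i, ] - data[i, ]) / sd(data[i, ])
    expect_lt(rel, 0.05)
  }
  # the ICA route leaves blink-free data untouched on every channel
  out2 <- remove_ocular_artifacts(rec, method = "ica_corr", seed = 8)
  for (i in seq_len(5)) {
    rel <- sd(out2$data[i, ] - data[i, ]) / sd(data[i, ])
    expect_lt(rel, 0.05)
  }
})

test_that("ICA component selection is deterministic for a fixed seed", {
  bl <- blinky_recording(seed = 4)
  o1 <- remove_ocular_artifacts(bl$rec, method = "ica_corr", seed = 5)
  o2 <- remove_ocular_artifacts(bl$rec, method = "ica_corr", seed = 5)
  expect_identical(o1$ocular_report$removed_components,
                   o2$ocular_report$removed_components)
  expect_equal(o1$data, o2$data, tolerance = 1e-12)
})

test_that("cleaning requires the frontal proxy channels", {
  rec <- make_recording(matrix(rnorm(2 * 2000), 2), fs = 250,
                        events = data.frame(onset_sample = 500L, onset_s = 2,
                                            condition = "control"),
                        channels = c("O2", "Pz"))
  expect_error(remove_ocular_artifacts(rec), "Fp1 and Fp2")
})

test_that("epoch sets can be cleaned in place", {
  es <- noise_epochs(12, seed = 6)
  blink <- exp(-(seq_len(375) - 180)^2 / (2 * 20^2)) * 30
  fp <- match(c("Fp1", "Fp2"), es$channels)
  for (tr in c(2, 7)) for (ci in fp) es$data[tr, ci, ] <- es$data[tr, ci, ] + blink
  out <- remove_ocular_artifacts(es, method = "regression")
  expect_s3_class(out, "epoch_set")
  expect_equal(dim(out$data), dim(es$data))
  # the blink energy at the proxy channels is strongly reduced
  expect_lt(sd(out$data[2, fp[1], ]), 0.5 * sd(es$data[2, fp[1], ]))
  # untouched trials keep their shape
  expect_gt(cor(out$data[4, 1, ], es$data[4, 1, ]), 0.9)
})
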