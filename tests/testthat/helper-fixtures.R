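# Shared in-code fixtures. Heavyweight cohort simulations are memoised so
# that several test files can reuse the same objects.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small one-block session config (30 trials: 5 explosion, 5 burning, 20 control)
tiny_session <- function() session_config(n_blocks = 1)

# construct an epoch_set directly from an array (trials x channels x samples)
make_epoch_set <- function(data, conditions, fs = 250, window = c(-0.5, 1.0),
                           channels = NULL, subject_id = "T01") {
  channels <- channels %||% dimnames(data)[[2]] %||%
    paste0("ch", seq_len(dim(data)[2]))
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(
    data = data, channels = channels, sampling_rate = fs, window = window,
    conditions = conditions, kept = rep(TRUE, dim(data)[1]),
    reject_reason = rep(NA_character_, dim(data)[1]),
    skipped = data.frame(), baseline_corrected = FALSE,
    subject_id = subject_id
  ), class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# construct a continuous_recording directly
make_recording <- function(data, events, fs = 250, channels = NULL) {
  channels <- channels %||% rownames(data) %||% default_montage()$channel[seq_len(nrow(data))]
  rownames(data) <- channels
  structure(list(channel_names = channels, sampling_rate = fs, data = data,
                 events = events, montage = default_montage(),
                 subject_id = "T01"),
            class = "continuous_recording")
}

# epoch_set of white-noise trials over the 11 feature channels plus Fp1/Fp2
noise_epochs <- function(n_trials, n_samples = 375, sd = 1, seed = 1,
                         conditions = NULL) {
  chans <- c(feature_channels(), "Fp1", "Fp2")
  set.seed(seed)
  data <- array(stats::rnorm(n_trials * length(chans) * n_samples, sd = sd),
                dim = c(n_trials, length(chans), n_samples))
  make_epoch_set(data, conditions %||% rep("control", n_trials),
                 channels = chans)
}

# one preprocessed subject at full session size (memoised; used by several
# acceptance checks)
full_subject_epochs <- function(seed = 501) {
  memo(paste0("subj", seed), {
    suppressMessages(simulate_subject_epochs(
      session_config(), "visual_only", subject_profile(), noise_config(),
      seed = seed))
  })
}
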