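#' One-call preprocessing chain for a recording
#'
#' Channel exclusion, zero-phase filtering, epoching, baseline correction,
#' ocular-artifact removal and variance/kurtosis trial rejection, in that
#' order.
#'
#' @param rec a `continuous_recording`.
#' @param filters a [filter_spec()].
#' @param window epoch window in seconds.
#' @param exclude channels dropped before filtering (default O1, PO7).
#' @param ocular_method `"regression"` or `"ica_corr"` (NULL skips the step).
#' @param ocular_threshold ICA proxy-correlation threshold.
#' @param z_var,z_kurt rejection thresholds.
#' @param seed seed for the ICA initialization.
#' @return an `epoch_set`, cleaned and flagged.
#' @export
preprocess_recording <- function(rec, filters = filter_spec(),
                                 window = c(-0.5, 1.0),
                                 exclude = c("O1", "PO7"),
                                 ocular_method = "regression",
                                 ocular_threshold = 0.8,
                                 z_var = 3, z_kurt = 3, seed = 1) {
  rec <- exclude_channels(rec, exclude)
  rec <- apply_filters(rec, filters)
  es <- segment_epochs(rec, window)
  es <- baseline_correct(es)
  if (!is.null(ocular_method))
    es <- remove_ocular_artifacts(es, ocular_method,
                                  threshold = ocular_threshold, seed = seed)
  reject_trials(es, z_var = z_var, z_kurt = z_kurt)
}

#' Simulate and preprocess one subject
#'
#' @inheritParams simulate_session
#' @param preprocess_args list of overrides for [preprocess_recording()].
#' @return an `epoch_set`.
#' @export
simulate_subject_epochs <- function(cfg = session_config(),
                                    modality = "visual_only",
                                    profile = subject_profile(),
                                    noise = noise_config(), seed,
                                    preprocess_args = list()) {
  rec <- simulate_session(cfg, modality, profile, noise, seed)
  do.call(preprocess_recording, c(list(rec = rec), preprocess_args))
}

#' Simulate a cohort and recover condition averages
#'
#' Simulates `n_subjects` full sessions (with sampled inter-subject
#' variability), preprocesses each, computes per-subject condition averages
#' (default 38 trials) and the grand average. This is the parameter-recovery
#' experiment used to check that the analysis chain reproduces the injected
#' evoked templates.
#'
#' @param n_subjects cohort size (default 8).
#' @param condition condition to average.
#' @param modality stimulus modality.
#' @param seed master seed (fans out to profiles, sessions and selections).
#' @param cfg a [session_config()].
#' @param noise a [noise_config()].
#' @param n_select trials per subject average.
#' @param keep_epochs also return the per-subject `epoch_set`s (memory
#'   permitting).
#' @param preprocess_args list of overrides for [preprocess_recording()].
#' @param profile_args list of overrides for [sample_subject_profiles()].
#' @param max_redraws subjects whose preprocessed recording retains fewer
#'   than `n_select` trials of the target condition are replaced by a fresh
#'   draw (up to this many times each), mirroring the exclusion of subjects
#'   with unusable recordings in cohort studies.
#' @return list with `grand` (a `grand_average`), `subject_averages`, and
#'   optionally `epoch_sets`.
#' @export
run_recovery_cohort <- function(n_subjects = 8, condition = "explosion",
                                modality = "visual_only", seed,
                                cfg = session_config(),
                                noise = noise_config(), n_select = 38,
                                keep_epochs = FALSE,
                                preprocess_args = list(),
                                profile_args = list(),
                                max_redraws = 3) {
  sds <- derive_seeds(seed, 4 * n_subjects * (max_redraws + 1) + 1)
  profiles <- do.call(sample_subject_profiles,
                      c(list(n_subjects = n_subjects * (max_redraws + 1),
                             seed = sds[1]),
                        profile_args))
  subject_averages <- vector("list", n_subjects)
  used_profiles <- vector("list", n_subjects)
  epoch_sets <- if (keep_epochs) vector("list", n_subjects) else NULL
  draw <- 0
  for (i in seq_len(n_subjects)) {
    for (attempt in 0:max_redraws) {
      draw <- draw + 1
      es <- simulate_subject_epochs(cfg, modality, profiles[[draw]], noise,
                                    seed = sds[2 * draw],
                                    preprocess_args = preprocess_args)
      n_kept <- sum(es$kept & es$conditions == condition)
      if (n_kept >= n_select || attempt == max_redraws) break
      message(sprintf(
        "subject %d draw %d retains %d '%s' trials (< %d); excluded and redrawn",
        i, attempt + 1, n_kept, condition, n_select))
    }
    subject_averages[[i]] <- subject_average(es, condition,
                                             n_select = n_select,
                                             seed = sds[2 * draw + 1])
    used_profiles[[i]] <- profiles[[draw]]
    if (keep_epochs) epoch_sets[[i]] <- es
  }
  profiles <- used_profiles
  out <- list(grand = grand_average(subject_averages),
              subject_averages = subject_averages,
              profiles = profiles)
  if (keep_epochs) out$epoch_sets <- epoch_sets
  out
}

#' Build per-method detection feature sets from cohort epochs
#'
#' Selects `n_select` kept stimulus trials per subject and the same number of
#' control trials, extracts VAR, PSD and DWT features and their DVP fusion,
#' and assembles balanced two-class datasets.
#'
#' @param epoch_sets list of per-subject `epoch_set`s.
#' @param condition stimulus condition (explosion or burning).
#' @param feature_cfg a [feature_config()].
#' @param n_select trials per subject and class.
#' @param seed selection seed.
#' @return named list of datasets (`VAR`, `PSD`, `DWT`, `DVP`), each as
#'   returned by [assemble_dataset()].
#' @export
cohort_detection_datasets <- function(epoch_sets, condition,
                                      feature_cfg = feature_config(),
                                      n_select = 38, seed = 1) {
  sds <- derive_seeds(seed, length(epoch_sets) + 1)
  stim_parts <- list(); ctrl_parts <- list()
  for (i in seq_along(epoch_sets)) {
    es <- epoch_sets[[i]]
    ssd <- derive_seeds(sds[i], 2)
    pick <- function(cond, s) {
      idx <- which(es$kept & es$conditions == cond)
      if (length(idx) < n_select)
        stop(sprintf("subject %d: %d kept '%s' trials, %d required",
                     i, length(idx), cond, n_select), call. = FALSE)
      sub <- es
      used <- sort(with_seed(s, sample(idx, n_select)))
      sub$data <- es$data[used, , , drop = FALSE]
      sub$conditions <- es$conditions[used]
      sub$kept <- rep(TRUE, n_select)
      sub$reject_reason <- rep(NA_character_, n_select)
      sub
    }
    stim_parts[[i]] <- pick(condition, ssd[1])
    ctrl_parts[[i]] <- pick("control", ssd[2])
  }
  merge_sets <- function(parts) {
    ref <- parts[[1]]
    ref$data <- do.call(abind_trials, lapply(parts, `[[`, "data"))
    ref$conditions <- unlist(lapply(parts, `[[`, "conditions"))
    ref$kept <- rep(TRUE, length(ref$conditions))
    ref$reject_reason <- rep(NA_character_, length(ref$conditions))
    ref
  }
  stim_es <- merge_sets(stim_parts)
  ctrl_es <- merge_sets(ctrl_parts)
  fm <- function(es) list(VAR = var_features(es, feature_cfg),
                          PSD = psd_features(es, feature_cfg),
                          DWT = dwt_features(es, feature_cfg))
  fs_ <- fm(stim_es); fc_ <- fm(ctrl_es)
  fs_$DVP <- fuse_features(fs_[c("VAR", "PSD", "DWT")])
  fc_$DVP <- fuse_features(fc_[c("VAR", "PSD", "DWT")])
  lapply(stats::setNames(nm = c("VAR", "PSD", "DWT", "DVP")), function(m)
    assemble_dataset(fs_[[m]], fc_[[m]], balance = TRUE,
                     seed = sds[length(epoch_sets) + 1]))
}

#' Cross-validated detection over all feature methods
#'
#' @param datasets output of [cohort_detection_datasets()].
#' @param cv a [cv_config()].
#' @param svm a [svm_config()].
#' @return named list of `cv_result`s.
#' @export
detection_run <- function(datasets, cv = cv_config(), svm = svm_config()) {
  lapply(datasets, function(ds) crossval_train_eval(ds$x, ds$y, cv, svm))
}
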