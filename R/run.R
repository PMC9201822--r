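# Configuration, staging and provenance for the command-line front end.

run_config_schema <- function() {
  list(
    out_dir = NULL, master_seed = NULL, log_level = NULL,
    session = c("n_blocks", "trials_per_block", "trial_duration",
                "deviant_fraction", "sampling_rate", "inter_trial_gap",
                "stimulus_delay"),
    cohort = c("n_subjects", "modalities", "amp_scale_sd", "latency_shift_sd",
               "latency_jitter_sd", "noise_level", "blink_rate"),
    noise = c("pink_exponent", "alpha_freq", "alpha_bw", "alpha_rms",
              "alpha_sigma", "line_freqs", "line_amps", "drift_rms",
              "blink_amplitude", "blink_width", "blink_sigma", "trial_amp_sd",
              "reference_level"),
    filters = c("notch_freqs", "notch_halfwidth", "bp_low", "bp_high",
                "bp_order", "notch_order"),
    epochs = c("window"),
    exclude_channels = NULL,
    ocular = c("method", "threshold"),
    rejection = c("z_var", "z_kurt"),
    averaging = c("n_select", "select"),
    features = c("profile"),
    cv = c("k", "train_fraction", "scheme", "stratified"),
    svm = c("cost"),
    conditions = NULL
  )
}

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML configuration, rejects unknown keys against the schema, and
#' fills defaults. The shipped full-size study profile is at
#' `system.file("extdata", "paper_profile.yaml", package = "oddballerp")`.
#'
#' @param path YAML file path, or NULL for the shipped defaults.
#' @param overrides named list merged over the file contents (CLI flags take
#'   precedence over the file).
#' @return validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  path <- path %||% system.file("extdata", "paper_profile.yaml",
                                package = "oddballerp")
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  schema <- run_config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (blk in names(schema)) {
    allowed <- schema[[blk]]
    if (is.null(allowed) || !is.list(cfg[[blk]])) next
    bad <- setdiff(names(cfg[[blk]]), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in block '%s': %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg$out_dir <- cfg$out_dir %||% "oddballerp_run"
  cfg$master_seed <- cfg$master_seed %||% 1L
  cfg$log_level <- cfg$log_level %||% "INFO"
  cfg$conditions <- cfg$conditions %||% c("explosion", "burning")
  class(cfg) <- "run_config"
  cfg
}

log_msg <- function(cfg, level, fmt, ...) {
  levels_ <- c(DEBUG = 1, INFO = 2, WARN = 3)
  if (levels_[[level]] >= levels_[[cfg$log_level %||% "INFO"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

cfg_session <- function(cfg) do.call(session_config, cfg$session %||% list())
cfg_noise <- function(cfg) do.call(noise_config, cfg$noise %||% list())
cfg_filters <- function(cfg) do.call(filter_spec, cfg$filters %||% list())
cfg_feature <- function(cfg)
  feature_config(profile = (cfg$features %||% list())$profile %||% "paper-dims")
cfg_cv <- function(cfg, seed)
  do.call(cv_config, c(cfg$cv %||% list(), list(seed = seed)))
cfg_svm <- function(cfg) do.call(svm_config, cfg$svm %||% list())

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

write_manifest <- function(cfg, stage, inputs, outputs) {
  man <- list(stage = stage,
              config_hash = object_hash(unclass(cfg)),
              master_seed = cfg$master_seed,
              package_version = as.character(utils::packageVersion("oddballerp")),
              inputs = inputs,
              input_hashes = vapply(inputs, function(p)
                if (file.exists(p)) object_hash(readBin(p, "raw", file.size(p)))
                else NA_character_, ""),
              outputs = outputs,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(man, file.path(stage_path(cfg, stage), "manifest.json"),
                       auto_unbox = TRUE)
  invisible(man)
}

require_stage <- function(cfg, stage) {
  d <- stage_path(cfg, stage)
  if (!dir.exists(d))
    stop(sprintf("missing upstream artifacts: run stage '%s' first", stage),
         call. = FALSE)
  d
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write per-subject EDF sessions + event tables),
#' `preprocess` (epoch sets + rejection logs), `erp` (subject/grand averages
#' and peak tables), `features` (per-method feature matrices), `classify`
#' (cross-validated detection results), `report` (detection report). Each
#' stage writes its artifacts plus a manifest with config hash, seed and
#' input hashes under `<out_dir>/<stage>/`.
#'
#' @param name stage name.
#' @param cfg a `run_config` from [load_run_config()].
#' @return invisibly, the list of artifact paths written.
#' @export
run_stage <- function(name = c("simulate", "preprocess", "erp", "features",
                               "classify", "report"), cfg) {
  name <- match.arg(name)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(stage_path(cfg, name), recursive = TRUE, showWarnings = FALSE)
  coh <- cfg$cohort %||% list()
  n_subj <- coh$n_subjects %||% 8
  modalities <- coh$modalities %||% c("visual_only", "audio_visual")
  sds <- derive_seeds(cfg$master_seed, 4 * n_subj * length(modalities) + 16)
  outputs <- character()

  if (name == "simulate") {
    scfg <- cfg_session(cfg)
    noise <- cfg_noise(cfg)
    k <- 0
    for (mod in modalities) {
      profiles <- sample_subject_profiles(
        n_subj, seed = sds[1],
        amp_scale_sd = coh$amp_scale_sd %||% 0.2,
        latency_shift_sd = coh$latency_shift_sd %||% 6,
        latency_jitter_sd = coh$latency_jitter_sd %||% 6,
        noise_level = coh$noise_level %||% 12,
        blink_rate = coh$blink_rate %||% 10)
      for (i in seq_len(n_subj)) {
        k <- k + 1
        rec <- simulate_session(scfg, mod, profiles[[i]], noise,
                                seed = sds[2 + k])
        prefix <- file.path(stage_path(cfg, "simulate"),
                            sprintf("%s_S%02d", mod, i))
        write_session(rec, prefix)
        outputs <- c(outputs, paste0(prefix, ".edf"))
        log_msg(cfg, "DEBUG", "simulated %s subject %d (%d events)",
                mod, i, nrow(rec$events))
      }
    }
    write_manifest(cfg, "simulate", character(), outputs)
  } else if (name == "preprocess") {
    ind <- require_stage(cfg, "simulate")
    ppa <- list(filters = cfg_filters(cfg),
                window = unlist((cfg$epochs %||% list())$window %||% c(-0.5, 1)),
                exclude = cfg$exclude_channels %||% c("O1", "PO7"),
                ocular_method = (cfg$ocular %||% list())$method %||% "regression",
                ocular_threshold = (cfg$ocular %||% list())$threshold %||% 0.8,
                z_var = (cfg$rejection %||% list())$z_var %||% 3,
                z_kurt = (cfg$rejection %||% list())$z_kurt %||% 3)
    edfs <- list.files(ind, pattern = "\\.edf$", full.names = TRUE)
    logs <- list()
    for (f in edfs) {
      rec <- read_session(sub("\\.edf$", "", f))
      es <- do.call(preprocess_recording, c(list(rec = rec), ppa))
      out <- file.path(stage_path(cfg, "preprocess"),
                       sub("\\.edf$", "_epochs.rds", basename(f)))
      saveRDS(es, out)
      outputs <- c(outputs, out)
      logs[[basename(f)]] <- data.frame(
        file = basename(f), epoch = seq_along(es$kept),
        condition = es$conditions, kept = es$kept,
        reason = es$reject_reason, stringsAsFactors = FALSE)
      log_msg(cfg, "DEBUG", "%s: %d/%d epochs kept", basename(f),
              sum(es$kept), length(es$kept))
    }
    logf <- file.path(stage_path(cfg, "preprocess"), "rejection_log.tsv")
    utils::write.table(do.call(rbind, logs), logf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_manifest(cfg, "preprocess", edfs, c(outputs, logf))
  } else if (name == "erp") {
    ind <- require_stage(cfg, "preprocess")
    n_sel <- (cfg$averaging %||% list())$n_select %||% 38
    sel <- (cfg$averaging %||% list())$select %||% "random"
    peak_rows <- list()
    for (mod in modalities) {
      files <- list.files(ind, pattern = paste0("^", mod, "_S.*_epochs\\.rds$"),
                          full.names = TRUE)
      sets <- lapply(files, readRDS)
      for (cond in cfg$conditions) {
        sas <- lapply(seq_along(sets), function(i)
          subject_average(sets[[i]], cond, n_select = n_sel, select = sel,
                          seed = sds[10 + i]))
        ga <- grand_average(sas)
        out <- file.path(stage_path(cfg, "erp"),
                         sprintf("grand_%s_%s.rds", mod, cond))
        saveRDS(ga, out)
        outputs <- c(outputs, out)
        pk <- peak_table(list(ga), channel = "O2")
        pk$modality <- mod; pk$condition <- cond
        peak_rows[[paste(mod, cond)]] <- pk
      }
    }
    pt <- do.call(rbind, peak_rows)
    ptf <- file.path(stage_path(cfg, "erp"), "peaks_O2.tsv")
    utils::write.table(pt, ptf, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(pt, file.path(stage_path(cfg, "erp"), "peaks_O2.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(cfg, "erp", character(), c(outputs, ptf))
  } else if (name == "features" || name == "classify" || name == "report") {
    ind <- require_stage(cfg, "preprocess")
    n_sel <- (cfg$averaging %||% list())$n_select %||% 38
    fcfg <- cfg_feature(cfg)
    runs <- list()
    for (mod in modalities) {
      files <- list.files(ind, pattern = paste0("^", mod, "_S.*_epochs\\.rds$"),
                          full.names = TRUE)
      sets <- lapply(files, readRDS)
      for (cond in cfg$conditions) {
        ds <- cohort_detection_datasets(sets, cond, fcfg, n_select = n_sel,
                                        seed = sds[5])
        if (name == "features") {
          out <- file.path(stage_path(cfg, "features"),
                           sprintf("features_%s_%s.rds", mod, cond))
          saveRDS(ds, out)
          outputs <- c(outputs, out)
        } else {
          res <- detection_run(ds, cfg_cv(cfg, seed = sds[6]), cfg_svm(cfg))
          for (m in names(res)) runs[[m]][[cond]][[mod]] <- res[[m]]
        }
      }
    }
    if (name == "features") {
      write_manifest(cfg, "features", character(), outputs)
    } else {
      rep_ <- build_report(runs)
      out <- file.path(stage_path(cfg, name), "detection_report")
      write_report(rep_, out)
      cvout <- file.path(stage_path(cfg, name), "cv_results.rds")
      saveRDS(runs, cvout)
      outputs <- c(outputs, paste0(out, ".json"), cvout)
      write_manifest(cfg, name, character(), outputs)
      return(invisible(rep_))
    }
  }
  invisible(outputs)
}

#' Run the full pipeline
#'
#' `simulate`, `preprocess`, `erp` and `classify`/`report` in sequence.
#'
#' @param cfg a `run_config`.
#' @return the final `detection_report`, invisibly.
#' @export
run_pipeline <- function(cfg) {
  for (st in c("simulate", "preprocess", "erp")) {
    log_msg(cfg, "INFO", "running stage %s", st)
    run_stage(st, cfg)
  }
  log_msg(cfg, "INFO", "running stage report")
  run_stage("report", cfg)
}
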