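#' Cross-validation configuration
#'
#' The published protocol ("k = 10, 80% training data, 20% testing data") is
#' realized by default as 10 repeated stratified random 80/20 splits;
#' canonical disjoint k-fold partitioning is available via
#' `scheme = "kfold"`.
#'
#' @param k number of folds / repeats (default 10).
#' @param train_fraction training fraction for `repeated_split` (default 0.8).
#' @param scheme `"repeated_split"` (default) or `"kfold"`.
#' @param stratified keep class proportions in every split (default TRUE).
#' @param seed split seed.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(k = 10, train_fraction = 0.8,
                      scheme = c("repeated_split", "kfold"),
                      stratified = TRUE, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(k >= 2, train_fraction > 0, train_fraction < 1)
  structure(list(k = as.integer(k), train_fraction = train_fraction,
                 scheme = scheme, stratified = stratified, seed = seed),
            class = "cv_config")
}

#' Linear-SVM configuration
#' @param cost regularization parameter C (default 1).
#' @return object of class `svm_config`.
#' @export
svm_config <- function(cost = 1) {
  assert_scalar_num(cost, "cost", lower = 1e-12)
  structure(list(kernel = "linear", cost = cost), class = "svm_config")
}

#' Assemble a two-class detection dataset
#'
#' Pools stimulus and control feature matrices into one labelled dataset.
#' With `balance = TRUE` (default) the majority class is subsampled (seeded)
#' to the minority size, reproducing the balanced 304-vs-304 pooled design.
#'
#' @param stim_features `feature_matrix` of stimulus trials.
#' @param ctrl_features `feature_matrix` of control trials.
#' @param balance subsample the majority class (default TRUE).
#' @param seed subsampling seed.
#' @return list with `x` (matrix), `y` (factor, levels control < stimulus),
#'   `feature_names`, `class_counts`.
#' @export
assemble_dataset <- function(stim_features, ctrl_features, balance = TRUE,
                             seed = 1) {
  stopifnot(inherits(stim_features, "feature_matrix"),
            inherits(ctrl_features, "feature_matrix"))
  if (nrow(stim_features$matrix) == 0 || nrow(ctrl_features$matrix) == 0)
    stop("both classes must be nonempty", call. = FALSE)
  if (!identical(stim_features$feature_names, ctrl_features$feature_names))
    stop("feature sets differ between classes", call. = FALSE)
  xs <- stim_features$matrix
  xc <- ctrl_features$matrix
  if (balance) {
    n <- min(nrow(xs), nrow(xc))
    sds <- derive_seeds(seed, 2)
    if (nrow(xs) > n) xs <- xs[sort(with_seed(sds[1], sample(nrow(xs), n))), , drop = FALSE]
    if (nrow(xc) > n) xc <- xc[sort(with_seed(sds[2], sample(nrow(xc), n))), , drop = FALSE]
  }
  x <- rbind(xs, xc)
  y <- factor(c(rep("stimulus", nrow(xs)), rep("control", nrow(xc))),
              levels = c("control", "stimulus"))
  list(x = x, y = y, feature_names = stim_features$feature_names,
       class_counts = table(y))
}

fold_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

make_splits <- function(y, cv) {
  n <- length(y)
  idx_by_class <- split(seq_len(n), y)
  sds <- derive_seeds(cv$seed, cv$k)
  if (cv$scheme == "repeated_split") {
    lapply(seq_len(cv$k), function(f) {
      train <- with_seed(sds[f], {
        if (cv$stratified) {
          unlist(lapply(idx_by_class, function(ix)
            sample(ix, round(cv$train_fraction * length(ix)))))
        } else sample(n, round(cv$train_fraction * n))
      })
      list(train = sort(train), test = setdiff(seq_len(n), train))
    })
  } else {
    folds <- with_seed(sds[1], {
      if (cv$stratified) {
        f <- integer(n)
        for (ix in idx_by_class)
          f[ix] <- sample(rep_len(seq_len(cv$k), length(ix)))
        f
      } else sample(rep_len(seq_len(cv$k), n))
    })
    lapply(seq_len(cv$k), function(f)
      list(train = which(folds != f), test = which(folds == f)))
  }
}

#' Cross-validated linear-SVM training and evaluation
#'
#' Per fold: fit the [-1, 1] normalizer on the training split only, apply it
#' unchanged to the test split, train a linear SVM, and score the test
#' split. The stimulus class is positive; decision values of exactly zero
#' are assigned to the positive class.
#'
#' @param x feature matrix (trials x features).
#' @param y factor with levels control, stimulus.
#' @param cv a [cv_config()].
#' @param svm a [svm_config()].
#' @param normalize fit/apply the min-max normalizer per fold (default TRUE).
#' @return object of class `cv_result`: list with `folds` (per-fold metric
#'   lists), `mean` and `sd` of accuracy/sensitivity/specificity.
#' @export
crossval_train_eval <- function(x, y, cv = cv_config(), svm = svm_config(),
                                normalize = TRUE) {
  stopifnot(is.factor(y), nlevels(y) == 2, nrow(x) == length(y))
  splits <- make_splits(y, cv)
  folds <- vector("list", length(splits))
  for (f in seq_along(splits)) {
    sp <- splits[[f]]
    if (length(unique(y[sp$train])) < 2 || length(sp$test) == 0)
      stop(sprintf("degenerate split in fold %d", f), call. = FALSE)
    xtr <- x[sp$train, , drop = FALSE]
    xte <- x[sp$test, , drop = FALSE]
    if (normalize) {
      lo <- apply(xtr, 2, min); hi <- apply(xtr, 2, max)
      rng <- hi - lo
      flat <- rng <= 0
      rng[flat] <- 1
      scale01 <- function(m) {
        out <- sweep(sweep(m, 2, (lo + hi) / 2), 2, rng / 2, "/")
        out[, flat] <- 0
        out
      }
      xtr <- scale01(xtr); xte <- scale01(xte)
    }
    fit <- e1071::svm(x = xtr, y = y[sp$train], kernel = "linear",
                      cost = svm$cost, scale = FALSE)
    dv <- attr(stats::predict(fit, xte, decision.values = TRUE),
               "decision.values")
    # orient decision values so positive => stimulus
    pos_first <- colnames(dv)[1] == "stimulus/control"
    score <- if (pos_first) dv[, 1] else -dv[, 1]
    pred <- ifelse(score >= 0, "stimulus", "control")
    truth <- as.character(y[sp$test])
    folds[[f]] <- fold_metrics(tp = sum(pred == "stimulus" & truth == "stimulus"),
                               fn = sum(pred == "control" & truth == "stimulus"),
                               tn = sum(pred == "control" & truth == "control"),
                               fp = sum(pred == "stimulus" & truth == "control"))
  }
  met <- function(name) vapply(folds, `[[`, 0, name)
  structure(list(
    folds = folds,
    accuracy = met("accuracy"),
    sensitivity = met("sensitivity"),
    specificity = met("specificity"),
    mean = c(accuracy = mean(met("accuracy")),
             sensitivity = mean(met("sensitivity")),
             specificity = mean(met("specificity"))),
    sd = c(accuracy = stats::sd(met("accuracy")),
           sensitivity = stats::sd(met("sensitivity")),
           specificity = stats::sd(met("specificity"))),
    cv = cv, svm = svm
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds: accuracy %.4f +- %.4f, sensitivity %.4f, specificity %.4f\n",
              length(x$folds), x$mean["accuracy"], x$sd["accuracy"],
              x$mean["sensitivity"], x$mean["specificity"]))
  invisible(x)
}

#' Subject-specific cross-validated evaluation
#'
#' Runs the same protocol within each subject's own data and reports
#' per-subject metrics plus their mean. Subjects lacking a class are skipped
#' with a warning.
#'
#' @param datasets named list, one [assemble_dataset()]-style list per
#'   subject.
#' @param cv a [cv_config()].
#' @param svm a [svm_config()].
#' @return list with `per_subject` (list of `cv_result`s), `mean_accuracy`,
#'   `n_subjects`.
#' @export
subject_specific_eval <- function(datasets, cv = cv_config(), svm = svm_config()) {
  results <- list()
  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    if (length(unique(ds$y)) < 2) {
      warning(sprintf("subject %s lacks a class; skipped", nm))
      next
    }
    results[[nm]] <- crossval_train_eval(ds$x, ds$y, cv, svm)
  }
  list(per_subject = results,
       mean_accuracy = mean(vapply(results, function(r) r$mean["accuracy"], 0)),
       n_subjects = length(results))
}

#' Welch comparison of fold accuracies
#'
#' Compares two cross-validation runs by a Welch t-test on their fold
#' accuracies and reports the mean difference in percentage points
#' (`a` minus `b`).
#'
#' @param metrics_a,metrics_b `cv_result`s.
#' @return list with `test` (a `welch_test`) and `delta_pp`.
#' @export
compare_fold_accuracies <- function(metrics_a, metrics_b) {
  stopifnot(inherits(metrics_a, "cv_result"), inherits(metrics_b, "cv_result"))
  wt <- welch_ttest(metrics_a$accuracy, metrics_b$accuracy)
  list(test = wt, delta_pp = 100 * (mean(metrics_a$accuracy) -
                                    mean(metrics_b$accuracy)))
}

#' Detection report over methods, conditions and modalities
#'
#' Collects cross-validation results into the standard grid (feature method
#' x condition x modality x metric), computes audio-visual minus visual-only
#' deltas in percentage points with fold-wise Welch tests, and flags the
#' highest-accuracy method per condition/modality column.
#'
#' @param runs nested list: `runs[[method]][[condition]][[modality]]` is a
#'   `cv_result`. Methods are typically VAR, PSD, DWT, DVP.
#' @return object of class `detection_report`: list with `table`
#'   (data.frame), `deltas` (data.frame with Welch p values), `best`
#'   (data.frame of flagged methods).
#' @export
build_report <- function(runs) {
  rows <- list()
  for (m in names(runs)) for (cond in names(runs[[m]]))
    for (mod in names(runs[[m]][[cond]])) {
      r <- runs[[m]][[cond]][[mod]]
      rows[[length(rows) + 1]] <- data.frame(
        method = m, condition = cond, modality = mod,
        accuracy = 100 * r$mean["accuracy"],
        accuracy_sd = 100 * r$sd["accuracy"],
        specificity = 100 * r$mean["specificity"],
        sensitivity = 100 * r$mean["sensitivity"],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  tab <- do.call(rbind, rows)
  deltas <- list()
  for (m in names(runs)) for (cond in names(runs[[m]])) {
    mods <- runs[[m]][[cond]]
    if (all(c("visual_only", "audio_visual") %in% names(mods))) {
      cmpr <- compare_fold_accuracies(mods$audio_visual, mods$visual_only)
      deltas[[length(deltas) + 1]] <- data.frame(
        method = m, condition = cond, delta_pp = cmpr$delta_pp,
        t = cmpr$test$t, p = cmpr$test$p,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  deltas <- if (length(deltas)) do.call(rbind, deltas) else NULL
  best <- do.call(rbind, lapply(split(tab, paste(tab$condition, tab$modality)),
    function(g) g[which.max(g$accuracy), c("method", "condition", "modality",
                                           "accuracy")]))
  rownames(best) <- NULL
  structure(list(table = tab, deltas = deltas, best = best),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat("Detection report (values in %):\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$deltas)) {
    cat("\nAudio-visual minus visual-only deltas (percentage points):\n")
    print(x$deltas, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a detection report to disk
#'
#' @param report a `detection_report`.
#' @param prefix path prefix; writes `<prefix>.json` and `<prefix>.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_report <- function(report, prefix) {
  jsonlite::write_json(list(table = report$table, deltas = report$deltas,
                            best = report$best),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(report$table, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
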