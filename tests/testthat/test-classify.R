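mk_fm <- function(mat, labels, names = paste0("f", seq_len(ncol(mat)))) {
  structure(list(matrix = as.matrix(mat), feature_names = names,
                 labels = labels, method = "VAR", normalization = "none"),
            class = "feature_matrix")
}

test_that("assemble_dataset balances classes to the pooled design counts", {
  set.seed(1)
  stim <- mk_fm(matrix(rnorm(304 * 5), 304), rep("explosion", 304))
  ctrl <- mk_fm(matrix(rnorm(1280 * 5), 1280), rep("control", 1280))
  ds <- assemble_dataset(stim, ctrl, balance = TRUE, seed = 2)
  expect_equal(as.integer(table(ds$y)), c(304L, 304L))
  ds2 <- assemble_dataset(stim, ctrl, balance = FALSE)
  expect_equal(nrow(ds2$x), 1584L)
  expect_equal(nlevels(ds2$y), 2L)
  empty <- mk_fm(matrix(0, 0, 5), character())
  expect_error(assemble_dataset(empty, ctrl), "nonempty")
})

test_that("well-separated clouds are classified perfectly", {
  set.seed(3)
  x <- rbind(matrix(rnorm(60 * 4, mean = 10), 60),
             matrix(rnorm(60 * 4, mean = -10), 60))
  y <- factor(rep(c("stimulus", "control"), each = 60),
              levels = c("control", "stimulus"))
  res <- crossval_train_eval(x, y, cv_config(seed = 4))
  expect_equal(unname(res$mean["accuracy"]), 1)
  expect_equal(unname(res$mean["sensitivity"]), 1)
  expect_equal(unname(res$mean["specificity"]), 1)
})

test_that("permuted labels score inside the 99% chance band", {
  set.seed(5)
  n <- 600
  x <- matrix(rnorm(n * 10), n)
  y <- factor(sample(rep(c("stimulus", "control"), n / 2)),
              levels = c("control", "stimulus"))
  res <- crossval_train_eval(x, y, cv_config(k = 10, seed = 6))
  n_test <- n * 0.2
  band <- qbinom(c(0.005, 0.995), n_test, 0.5) / n_test
  expect_gte(unname(res$mean["accuracy"]), band[1])
  expect_lte(unname(res$mean["accuracy"]), band[2])
})

test_that("fold metrics satisfy the confusion-count identities", {
  fm <- oddballerp:::fold_metrics(tp = 9, fn = 1, tn = 8, fp = 2)
  expect_equal(fm$sensitivity, 0.9)
  expect_equal(fm$specificity, 0.8)
  expect_equal(fm$accuracy, 0.85)
  # identities hold on every fold of a real run
  set.seed(7)
  x <- matrix(rnorm(80 * 3), 80)
  y <- factor(rep(c("stimulus", "control"), 40), levels = c("control", "stimulus"))
  res <- crossval_train_eval(x, y, cv_config(k = 5, seed = 8))
  for (f in res$folds) {
    expect_equal(f$accuracy, (f$tp + f$tn) / (f$tp + f$tn + f$fp + f$fn))
    expect_equal(f$tp + f$fn + f$tn + f$fp, 16)
  }
})

test_that("accuracy is invariant under monotone rescaling of one feature", {
  set.seed(9)
  x <- rbind(matrix(rnorm(40 * 3, mean = 2), 40),
             matrix(rnorm(40 * 3, mean = -2), 40))
  y <- factor(rep(c("stimulus", "control"), each = 40),
              levels = c("control", "stimulus"))
  r1 <- crossval_train_eval(x, y, cv_config(k = 5, seed = 10))
  x2 <- x; x2[, 2] <- 10 * x2[, 2] + 3
  r2 <- crossval_train_eval(x2, y, cv_config(k = 5, seed = 10))
  expect_equal(r1$mean["accuracy"], r2$mean["accuracy"], tolerance = 0.05)
})

test_that("fold-accuracy comparisons report deltas in percentage points", {
  mk_cv <- function(acc) structure(list(accuracy = acc, folds = list()),
                                   class = "cv_result")
  same <- compare_fold_accuracies(mk_cv(c(0.9, 0.9, 0.9)), mk_cv(c(0.9, 0.9, 0.9)))
  expect_equal(same$test$t, 0); expect_equal(same$test$p, 1)
  expect_equal(same$delta_pp, 0)
  d <- compare_fold_accuracies(mk_cv(c(0.9, 0.9, 0.9)), mk_cv(c(0.8, 0.8, 0.8)))
  expect_equal(d$delta_pp, 10)
  # agrees with the package t-test on arbitrary fold vectors
  set.seed(11)
  a <- runif(10, 0.7, 0.9); b <- runif(10, 0.6, 0.8)
  cmp <- compare_fold_accuracies(mk_cv(a), mk_cv(b))
  ref <- welch_ttest(a, b)
  expect_equal(cmp$test$t, ref$t)
  expect_equal(cmp$test$p, ref$p)
})

test_that("subject-specific evaluation preserves identity and counts", {
  set.seed(12)
  x <- rbind(matrix(rnorm(30 * 3, 5), 30), matrix(rnorm(30 * 3, -5), 30))
  y <- factor(rep(c("stimulus", "control"), each = 30),
              levels = c("control", "stimulus"))
  ds <- list(x = x, y = y)
  out <- subject_specific_eval(list(S1 = ds, S2 = ds),
                               cv_config(k = 3, seed = 13))
  expect_equal(out$n_subjects, 2L)
  expect_equal(out$per_subject$S1$mean, out$per_subject$S2$mean)
  expect_equal(out$mean_accuracy, 1)
  bad <- list(x = x[1:30, ], y = droplevels(y[1:30]))
  expect_warning(out2 <- subject_specific_eval(list(S1 = ds, S2 = bad),
                                               cv_config(k = 3, seed = 13)),
                 "lacks a class")
  expect_equal(out2$n_subjects, 1L)
})

test_that("detection reports are complete, consistent and flag the argmax", {
  mk_cv <- function(acc) structure(
    list(accuracy = acc, folds = list(),
         mean = c(accuracy = mean(acc), sensitivity = mean(acc),
                  specificity = mean(acc)),
         sd = c(accuracy = sd(acc), sensitivity = sd(acc),
                specificity = sd(acc))),
    class = "cv_result")
  runs <- list()
  accs <- list(VAR = c(0.70, 0.72), DVP = c(0.90, 0.88))
  for (m in names(accs)) for (cond in c("explosion", "burning"))
    for (mod in c("visual_only", "audio_visual")) {
      shift <- if (mod == "audio_visual") 0.02 else 0
      runs[[m]][[cond]][[mod]] <- mk_cv(accs[[m]] + shift)
    }
  rep_ <- build_report(runs)
  expect_equal(nrow(rep_$table), 2 * 2 * 2)
  # delta equals the difference of stored means
  for (i in seq_len(nrow(rep_$deltas))) {
    row <- rep_$deltas[i, ]
    sub <- rep_$table[rep_$table$method == row$method &
                      rep_$table$condition == row$condition, ]
    expect_equal(row$delta_pp,
                 sub$accuracy[sub$modality == "audio_visual"] -
                 sub$accuracy[sub$modality == "visual_only"],
                 tolerance = 1e-9)
  }
  expect_true(all(rep_$best$method == "DVP"))
})
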