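#' Subject-level condition average
#'
#' Averages a fixed number of kept trials of one condition (38 by default):
#' either a seeded random selection or the first `n_select` kept trials. The
#' indices of the trials used are returned as a manifest.
#'
#' @param es an `epoch_set` (baseline-corrected, after rejection).
#' @param condition condition to average.
#' @param n_select number of trials entering the average (default 38).
#' @param select `"random"` (seeded) or `"first"`.
#' @param seed seed for the random selection.
#' @return object of class `erp_average`: list with `mean` (channels x
#'   samples), `channels`, `sampling_rate`, `window`, `condition`,
#'   `n_trials`, `trials_used`, `subject_id`.
#' @export
subject_average <- function(es, condition, n_select = 38,
                            select = c("random", "first"), seed = 1) {
  stopifnot(inherits(es, "epoch_set"))
  select <- match.arg(select)
  idx <- which(es$kept & es$conditions == condition)
  if (length(idx) < n_select)
    stop(sprintf("condition '%s' has only %d kept trials, %d required",
                 condition, length(idx), n_select), call. = FALSE)
  used <- if (select == "first") idx[seq_len(n_select)]
          else sort(with_seed(seed, sample(idx, n_select)))
  m <- apply(es$data[used, , , drop = FALSE], c(2, 3), mean)
  dimnames(m) <- list(es$channels, NULL)
  structure(list(mean = m, channels = es$channels,
                 sampling_rate = es$sampling_rate, window = es$window,
                 condition = condition, n_trials = n_select,
                 trials_used = used, subject_id = es$subject_id),
            class = "erp_average")
}

#' Pool control trials across subjects
#'
#' Selects `n_per_subject` kept control trials per subject (seeded) and pools
#' them into one epoch set; 8 subjects x 38 trials gives the 304-trial pooled
#' control ensemble.
#'
#' @param epoch_sets list of per-subject `epoch_set`s.
#' @param n_per_subject control trials per subject (default 38).
#' @param seed selection seed.
#' @return an `epoch_set` holding the pooled control trials, with a
#'   `subject` vector marking provenance.
#' @export
pool_control_trials <- function(epoch_sets, n_per_subject = 38, seed = 1) {
  stopifnot(length(epoch_sets) >= 1)
  sds <- derive_seeds(seed, length(epoch_sets))
  picked <- vector("list", length(epoch_sets))
  for (i in seq_along(epoch_sets)) {
    es <- epoch_sets[[i]]
    idx <- which(es$kept & es$conditions == "control")
    if (length(idx) < n_per_subject)
      stop(sprintf("subject %d has only %d kept control trials, %d required",
                   i, length(idx), n_per_subject), call. = FALSE)
    used <- sort(with_seed(sds[i], sample(idx, n_per_subject)))
    sub <- es
    sub$data <- es$data[used, , , drop = FALSE]
    sub$conditions <- es$conditions[used]
    sub$kept <- rep(TRUE, n_per_subject)
    sub$reject_reason <- rep(NA_character_, n_per_subject)
    picked[[i]] <- sub
  }
  ref <- picked[[1]]
  ref$data <- do.call(abind_trials, lapply(picked, `[[`, "data"))
  ref$conditions <- unlist(lapply(picked, `[[`, "conditions"))
  ref$kept <- rep(TRUE, length(ref$conditions))
  ref$reject_reason <- rep(NA_character_, length(ref$conditions))
  ref$subject <- rep(vapply(epoch_sets, function(e) e$subject_id %||% NA_character_, ""),
                     each = n_per_subject)
  ref$subject_id <- "pooled"
  ref
}

# bind trial arrays along dim 1
abind_trials <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, dim = c(total, d[2], d[3]),
               dimnames = list(NULL, dimnames(parts[[1]])[[2]], NULL))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Grand average across subjects
#'
#' Pointwise mean and across-subject standard deviation of subject-level
#' averages of one condition.
#'
#' @param subject_averages list of `erp_average`s (same condition, channels
#'   and window).
#' @return object of class `grand_average`: list with `mean`, `sd` (channels
#'   x samples), `n_subjects`, `channels`, `sampling_rate`, `window`,
#'   `condition`.
#' @export
grand_average <- function(subject_averages) {
  stopifnot(length(subject_averages) >= 2,
            all(vapply(subject_averages, inherits, TRUE, "erp_average")))
  ref <- subject_averages[[1]]
  for (sa in subject_averages[-1]) {
    if (!identical(sa$channels, ref$channels))
      stop("subject averages have mismatched channel sets", call. = FALSE)
    if (!identical(dim(sa$mean), dim(ref$mean)))
      stop("subject averages have mismatched dimensions", call. = FALSE)
  }
  stack <- array(unlist(lapply(subject_averages, `[[`, "mean")),
                 dim = c(dim(ref$mean), length(subject_averages)))
  m <- apply(stack, c(1, 2), mean)
  s <- apply(stack, c(1, 2), stats::sd)
  dimnames(m) <- dimnames(s) <- list(ref$channels, NULL)
  structure(list(mean = m, sd = s, n_subjects = length(subject_averages),
                 channels = ref$channels, sampling_rate = ref$sampling_rate,
                 window = ref$window, condition = ref$condition),
            class = "grand_average")
}

#' @export
print.grand_average <- function(x, ...) {
  cat(sprintf("<grand_average> '%s': %d subjects, %d channels x %d samples\n",
              x$condition, x$n_subjects, nrow(x$mean), ncol(x$mean)))
  invisible(x)
}
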