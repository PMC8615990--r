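#' Time-resolved cross-validated decoding of near vs. far
#'
#' Trains an independent shrinkage-LDA classifier on the single-sample
#' channel patterns at every time point of the analysis window and evaluates
#' it under cross-validation: with `cv = "subject"` (leave-one-subject-out,
#' the default) each fold holds all trials of one subject and the classifier
#' is trained on the pooled trials of the remaining subjects; with
#' `cv = "trial"` (leave-one-trial-out, for single-subject data) each fold is
#' one trial. The chance rate for the two balanced conditions is 0.5.
#'
#' @param ep An `eeg_epochs`.
#' @param cv `"subject"` or `"trial"`.
#' @param shrinkage `"auto"` (analytic, per training split) or a fixed value
#'   in `[0, 1]`; see [fit_lda()].
#' @param window_ms Analysis window, half-open `[start, end)` ms; the default
#'   -1200..1000 ms spans prime onset to approximately movement onset.
#' @return An `accuracy_timecourse`: tibble with `time_ms`, `accuracy`
#'   (mean across folds), `se` (standard error across folds), and attributes
#'   `n_folds`, `cv_scheme`, `fold_accuracy` (time x fold matrix).
#' @examples
#' \donttest{
#' cfg <- study_config(n_subjects = 3, n_trials_per_condition = 10,
#'                     n_channels = 8, effects = list(), seed = 2,
#'                     artifact_rate = 0)
#' ep <- preprocess_study(simulate_study(cfg), min_epochs = 5)
#' acc <- decode_timecourse(ep, window_ms = c(-100, 100))
#' head(acc)
#' }
#' @export
decode_timecourse <- function(ep, cv = c("subject", "trial"),
                              shrinkage = "auto",
                              window_ms = c(-1200, 1000)) {
  stopifnot(inherits(ep, "eeg_epochs"))
  cv <- match.arg(cv)
  fold <- make_folds(ep, cv)
  idx <- window_indices(ep$times_ms, window_ms)
  shrink <- if (identical(shrinkage, "auto")) -1 else {
    assert_scalar_number(shrinkage, "shrinkage")
    if (shrinkage < 0 || shrinkage > 1) {
      stop_invalid("`shrinkage` must be in [0, 1] or \"auto\".")
    }
    shrinkage
  }
  fold_acc <- cpp_cv_accuracy(ep$data[, , idx, drop = FALSE],
                              as.numeric(ep$labels), fold, shrink)
  n_folds <- ncol(fold_acc)
  res <- tibble(
    time_ms = ep$times_ms[idx],
    accuracy = rowMeans(fold_acc),
    se = apply(fold_acc, 1, sd) / sqrt(n_folds)
  )
  structure(res, class = c("accuracy_timecourse", class(res)),
            n_folds = n_folds, cv_scheme = cv, shrinkage = shrinkage,
            fold_accuracy = fold_acc)
}

# Fold ids (1..F). Under leave-one-subject-out every fold must contain both
# classes, otherwise some training split cannot be stratified.
make_folds <- function(ep, cv) {
  n <- length(ep$labels)
  if (cv == "trial") {
    if (n < 2) stop_invalid("leave-one-trial-out needs >= 2 trials.")
    return(seq_len(n))
  }
  subj <- factor(ep$subjects, levels = unique(ep$subjects))
  if (nlevels(subj) < 2) {
    stop_invalid(paste0("leave-one-subject-out needs >= 2 subjects; ",
                        "use cv = \"trial\" for single-subject data."))
  }
  for (s in levels(subj)) {
    if (length(unique(ep$labels[subj == s])) < 2) {
      abort(sprintf(paste0("subject %s has trials of only one class; ",
                           "rebalance conditions before decoding"), s),
            class = "erpdecode_unbalanced_fold")
    }
  }
  as.integer(subj)
}

#' @export
print.accuracy_timecourse <- function(x, ...) {
  cat(sprintf(
    "<accuracy_timecourse> %d time points (%g..%g ms), %d folds (%s CV)\n",
    nrow(x), min(x$time_ms), max(x$time_ms), attr(x, "n_folds"),
    attr(x, "cv_scheme")))
  cat(sprintf("  mean accuracy %.3f, peak %.3f at %g ms\n",
              mean(x$accuracy), max(x$accuracy),
              x$time_ms[which.max(x$accuracy)]))
  invisible(x)
}

#' @export
glance.accuracy_timecourse <- function(x, ...) {
  tibble(mean_accuracy = mean(x$accuracy),
         peak_accuracy = max(x$accuracy),
         peak_time_ms = x$time_ms[which.max(x$accuracy)],
         n_times = nrow(x),
         n_folds = attr(x, "n_folds"),
         cv_scheme = attr(x, "cv_scheme"))
}
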