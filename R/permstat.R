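#' Permutation null distribution of the accuracy time course
#'
#' Builds the empirical null of the cross-validated decoding accuracy by
#' repeatedly shuffling condition labels across the pooled trial set (the
#' trial-to-subject assignment, and hence the fold structure, is kept fixed)
#' and re-running the full time-resolved CV decode for each shuffle.
#'
#' @param ep An `eeg_epochs`.
#' @param n_perm Number of label shuffles (>= 1; a warning is issued below
#'   100, where upper percentiles are unstable).
#' @param cv,shrinkage,window_ms As in [decode_timecourse()].
#' @param seed Seed for the label shuffles; the null is deterministic given
#'   the seed.
#' @param permutations Optional explicit `n_trials x n_perm` matrix of
#'   label assignments (values `+1`/`-1`), e.g. the exhaustive enumeration
#'   for a tiny trial set; overrides `n_perm` and `seed`.
#' @return A `perm_null`: list with `values` (`n_perm x n_times` accuracy
#'   matrix), `times_ms`, `n_perm`, `seed`.
#' @export
permutation_null <- function(ep, n_perm = 500, cv = c("subject", "trial"),
                             shrinkage = "auto", window_ms = c(-1200, 1000),
                             seed = 1, permutations = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"))
  cv <- match.arg(cv)
  if (length(unique(ep$labels)) < 2) {
    stop_invalid("labels are degenerate (single class).")
  }
  if (is.null(permutations)) {
    assert_scalar_number(n_perm, "n_perm")
    if (n_perm < 1) stop_invalid("`n_perm` must be >= 1.")
    if (n_perm < 100) {
      warn(sprintf("n_perm = %d is low; upper percentiles will be unstable.",
                   n_perm))
    }
    permutations <- with_seed(seed, vapply(
      seq_len(n_perm), function(i) sample(ep$labels),
      numeric(length(ep$labels))))
  } else {
    permutations <- as.matrix(permutations)
    if (nrow(permutations) != length(ep$labels) ||
        !all(permutations %in% c(-1, 1))) {
      stop_invalid("`permutations` must be an n_trials x n_perm +1/-1 matrix.")
    }
    n_perm <- ncol(permutations)
  }
  fold <- make_folds(ep, cv)
  idx <- window_indices(ep$times_ms, window_ms)
  shrink <- if (identical(shrinkage, "auto")) -1 else shrinkage
  values <- cpp_perm_null(ep$data[, , idx, drop = FALSE], permutations,
                          fold, shrink)
  structure(list(values = values, times_ms = ep$times_ms[idx],
                 n_perm = n_perm, seed = seed, cv_scheme = cv),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> %d permutations x %d time points (%s CV)\n",
              x$n_perm, length(x$times_ms), x$cv_scheme))
  invisible(x)
}

#' Per-time-point significance of an accuracy time course
#'
#' A time point is flagged when the observed accuracy exceeds the requested
#' percentile of its empirical null (default 99th, i.e. p < 0.01) AND
#' exceeds an absolute chance threshold (default 60%, a conservative margin
#' over the 50% guessing rate of two balanced conditions). Each criterion
#' can be disabled with `NULL` (e.g. for calibration studies). Percentiles
#' use the empirical order statistic with linear interpolation.
#'
#' @param obs An `accuracy_timecourse` from [decode_timecourse()].
#' @param null A `perm_null` sharing the time axis.
#' @param percentile Null percentile in (0, 100], or `NULL` to disable.
#' @param chance_threshold Absolute accuracy floor in (0, 1), or `NULL` to
#'   disable.
#' @return A tibble with `time_ms`, `accuracy`, `null_threshold`,
#'   `significant`.
#' @export
significant_mask <- function(obs, null, percentile = 99,
                             chance_threshold = 0.60) {
  stopifnot(inherits(null, "perm_null"))
  if (!isTRUE(all.equal(obs$time_ms, null$times_ms))) {
    stop_invalid("`obs` and `null` must share the time axis.")
  }
  keep <- rep(TRUE, nrow(obs))
  thr <- rep(NA_real_, nrow(obs))
  if (!is.null(percentile)) {
    thr <- apply(null$values, 2, quantile, probs = percentile / 100,
                 names = FALSE, type = 7)
    keep <- keep & (obs$accuracy > thr)
  }
  if (!is.null(chance_threshold)) {
    keep <- keep & (obs$accuracy > chance_threshold)
  }
  tibble(time_ms = obs$time_ms, accuracy = obs$accuracy,
         null_threshold = thr, significant = keep)
}

#' Contiguous significant intervals
#'
#' Converts a per-time-point significance mask into maximal runs of
#' consecutive significant samples, expressed as half-open intervals
#' `[start_ms, end_ms)` (the end is one sample step past the last
#' significant sample). Runs shorter than `min_duration_ms` are discarded.
#'
#' @param mask Either the tibble returned by [significant_mask()] or a
#'   logical vector (then `times_ms` is required).
#' @param times_ms Time axis matching a logical-vector `mask`.
#' @param min_duration_ms Minimal interval duration in ms (default 0).
#' @return A tibble of intervals, sorted by start time, with columns
#'   `start_ms`, `end_ms`, `n_samples`, `peak_accuracy`, `mean_accuracy`
#'   (accuracy columns are `NA` when `mask` carries no accuracies).
#' @export
extract_intervals <- function(mask, times_ms = NULL, min_duration_ms = 0) {
  acc <- NULL
  if (is.data.frame(mask)) {
    times_ms <- mask$time_ms
    acc <- mask$accuracy
    mask <- mask$significant
  }
  if (is.null(times_ms) || length(times_ms) != length(mask)) {
    stop_invalid("`mask` and `times_ms` must be aligned.")
  }
  empty <- tibble(start_ms = numeric(), end_ms = numeric(),
                  n_samples = integer(), peak_accuracy = numeric(),
                  mean_accuracy = numeric())
  if (!any(mask)) return(empty)
  dt <- if (length(times_ms) > 1) times_ms[2] - times_ms[1] else NA_real_
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    tibble(start_ms = times_ms[starts[k]],
           end_ms = times_ms[ends[k]] + dt,
           n_samples = length(i),
           peak_accuracy = if (is.null(acc)) NA_real_ else max(acc[i]),
           mean_accuracy = if (is.null(acc)) NA_real_ else mean(acc[i]))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$end_ms - out$start_ms >= min_duration_ms - 1e-9, ,
             drop = FALSE]
  out[order(out$start_ms), , drop = FALSE]
}
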