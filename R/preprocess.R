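#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filters continuous data with an order-`order` Butterworth design
#' applied forward and backward (`signal::filtfilt`), i.e. zero-phase with a
#' squared magnitude response. Edge transients are controlled by reflection
#' padding (the signal is mirrored at both ends before filtering and the pads
#' discarded). The default 1-40 Hz band removes DC and slow drifts and
#' attenuates line-frequency and muscle activity.
#'
#' @param x An `eeg_recording`, or a `channels x samples` matrix, or a
#'   numeric vector (with `sfreq_hz` supplied).
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < sfreq/2`.
#' @param order Butterworth order per band edge (2 = the classic
#'   second-order design; forward-backward application doubles the
#'   effective rolloff).
#' @param sfreq_hz Sampling rate, required for matrix/vector input.
#' @return Same type as `x`.
#' @export
bandpass <- function(x, low_hz = 1, high_hz = 40, order = 2,
                     sfreq_hz = NULL) {
  UseMethod("bandpass")
}

#' @export
bandpass.eeg_recording <- function(x, low_hz = 1, high_hz = 40, order = 2,
                                   sfreq_hz = NULL) {
  x$data <- bandpass_matrix(x$data, low_hz, high_hz, order, x$sfreq_hz)
  x
}

#' @export
bandpass.matrix <- function(x, low_hz = 1, high_hz = 40, order = 2,
                            sfreq_hz = NULL) {
  if (is.null(sfreq_hz)) stop_invalid("`sfreq_hz` is required for matrices.")
  bandpass_matrix(x, low_hz, high_hz, order, sfreq_hz)
}

#' @export
bandpass.numeric <- function(x, low_hz = 1, high_hz = 40, order = 2,
                             sfreq_hz = NULL) {
  drop(bandpass.matrix(matrix(x, nrow = 1), low_hz, high_hz, order,
                       sfreq_hz))
}

bandpass_matrix <- function(data, low_hz, high_hz, order, sfreq_hz) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < sfreq_hz / 2)) {
    stop_invalid("need 0 < low_hz < high_hz < sfreq_hz / 2.")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (sfreq_hz / 2),
                       type = "pass")
  n <- ncol(data)
  pad <- min(n - 1L, ceiling(3 * sfreq_hz / low_hz))
  out <- data
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    xp <- c(2 * x[1] - rev(x[seq(2, pad + 1)]), x,
            2 * x[n] - rev(x[seq(n - pad, n - 1)]))
    y <- signal::filtfilt(bf, xp)
    out[ch, ] <- y[pad + seq_len(n)]
  }
  out
}

#' Common average reference
#'
#' Re-references every channel to the instantaneous mean across channels, so
#' the channel mean at each sample is zero. A linear projection; commutes
#' with baseline correction.
#'
#' @param x An `eeg_recording`, `eeg_epochs` or `channels x samples` matrix.
#' @return Same type as `x`.
#' @export
common_average <- function(x) UseMethod("common_average")

#' @export
common_average.eeg_recording <- function(x) {
  if (nrow(x$data) < 2) stop_invalid("common average needs >= 2 channels.")
  x$data <- sweep(x$data, 2, colMeans(x$data))
  x
}

#' @export
common_average.matrix <- function(x) {
  if (nrow(x) < 2) stop_invalid("common average needs >= 2 channels.")
  sweep(x, 2, colMeans(x))
}

#' @export
common_average.eeg_epochs <- function(x) {
  if (dim(x$data)[2] < 2) stop_invalid("common average needs >= 2 channels.")
  x$data <- sweep(x$data, c(1, 3), apply(x$data, c(1, 3), mean))
  x
}

#' Segment a continuous recording into target-locked epochs
#'
#' Cuts one epoch per event around target onset. By default only go trials
#' enter the epoch set (the decoding analyses are defined on go trials);
#' events whose epoch would extend past the recording edge are dropped with
#' a warning. Labels encode near = +1 and far = -1.
#'
#' @param raw An `eeg_recording`.
#' @param events Event tibble with `onset_sample`, `condition`
#'   (`"near"`/`"far"`), `trial_type` (`"go"`/`"nogo"`), optional `rt_ms`.
#' @param tmin_ms,tmax_ms Epoch extent in ms around target onset; the epoch
#'   holds `round((tmax - tmin)/1000 * sfreq)` samples covering
#'   `[tmin, tmax)`.
#' @param go_only Keep only go trials (default `TRUE`).
#' @return An `eeg_epochs`.
#' @export
epoch_trials <- function(raw, events, tmin_ms = -1500, tmax_ms = 1500,
                         go_only = TRUE) {
  stopifnot(inherits(raw, "eeg_recording"))
  if (any(diff(events$onset_sample) <= 0)) {
    stop_invalid("event onsets must be strictly increasing.")
  }
  if (go_only) events <- events[events$trial_type == "go", , drop = FALSE]
  if (nrow(events) == 0) stop_invalid("no events to epoch.")
  sf <- raw$sfreq_hz
  n_samp <- round((tmax_ms - tmin_ms) / 1000 * sf)
  offset <- round(tmin_ms / 1000 * sf)
  first <- events$onset_sample + offset
  ok <- first >= 1 & (first + n_samp - 1) <= ncol(raw$data)
  if (any(!ok)) {
    warn(sprintf("dropping %d event(s) too close to the recording edge (%s)",
                 sum(!ok), raw$subject))
    events <- events[ok, , drop = FALSE]
    first <- first[ok]
    if (nrow(events) == 0) stop_invalid("all events fell outside the recording.")
  }
  n_tr <- nrow(events)
  data <- array(0, dim = c(n_tr, nrow(raw$data), n_samp))
  for (k in seq_len(n_tr)) {
    data[k, , ] <- raw$data[, first[k] + seq_len(n_samp) - 1L]
  }
  times <- (offset + seq_len(n_samp) - 1L) / sf * 1000
  labels <- ifelse(events$condition == "near", 1L, -1L)
  eeg_epochs(data, times, labels, rep(raw$subject, n_tr), sf,
             channels = raw$channels,
             rt_ms = if ("rt_ms" %in% names(events)) events$rt_ms else NULL)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window. The
#' default window is the 300 ms preceding prime onset (-1500..-1200 ms).
#' Idempotent; commutes with common-average referencing.
#'
#' @param ep An `eeg_epochs`.
#' @param window_ms Half-open baseline window `[start, end)` in ms.
#' @return The corrected `eeg_epochs`.
#' @export
baseline_correct <- function(ep, window_ms = c(-1500, -1200)) {
  stopifnot(inherits(ep, "eeg_epochs"))
  idx <- window_indices(ep$times_ms, window_ms)
  base <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- sweep(ep$data, c(1, 2), base)
  ep
}

#' Reject high-amplitude epochs
#'
#' Removes trials whose peak-to-peak amplitude on any channel exceeds a
#' threshold — a deterministic stand-in for visual/ICA-based artifact
#' cleaning. Errors if any subject is left with fewer than `min_epochs`
#' trials in either condition, naming the subject and condition.
#'
#' @param ep An `eeg_epochs`.
#' @param peak_to_peak_uv Rejection threshold in µV (default 150).
#' @param min_epochs Minimal surviving trials per subject and condition.
#' @return The cleaned `eeg_epochs`, with rejection bookkeeping in
#'   `$rejected`.
#' @export
reject_artifacts <- function(ep, peak_to_peak_uv = 150, min_epochs = 40) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (peak_to_peak_uv <= 0) stop_invalid("`peak_to_peak_uv` must be > 0.")
  ptp <- apply(ep$data, 1, function(tr) max(apply(tr, 1, function(ch)
    max(ch) - min(ch))))
  bad <- which(ptp > peak_to_peak_uv)
  rejected <- tibble(subject = ep$subjects[bad], trial = as.integer(bad),
                     reason = sprintf("ptp %.0f uV > %.0f uV",
                                      ptp[bad], peak_to_peak_uv))
  out <- if (length(bad)) subset_epochs(ep, trials = -bad) else ep
  out$rejected <- dplyr::bind_rows(ep$rejected, rejected)
  counts <- epoch_counts(out)
  short <- counts[counts$n < min_epochs, , drop = FALSE]
  if (nrow(short)) {
    abort(sprintf(
      "too few clean epochs: %s",
      paste(sprintf("subject %s, %s condition: %d < %d", short$subject,
                    short$condition, short$n, min_epochs), collapse = "; ")),
      class = "erpdecode_too_few_epochs")
  }
  out
}

#' Full preprocessing pipeline for a simulated study
#'
#' Band-pass filters each subject's continuous recording (applied before
#' epoching to keep filter transients away from the analysis window),
#' re-references to the common average, segments go trials around target
#' onset, baseline-corrects on the pre-prime window, rejects high-amplitude
#' epochs, and concatenates subjects into one epoch set.
#'
#' @param study A `synthetic_study`.
#' @param low_hz,high_hz,order Band-pass settings (see [bandpass()]).
#' @param tmin_ms,tmax_ms Epoch extent (defaults from the study config).
#' @param baseline_ms Baseline window.
#' @param peak_to_peak_uv,min_epochs Artifact rejection settings (see
#'   [reject_artifacts()]).
#' @return An `eeg_epochs` pooling all subjects.
#' @export
preprocess_study <- function(study, low_hz = 1, high_hz = 40, order = 2,
                             tmin_ms = NULL, tmax_ms = NULL,
                             baseline_ms = c(-1500, -1200),
                             peak_to_peak_uv = 150, min_epochs = 40) {
  stopifnot(inherits(study, "synthetic_study"))
  tmin_ms <- tmin_ms %||% study$config$epoch_ms[1]
  tmax_ms <- tmax_ms %||% study$config$epoch_ms[2]
  per_subject <- lapply(seq_along(study$recordings), function(s) {
    study$recordings[[s]] |>
      bandpass(low_hz, high_hz, order) |>
      common_average() |>
      epoch_trials(study$events[[s]], tmin_ms, tmax_ms) |>
      baseline_correct(baseline_ms) |>
      reject_artifacts(peak_to_peak_uv, min_epochs)
  })
  bind_epochs(per_subject)
}

#' Concatenate epoch sets along the trial dimension
#'
#' @param eps List of `eeg_epochs` sharing channels and time axis.
#' @return One pooled `eeg_epochs`.
#' @export
bind_epochs <- function(eps) {
  stopifnot(length(eps) >= 1, all(vapply(eps, inherits, TRUE, "eeg_epochs")))
  t0 <- eps[[1]]$times_ms
  for (e in eps) {
    if (!isTRUE(all.equal(e$times_ms, t0))) {
      stop_invalid("epoch sets must share the time axis.")
    }
  }
  data <- do.call(abind3, lapply(eps, `[[`, "data"))
  eeg_epochs(data, t0,
             unlist(lapply(eps, `[[`, "labels")),
             unlist(lapply(eps, `[[`, "subjects")),
             eps[[1]]$sfreq_hz, eps[[1]]$channels,
             rt_ms = {
               rts <- lapply(eps, `[[`, "rt_ms")
               if (all(vapply(rts, is.null, TRUE))) NULL else
                 unlist(lapply(seq_along(eps), function(i)
                   rts[[i]] %||% rep(NA_real_, dim(eps[[i]]$data)[1])))
             },
             rejected = dplyr::bind_rows(lapply(eps, `[[`, "rejected")))
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 1L))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
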