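#' Construct an epoch set
#'
#' Container for segmented single trials: a `trials x channels x samples`
#' tensor with a time axis in ms relative to target onset, per-trial class
#' labels (`+1` = near, `-1` = far), subject ids, and optional reaction
#' times. This is the decoder's input type.
#'
#' @param data `trials x channels x samples` numeric array, µV.
#' @param times_ms Time axis (length = dim 3), equally spaced.
#' @param labels Per-trial labels in `{+1, -1}` (near = +1, far = -1).
#' @param subjects Per-trial subject ids.
#' @param sfreq_hz Sampling frequency in Hz.
#' @param channels Optional channel names.
#' @param rt_ms Optional per-trial reaction times.
#' @param rejected Bookkeeping tibble of rejected trials (may be empty).
#' @return An `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times_ms, labels, subjects, sfreq_hz,
                       channels = NULL, rt_ms = NULL, rejected = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] != length(times_ms)) {
    stop_invalid("`times_ms` length must match the sample dimension.")
  }
  if (dim(data)[1] != length(labels) || dim(data)[1] != length(subjects)) {
    stop_invalid("`labels`/`subjects` length must match the trial dimension.")
  }
  if (!all(labels %in% c(-1, 1))) {
    stop_invalid("`labels` must be +1 (near) or -1 (far).")
  }
  channels <- channels %||% dimnames(data)[[2]] %||%
    sprintf("E%03d", seq_len(dim(data)[2]))
  dimnames(data) <- list(NULL, channels, NULL)
  structure(
    list(data = data, times_ms = as.numeric(times_ms),
         labels = as.integer(labels), subjects = as.character(subjects),
         sfreq_hz = sfreq_hz, channels = channels,
         rt_ms = rt_ms,
         rejected = rejected %||% tibble(subject = character(),
                                         trial = integer(),
                                         reason = character())),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("<eeg_epochs> %d trials (%d near / %d far), ",
                     "%d channels, %d samples (%g..%g ms), %d subject(s)\n"),
              d[1], sum(x$labels == 1), sum(x$labels == -1), d[2], d[3],
              min(x$times_ms), max(x$times_ms), length(unique(x$subjects))))
  if (nrow(x$rejected)) {
    cat(sprintf("  %d trial(s) rejected\n", nrow(x$rejected)))
  }
  invisible(x)
}

#' Number of trials per subject and condition
#'
#' @param ep An `eeg_epochs`.
#' @return A tibble with columns `subject`, `condition`, `n`.
#' @export
epoch_counts <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  cond <- ifelse(ep$labels == 1, "near", "far")
  tab <- table(subject = ep$subjects, condition = cond)
  df <- as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(df) <- c("subject", "condition", "n")
  df
}

subset_epochs <- function(ep, trials = NULL, samples = NULL) {
  trials <- trials %||% seq_len(dim(ep$data)[1])
  samples <- samples %||% seq_len(dim(ep$data)[3])
  eeg_epochs(ep$data[trials, , samples, drop = FALSE],
             ep$times_ms[samples], ep$labels[trials], ep$subjects[trials],
             ep$sfreq_hz, ep$channels, ep$rt_ms[trials], ep$rejected)
}
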