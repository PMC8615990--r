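#' Construct a continuous EEG recording
#'
#' Thin container for one subject's continuous multichannel signal.
#'
#' @param data `channels x samples` numeric matrix, in µV.
#' @param sfreq_hz Sampling frequency in Hz.
#' @param channels Optional channel names (default `E001`, ...).
#' @param subject Subject identifier.
#' @return An `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq_hz, channels = NULL, subject = "S01") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_invalid("`data` must be a numeric channels x samples matrix.")
  }
  if (!all(is.finite(data))) stop_invalid("`data` must be finite.")
  assert_scalar_number(sfreq_hz, "sfreq_hz")
  channels <- channels %||% rownames(data) %||%
    sprintf("E%03d", seq_len(nrow(data)))
  rownames(data) <- channels
  structure(list(data = data, sfreq_hz = sfreq_hz, channels = channels,
                 subject = subject),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject, nrow(x$data), ncol(x$data), x$sfreq_hz,
              ncol(x$data) / x$sfreq_hz))
  invisible(x)
}
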