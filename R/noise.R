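#' Generate 1/f ("pink") background noise
#'
#' Spectrally shaped Gaussian noise: each channel is white Gaussian noise
#' whose Fourier amplitudes are scaled by `f^(slope/2)`, giving a power
#' spectral density proportional to `f^slope`. `slope = 0` is white noise,
#' `slope = -1` the classic EEG-like 1/f background. Channels are
#' independent; the study simulator mixes a few such sources to obtain
#' channel-correlated background activity.
#'
#' @param n_channels Number of channels.
#' @param n_samples Number of samples (>= 64, so the spectrum is resolvable).
#' @param sfreq_hz Sampling frequency in Hz.
#' @param slope Spectral exponent in `[-2, 0]`.
#' @param scale_uv Per-channel standard deviation of the output, in µV;
#'   `0` yields an all-zero array.
#' @param seed Optional seed; when given, output is deterministic and the
#'   caller's RNG state is left untouched.
#' @return An `n_channels x n_samples` matrix, zero-mean per channel.
#' @examples
#' x <- pink_noise(4, 1024, 250, slope = -1, seed = 1)
#' rowMeans(x)
#' @export
pink_noise <- function(n_channels, n_samples, sfreq_hz, slope = -1,
                       scale_uv = 1, seed = NULL) {
  assert_scalar_number(n_samples, "n_samples")
  assert_scalar_number(slope, "slope")
  if (n_samples < 64) stop_invalid("`n_samples` must be >= 64.")
  if (slope < -2 || slope > 0) stop_invalid("`slope` must lie in [-2, 0].")
  if (scale_uv == 0) return(matrix(0, n_channels, n_samples))
  gen <- function() {
    freqs <- seq(0, n_samples - 1) * (sfreq_hz / n_samples)
    # shape only positive frequencies; keep Hermitian symmetry for a real IFFT
    half <- freqs[seq(2, floor(n_samples / 2) + 1)]
    amp <- half^(slope / 2)
    out <- matrix(0, n_channels, n_samples)
    for (ch in seq_len(n_channels)) {
      spec <- fft(rnorm(n_samples))
      shape <- numeric(n_samples)
      shape[seq(2, floor(n_samples / 2) + 1)] <- amp
      if (n_samples %% 2 == 0) {
        shape[seq(n_samples, floor(n_samples / 2) + 2)] <-
          amp[seq_len(floor(n_samples / 2) - 1)]
      } else {
        shape[seq(n_samples, floor(n_samples / 2) + 2)] <- amp
      }
      x <- Re(fft(spec * shape, inverse = TRUE)) / n_samples
      x <- x - mean(x)
      out[ch, ] <- x / sd(x) * scale_uv
    }
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
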