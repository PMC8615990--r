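#' Specify a condition-difference effect
#'
#' An effect is a smooth unimodal (Hann) source waveform confined to a time
#' window relative to target onset, carried by one or more sources of the
#' head model, with a signed far-minus-near amplitude: a positive
#' `amplitude_uv` makes the far-condition channel projection exceed the near
#' one by `amplitude_uv * gain` at the waveform peak; `0` makes the two
#' conditions distributionally identical.
#'
#' @param window_ms Length-2 window (start, end) in ms relative to target
#'   onset; half-open `[start, end)`.
#' @param source_indices Indices into the head model's sources carrying the
#'   effect.
#' @param amplitude_uv Signed far-minus-near peak amplitude, in µV at the
#'   best-coupled sensor (gain columns peak at 1).
#' @return An `effect_spec`.
#' @export
effect_spec <- function(window_ms, source_indices, amplitude_uv) {
  if (length(window_ms) != 2 || window_ms[1] >= window_ms[2]) {
    stop_invalid("`window_ms` must be (start, end) with start < end.")
  }
  structure(list(window_ms = as.numeric(window_ms),
                 source_indices = as.integer(source_indices),
                 amplitude_uv = as.numeric(amplitude_uv)),
            class = "effect_spec")
}

#' Default two-effect configuration
#'
#' The canonical simulated ground truth: a positive far-minus-near
#' fronto-central effect in the 100 ms bridging the end of the prime picture
#' and the start of the inter-stimulus interval (-550..-450 ms), and a
#' negative far-minus-near posterior effect late in the target period
#' (600..700 ms).
#'
#' @param head A `head_model`; effect sources are chosen as the sources
#'   nearest the fronto-central and posterior reference locations.
#' @param amplitude_uv Magnitude applied with signs `(+, -)` to the two
#'   effects. Default 2.5 µV, a typical ERP condition difference.
#' @return List of two `effect_spec`s.
#' @export
default_effects <- function(head, amplitude_uv = 2.5) {
  list(
    effect_spec(c(-550, -450), nearest_source(head, "frontocentral"),
                +amplitude_uv),
    effect_spec(c(600, 700), nearest_source(head, "posterior"),
                -amplitude_uv)
  )
}

#' Configure a synthetic two-condition go/no-go ERP study
#'
#' Defaults mirror the study design the simulator emulates: 30 subjects,
#' 84 go trials per distance condition (near/far), a 128-channel montage
#' sampled at 250 Hz, epochs of -1500..+1500 ms around target-picture onset,
#' with the prime picture at -1200 ms, 700 ms picture presentations, a
#' 500 ms inter-stimulus interval and a 2500 ms inter-trial interval. No-go
#' trials (prime and target from different distance categories) are included
#' at a 1:4 ratio to go trials and are excluded from decoding downstream.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_condition Go trials per condition per subject (>= 1).
#' @param n_channels,sfreq_hz Montage size and sampling rate.
#' @param epoch_ms Epoch extent (start, end) in ms around target onset.
#' @param prime_onset_ms Prime onset relative to target onset (negative).
#' @param picture_duration_ms,isi_ms,iti_ms Presentation timing in ms.
#' @param noise List with elements `pink_uv` (rms of the correlated 1/f
#'   background, default 10 µV), `white_uv` (per-sensor white noise, 2 µV),
#'   `slope` (spectral exponent, -1) and `n_noise_sources` (latent background
#'   sources mixed into channels).
#' @param effects List of [effect_spec()]s; `NULL` means
#'   [default_effects()] of the head model used at simulation time, and
#'   `list()` means no condition effect at all (the two conditions are then
#'   exchangeable by construction).
#' @param rt_model Shifted-lognormal reaction-time model: list with
#'   `near_mean_ms`, `far_mean_ms`, `sd_ms`, `shift_ms`, `subject_sd_ms`.
#'   Defaults put the far mean 40 ms below the near mean, mirroring the
#'   behavioural facilitation for far views.
#' @param artifact_rate Per-trial probability of a large (300 µV) transient
#'   artifact, exercising peak-to-peak rejection downstream.
#' @param nogo_fraction No-go trials as a fraction of go trials.
#' @param seed Integer seed; the study is a deterministic function of the
#'   configuration.
#' @return A `study_config`.
#' @export
study_config <- function(n_subjects = 30,
                         n_trials_per_condition = 84,
                         n_channels = 128,
                         sfreq_hz = 250,
                         epoch_ms = c(-1500, 1500),
                         prime_onset_ms = -1200,
                         picture_duration_ms = 700,
                         isi_ms = 500,
                         iti_ms = 2500,
                         noise = NULL,
                         effects = NULL,
                         rt_model = NULL,
                         artifact_rate = 0.02,
                         nogo_fraction = 0.25,
                         seed = 1) {
  if (n_trials_per_condition < 1) {
    stop_invalid("`n_trials_per_condition` must be >= 1.")
  }
  if (n_subjects < 1) stop_invalid("`n_subjects` must be >= 1.")
  if (length(epoch_ms) != 2 || epoch_ms[1] >= epoch_ms[2]) {
    stop_invalid("`epoch_ms` must be (start, end) with start < end.")
  }
  noise_defaults <- list(pink_uv = 10, white_uv = 2, slope = -1,
                         n_noise_sources = max(4L, ceiling(n_channels / 4)))
  noise <- utils::modifyList(noise_defaults, noise %||% list())
  rt_defaults <- list(near_mean_ms = 940, far_mean_ms = 900, sd_ms = 100,
                      shift_ms = 300, subject_sd_ms = 80)
  rt_model <- utils::modifyList(rt_defaults, rt_model %||% list())

  structure(
    list(n_subjects = as.integer(n_subjects),
         n_trials_per_condition = as.integer(n_trials_per_condition),
         n_channels = as.integer(n_channels),
         sfreq_hz = sfreq_hz,
         epoch_ms = as.numeric(epoch_ms),
         prime_onset_ms = prime_onset_ms,
         picture_duration_ms = picture_duration_ms,
         isi_ms = isi_ms,
         iti_ms = iti_ms,
         noise = noise,
         effects = effects,
         rt_model = rt_model,
         artifact_rate = artifact_rate,
         nogo_fraction = nogo_fraction,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0("<study_config> %d subjects, %d go trials/condition, ",
                     "%d channels @ %g Hz\n"),
              x$n_subjects, x$n_trials_per_condition, x$n_channels,
              x$sfreq_hz))
  cat(sprintf("  epoch %g..%g ms, prime at %g ms, picture %g ms, ISI %g ms\n",
              x$epoch_ms[1], x$epoch_ms[2], x$prime_onset_ms,
              x$picture_duration_ms, x$isi_ms))
  invisible(x)
}
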