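#' Simulate a multi-subject two-condition ERP study
#'
#' Generates continuous recordings and event tables for every subject of a
#' [study_config()]. Each recording is the sum of (i) channel-correlated 1/f
#' background noise (a few latent pink sources mixed into the montage) plus
#' sensor white noise, (ii) a condition-independent evoked response at every
#' picture onset, (iii) the configured condition effects, projected through
#' the head model's lead field and added on far-condition trials only (so the
#' expected far-minus-near evoked difference equals
#' `amplitude_uv * gain * waveform`), and (iv) occasional large transient
#' artifacts. Go-trial reaction times are drawn from a per-condition shifted
#' lognormal with a subject-level random offset.
#'
#' With all effect amplitudes zero the two conditions are exchangeable by
#' construction: labels carry no information about the signal.
#'
#' @param cfg A [study_config()].
#' @param head A [build_toy_headmodel()] with `cfg$n_channels` channels;
#'   `NULL` builds one with 16 sources from `cfg$seed`.
#' @return A `synthetic_study`: list of per-subject `eeg_recording`s and
#'   event tibbles (`onset_sample`, `condition`, `trial_type`, `rt_ms`), the
#'   configuration, the head model, and the ground-truth effect list.
#' @examples
#' cfg <- study_config(n_subjects = 2, n_trials_per_condition = 6,
#'                     n_channels = 8, effects = list(), seed = 7)
#' study <- simulate_study(cfg)
#' study$events[[1]]
#' @export
simulate_study <- function(cfg, head = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  head <- head %||% build_toy_headmodel(cfg$n_channels, n_sources = 16,
                                        seed = cfg$seed)
  if (nrow(head$gain) != cfg$n_channels) {
    stop_invalid("head model channel count does not match `cfg$n_channels`.")
  }
  effects <- cfg$effects %||% default_effects(head)
  for (ef in effects) {
    stopifnot(inherits(ef, "effect_spec"))
    if (ef$window_ms[1] < cfg$epoch_ms[1] ||
        ef$window_ms[2] > cfg$epoch_ms[2]) {
      stop_invalid(sprintf("effect window [%g, %g) lies outside the epoch.",
                           ef$window_ms[1], ef$window_ms[2]))
    }
    if (any(ef$source_indices < 1 | ef$source_indices > ncol(head$gain))) {
      stop_invalid("effect `source_indices` outside the head model.")
    }
  }

  out <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_subjects), function(s) {
      simulate_subject(cfg, head, effects, sprintf("S%02d", s))
    })
  })

  structure(
    list(recordings = lapply(out, `[[`, "recording"),
         events = lapply(out, `[[`, "events"),
         config = cfg,
         head = head,
         ground_truth = list(effects = effects, seed = cfg$seed)),
    class = "synthetic_study"
  )
}

simulate_subject <- function(cfg, head, effects, subject) {
  sf <- cfg$sfreq_hz
  n_ch <- cfg$n_channels
  target_offset_ms <- cfg$picture_duration_ms + cfg$isi_ms  # prime->target
  trial_ms <- target_offset_ms + cfg$picture_duration_ms + cfg$iti_ms
  pad_ms <- 2000

  n_go <- 2L * cfg$n_trials_per_condition
  n_nogo <- round(cfg$nogo_fraction * n_go)
  condition <- c(rep(c("near", "far"), cfg$n_trials_per_condition),
                 rep_len(c("near", "far"), n_nogo))
  trial_type <- c(rep("go", n_go), rep("nogo", n_nogo))
  ord <- sample(length(condition))
  condition <- condition[ord]
  trial_type <- trial_type[ord]
  n_trials <- length(condition)

  total_ms <- 2 * pad_ms + n_trials * trial_ms
  n_samples <- round(total_ms / 1000 * sf)
  target_onset <- round((pad_ms + (seq_len(n_trials) - 1) * trial_ms +
                           target_offset_ms) / 1000 * sf) + 1L

  # channel-correlated pink background + sensor white noise
  m <- cfg$noise$n_noise_sources
  src <- pink_noise(m, n_samples, sf, slope = cfg$noise$slope, scale_uv = 1)
  mix <- matrix(rnorm(n_ch * m), n_ch, m)
  mix <- mix / sqrt(rowSums(mix^2))
  data <- (mix %*% src) * cfg$noise$pink_uv
  if (cfg$noise$white_uv > 0) {
    data <- data + matrix(rnorm(n_ch * n_samples, sd = cfg$noise$white_uv),
                          n_ch, n_samples)
  }

  # condition-independent evoked response at each picture onset
  evoked <- picture_evoked(sf)
  evoked_topo <- head$gain[, nearest_source(head, "vertex")]
  prime_onset <- target_onset - round(target_offset_ms / 1000 * sf)
  for (on in c(prime_onset, target_onset)) {
    idx <- on + seq_along(evoked) - 1L
    data[, idx] <- data[, idx] + outer(evoked_topo, evoked)
  }

  # signed condition effects on far trials
  for (ef in effects) {
    if (ef$amplitude_uv == 0) next
    w_idx <- round(ef$window_ms[1] / 1000 * sf):
             (round(ef$window_ms[2] / 1000 * sf) - 1L)
    wave <- hann_wave(length(w_idx)) * ef$amplitude_uv
    topo <- rowSums(head$gain[, ef$source_indices, drop = FALSE])
    bump <- outer(topo, wave)
    for (k in which(condition == "far")) {
      idx <- target_onset[k] + w_idx
      data[, idx] <- data[, idx] + bump
    }
  }

  # occasional large transient artifacts (exercise peak-to-peak rejection)
  is_artifact <- runif(n_trials) < cfg$artifact_rate
  for (k in which(is_artifact)) {
    ch <- sample.int(n_ch, 1)
    center <- target_onset[k] + round(runif(1, -1.4, 1.4) * sf)
    half <- round(0.1 * sf)
    idx <- (center - half):(center + half)
    data[ch, idx] <- data[ch, idx] +
      sample(c(-300, 300), 1) * hann_wave(length(idx))
  }

  # shifted-lognormal reaction times for go trials
  rt <- rep(NA_real_, n_trials)
  subj_offset <- rnorm(1, sd = cfg$rt_model$subject_sd_ms)
  for (cond in c("near", "far")) {
    sel <- trial_type == "go" & condition == cond
    mu_target <- switch(cond, near = cfg$rt_model$near_mean_ms,
                        far = cfg$rt_model$far_mean_ms)
    m_ln <- max(100, mu_target - cfg$rt_model$shift_ms + subj_offset)
    s_ln <- cfg$rt_model$sd_ms
    sigma2 <- log(1 + s_ln^2 / m_ln^2)
    rt[sel] <- cfg$rt_model$shift_ms +
      rlnorm(sum(sel), meanlog = log(m_ln) - sigma2 / 2,
             sdlog = sqrt(sigma2))
  }

  events <- tibble(onset_sample = target_onset, condition = condition,
                   trial_type = trial_type, rt_ms = rt)
  list(recording = eeg_recording(data, sf, subject = subject),
       events = events)
}

# condition-independent P1/N1-like response to a picture onset (400 ms)
picture_evoked <- function(sfreq_hz) {
  t <- seq(0, 0.4, by = 1 / sfreq_hz)
  -1.2 * gauss_bump(t, 0.10, 0.03) + 2.0 * gauss_bump(t, 0.20, 0.06)
}

gauss_bump <- function(t, center, width) exp(-(t - center)^2 / (2 * width^2))

hann_wave <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d subjects, %d channels, %d effect(s)\n",
              length(x$recordings), x$config$n_channels,
              length(x$ground_truth$effects)))
  invisible(x)
}
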