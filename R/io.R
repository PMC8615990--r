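#' Write / read a synthetic study as a plain-text directory
#'
#' Serializes a study to a directory of portable text files:
#' `meta.json` (configuration, head model and ground-truth effects),
#' one `<subject>_data.csv` per subject (samples x channels, µV) and one
#' `<subject>_events.csv` (columns `onset_sample`, `condition`,
#' `trial_type`, `rt_ms`). `read_study()` restores the full object.
#'
#' @param study A `synthetic_study`.
#' @param dir Target directory (created if missing).
#' @return `write_study()` returns `dir` invisibly; `read_study()` returns
#'   the `synthetic_study`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  meta <- list(
    config = unclass(cfg),
    head = list(sensor_positions = study$head$sensor_positions,
                source_positions = study$head$source_positions,
                gain = study$head$gain, spread = study$head$spread,
                seed = study$head$seed),
    ground_truth = list(
      seed = study$ground_truth$seed,
      effects = lapply(study$ground_truth$effects, unclass)),
    subjects = vapply(study$recordings, `[[`, "", "subject")
  )
  meta$config$effects <- lapply(cfg$effects %||% list(), unclass)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  for (s in seq_along(study$recordings)) {
    rec <- study$recordings[[s]]
    data.table::fwrite(data.table::as.data.table(t(rec$data)),
                       file.path(dir, sprintf("%s_data.csv", rec$subject)))
    write_events(study$events[[s]],
                 file.path(dir, sprintf("%s_events.csv", rec$subject)))
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cfg_fields <- meta$config
  cfg_fields$effects <- relist_effects(cfg_fields$effects)
  cfg <- do.call(study_config, cfg_fields[names(cfg_fields) %in%
                                            names(formals(study_config))])
  sens <- as.matrix(meta$head$sensor_positions)
  srcs <- as.matrix(meta$head$source_positions)
  gain <- as.matrix(meta$head$gain)
  ch_names <- sprintf("E%03d", seq_len(nrow(gain)))
  dimnames(sens) <- list(ch_names, c("x", "y", "z"))
  dimnames(srcs) <- list(NULL, c("x", "y", "z"))
  dimnames(gain) <- list(ch_names, NULL)
  head <- structure(
    list(sensor_positions = sens, source_positions = srcs,
         gain = gain, spread = meta$head$spread, seed = meta$head$seed),
    class = "head_model")
  subjects <- meta$subjects
  recordings <- lapply(subjects, function(s) {
    d <- as.matrix(data.table::fread(file.path(dir,
                                               sprintf("%s_data.csv", s))))
    eeg_recording(t(d), cfg$sfreq_hz, channels = colnames(d), subject = s)
  })
  events <- lapply(subjects, function(s) {
    read_events(file.path(dir, sprintf("%s_events.csv", s)))
  })
  structure(list(recordings = recordings, events = events, config = cfg,
                 head = head,
                 ground_truth = list(
                   effects = relist_effects(meta$ground_truth$effects),
                   seed = meta$ground_truth$seed)),
            class = "synthetic_study")
}

relist_effects <- function(effects) {
  if (is.null(effects) || length(effects) == 0) return(list())
  if (is.data.frame(effects)) effects <- split(effects, seq_len(nrow(effects)))
  lapply(effects, function(e) {
    effect_spec(unlist(e$window_ms), unlist(e$source_indices),
                e$amplitude_uv)
  })
}

#' Write / read an event table as CSV
#'
#' @param events Event tibble (`onset_sample`, `condition`, `trial_type`,
#'   `rt_ms`).
#' @param path CSV file path.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- as_tibble(data.table::fread(path))
  ev$onset_sample <- as.integer(ev$onset_sample)
  if ("rt_ms" %in% names(ev)) ev$rt_ms <- as.numeric(ev$rt_ms)
  ev
}
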