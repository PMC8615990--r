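#' Behavioural reaction-time comparison
#'
#' Per-subject mean foot-pedal release times (go trials) for the near and
#' far conditions, compared with a two-tailed paired t-test — the standard
#' test for a locomotor facilitation by far/panoramic views (lower RT in
#' far than near).
#'
#' @param study A `synthetic_study`.
#' @return A list with `per_subject` (tibble: `subject`, `near_ms`,
#'   `far_ms`) and `test` (the [paired_ttest()] of near vs. far, so a
#'   positive `estimate` means slower near responses).
#' @export
rt_comparison <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  per_subject <- dplyr::bind_rows(lapply(seq_along(study$events), function(s) {
    ev <- study$events[[s]]
    go <- ev[ev$trial_type == "go", ]
    tibble(subject = study$recordings[[s]]$subject,
           near_ms = mean(go$rt_ms[go$condition == "near"]),
           far_ms = mean(go$rt_ms[go$condition == "far"]))
  }))
  list(per_subject = per_subject,
       test = paired_ttest(per_subject$near_ms, per_subject$far_ms))
}
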