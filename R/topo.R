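#' Per-subject channel means within a significant interval
#'
#' For every subject, channel and condition, averages first across the
#' subject's trials of that condition and then across the samples of the
#' interval. The result is the input to the channel-space paired t-tests.
#'
#' @param ep An `eeg_epochs` (multi-subject).
#' @param interval Either one row of the tibble returned by
#'   [extract_intervals()] or a length-2 `(start, end)` window in ms
#'   (half-open).
#' @return A `channel_window_means`: `subjects x channels x 2` array with
#'   condition slices ordered `(near, far)` and the interval stored as an
#'   attribute.
#' @export
interval_channel_means <- function(ep, interval) {
  stopifnot(inherits(ep, "eeg_epochs"))
  window_ms <- interval_window(interval)
  idx <- window_indices(ep$times_ms, window_ms)
  subjects <- unique(ep$subjects)
  out <- array(NA_real_,
               dim = c(length(subjects), length(ep$channels), 2L),
               dimnames = list(subjects, ep$channels, c("near", "far")))
  for (s in seq_along(subjects)) {
    for (cond in c("near", "far")) {
      lab <- if (cond == "near") 1L else -1L
      sel <- ep$subjects == subjects[s] & ep$labels == lab
      if (!any(sel)) {
        abort(sprintf("subject %s has no %s trials.", subjects[s], cond),
              class = "erpdecode_invalid_argument")
      }
      out[s, , cond] <- apply(ep$data[sel, , idx, drop = FALSE], 2, mean)
    }
  }
  structure(out, window_ms = window_ms, class = "channel_window_means")
}

interval_window <- function(interval) {
  if (is.data.frame(interval)) {
    if (nrow(interval) != 1) {
      stop_invalid("pass a single interval (one row).")
    }
    c(interval$start_ms, interval$end_ms)
  } else {
    if (length(interval) != 2) stop_invalid("`interval` must be (start, end).")
    as.numeric(interval)
  }
}

#' Paired t-test
#'
#' Classical two-tailed paired Student t-test: with differences
#' `d = a - b`, `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of
#' freedom.
#'
#' @param a,b Paired per-subject values of equal length >= 2.
#' @return A one-row tibble with `estimate` (mean difference), `t`, `df`,
#'   `p` (two-tailed).
#' @examples
#' paired_ttest(c(2, 3, 4), c(1, 1, 1))
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("`a` and `b` must be paired.")
  if (length(a) < 2) stop_invalid("need >= 2 pairs.")
  d <- a - b
  s <- sd(d)
  if (s == 0) {
    stop_invalid("differences have zero variance; t is undefined.")
  }
  n <- length(d)
  t_stat <- mean(d) / (s / sqrt(n))
  tibble(estimate = mean(d), t = t_stat, df = n - 1,
         p = 2 * pt(-abs(t_stat), df = n - 1))
}

#' Channel-space condition-difference topography
#'
#' Per-channel paired t-tests of far vs. near across subjects on interval
#' means, yielding the signed far-minus-near difference map and the set of
#' channels significant at `alpha`. Channels whose differences are
#' identically zero across subjects (no effect, no noise) report `t = 0`,
#' `p = 1`. Tests are uncorrected by default, matching the pointwise
#' starring convention of ERP topographies; set `bonferroni = TRUE` to
#' correct across channels.
#'
#' @param means A `channel_window_means` from [interval_channel_means()].
#' @param alpha Significance level per channel (default 0.05).
#' @param bonferroni Divide `alpha` by the channel count.
#' @return A `topo_stats` tibble with `channel`, `diff_uv` (far - near),
#'   `t`, `p`, `significant`.
#' @export
topo_difference <- function(means, alpha = 0.05, bonferroni = FALSE) {
  stopifnot(inherits(means, "channel_window_means"))
  if (dim(means)[1] < 2) stop_invalid("need >= 2 subjects.")
  channels <- dimnames(means)[[2]]
  thr <- if (bonferroni) alpha / length(channels) else alpha
  rows <- lapply(seq_along(channels), function(ch) {
    far <- means[, ch, "far"]
    near <- means[, ch, "near"]
    d <- far - near
    if (sd(d) == 0 && all(d == 0)) {
      tibble(channel = channels[ch], diff_uv = 0, t = 0, df = length(d) - 1,
             p = 1)
    } else {
      tt <- paired_ttest(far, near)
      tibble(channel = channels[ch], diff_uv = tt$estimate, t = tt$t,
             df = tt$df, p = tt$p)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p < thr
  structure(out, class = c("topo_stats", class(out)), alpha = alpha,
            window_ms = attr(means, "window_ms"))
}

#' Grand-average scalp topography in an interval
#'
#' Across-subject mean of the per-subject interval means, for one condition
#' or the signed far-minus-near difference.
#'
#' @param ep An `eeg_epochs`.
#' @param interval As in [interval_channel_means()].
#' @param condition `"near"`, `"far"`, or `"difference"` (far - near).
#' @return Named numeric vector, one value per channel (µV).
#' @export
grand_average_topography <- function(ep, interval,
                                     condition = c("difference", "near",
                                                   "far")) {
  condition <- match.arg(condition)
  m <- interval_channel_means(ep, interval)
  near <- apply(m[, , "near", drop = FALSE], 2, mean)
  far <- apply(m[, , "far", drop = FALSE], 2, mean)
  switch(condition, near = near, far = far, difference = far - near)
}
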