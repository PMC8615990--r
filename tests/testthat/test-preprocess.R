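test_that("band-pass rejects DC and passes/stops the right frequencies", {
  sf <- 250
  n <- 2500
  interior <- 500:2000
  # constant input: the 1 Hz high-pass edge removes DC
  dc <- bandpass(rep(5, 1000), 1, 40, sfreq_hz = sf)
  expect_lt(max(abs(dc)), 1e-6 * 5)
  # 10 Hz sinusoid: in-band, near-unit amplitude, zero-phase
  t <- (0:(n - 1)) / sf
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass(x10, 1, 40, sfreq_hz = sf)
  amp <- max(abs(y10[interior]))
  expect_gte(amp, 0.9)
  expect_lte(amp, 1.0)
  cc <- stats::ccf(y10[interior], x10[interior], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)  # zero-phase: peak at lag 0
  # 60 Hz sinusoid: attenuated by the squared magnitude response
  y60 <- bandpass(sin(2 * pi * 60 * t), 1, 40, sfreq_hz = sf)
  expect_lt(max(abs(y60[interior])), 0.1)
})

test_that("filter amplitudes match the analytic squared Butterworth response", {
  sf <- 250
  bf <- signal::butter(2, c(1, 40) / (sf / 2), type = "pass")
  for (f in c(5, 20, 60)) {
    w <- 2 * pi * f / sf
    z <- exp(-1i * w * (seq_along(bf$b) - 1))
    h <- sum(bf$b * z) / sum(bf$a * z)  # transfer function at f
    expected <- Mod(h)^2                # forward-backward = |H|^2
    t <- (0:2499) / sf
    y <- bandpass(sin(2 * pi * f * t), 1, 40, sfreq_hz = sf)
    expect_equal(max(abs(y[500:2000])), expected, tolerance = 0.02)
  }
})

test_that("invalid filter bands error", {
  expect_error(bandpass(rnorm(100), 0, 40, sfreq_hz = 250),
               class = "erpdecode_invalid_argument")
  expect_error(bandpass(rnorm(100), 40, 1, sfreq_hz = 250),
               class = "erpdecode_invalid_argument")
  expect_error(bandpass(rnorm(100), 1, 130, sfreq_hz = 250),
               class = "erpdecode_invalid_argument")
})

test_that("common average reference zeroes the channel mean everywhere", {
  x <- matrix(rnorm(5 * 100), 5, 100)
  y <- common_average(x)
  expect_lt(max(abs(colMeans(y))), 1e-10)
  # identical signal on every channel vanishes
  z <- matrix(rep(rnorm(50), each = 4), 4, 50)
  expect_equal(common_average(z), matrix(0, 4, 50), tolerance = 1e-12)
  # two channels (a, b) -> ((a - b)/2, (b - a)/2)
  ab <- rbind(a = rnorm(20), b = rnorm(20))
  expect_equal(unname(common_average(ab)),
               rbind((ab[1, ] - ab[2, ]) / 2, (ab[2, ] - ab[1, ]) / 2))
  expect_error(common_average(matrix(1, 1, 10)),
               class = "erpdecode_invalid_argument")
})

test_that("epoching cuts the documented sample grid and drops edge events", {
  sf <- 250
  raw <- eeg_recording(matrix(rnorm(2 * 3000), 2, 3000), sf)
  ev <- tibble::tibble(onset_sample = c(10L, 1500L),
                       condition = c("near", "far"),
                       trial_type = c("go", "go"))
  expect_warning(ep <- epoch_trials(raw, ev), "edge")
  expect_equal(dim(ep$data), c(1L, 2L, 750L))  # 3000 ms at 250 Hz
  expect_equal(ep$labels, -1L)                 # far trial survived
  expect_equal(range(ep$times_ms), c(-1500, 1496))
  # epoch content equals the raw slice
  expect_equal(ep$data[1, , ], raw$data[, 1500 - 375 + (0:749)],
               ignore_attr = TRUE)
})

test_that("no-go trials are excluded from the decoder's epochs", {
  study <- make_small_study(n_subjects = 1, n_trials = 5)
  ev <- study$events[[1]]
  ep <- epoch_trials(study$recordings[[1]], ev)
  expect_equal(dim(ep$data)[1], sum(ev$trial_type == "go"))
  ep_all <- epoch_trials(study$recordings[[1]], ev, go_only = FALSE)
  expect_equal(dim(ep_all$data)[1], nrow(ev))
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  ep <- make_tiny_epochs(n_per_class = 3, n_channels = 3, n_samples = 20)
  bc <- baseline_correct(ep, window_ms = c(0, 40))
  idx <- which(bc$times_ms >= 0 & bc$times_ms < 40)
  expect_lt(max(abs(apply(bc$data[, , idx], c(1, 2), mean))), 1e-10)
  expect_equal(baseline_correct(bc, c(0, 40))$data, bc$data,
               tolerance = 1e-12)
  # constant 5 uV epoch becomes all zeros
  const <- ep
  const$data[] <- 5
  expect_equal(max(abs(baseline_correct(const, c(0, 40))$data)), 0)
  expect_error(baseline_correct(ep, c(500, 600)),
               class = "erpdecode_invalid_argument")
})

test_that("baseline correction and common-average referencing commute", {
  ep <- make_tiny_epochs(n_per_class = 3, n_channels = 4, n_samples = 16)
  a <- common_average(baseline_correct(ep, c(0, 24)))
  b <- baseline_correct(common_average(ep), c(0, 24))
  expect_lt(max(abs(a$data - b$data)), 1e-10)
})

test_that("peak-to-peak rejection removes exactly the spiked epoch", {
  ep <- make_tiny_epochs(n_per_class = 5, n_channels = 3, n_samples = 12)
  spiked <- 7L
  ep$data[spiked, 2, 5] <- ep$data[spiked, 2, 5] + 50
  clean <- reject_artifacts(ep, peak_to_peak_uv = 20, min_epochs = 1)
  expect_equal(dim(clean$data)[1], dim(ep$data)[1] - 1L)
  expect_equal(clean$rejected$trial, spiked)
  # infinite threshold is the identity
  all_kept <- reject_artifacts(ep, peak_to_peak_uv = Inf, min_epochs = 1)
  expect_equal(all_kept$data, ep$data)
})

test_that("falling below the minimal epoch count is a hard error", {
  ep <- make_tiny_epochs(n_per_class = 40, n_channels = 2, n_samples = 8,
                         n_subjects = 1)
  ep$data[3, 1, 2] <- 1e4  # a near-condition trial: 39 clean remain
  expect_error(reject_artifacts(ep, peak_to_peak_uv = 100, min_epochs = 40),
               "S01.*near", class = "erpdecode_too_few_epochs")
})

test_that("filtering continuous data then epoching matches filtering a padded segment", {
  sf <- 250
  set.seed(4)
  raw <- eeg_recording(pink_noise(2, 12000, sf, seed = 4), sf)
  ev <- tibble::tibble(onset_sample = 6000L, condition = "near",
                       trial_type = "go")
  a <- epoch_trials(bandpass(raw, 1, 40), ev)
  pad <- 4 * sf
  seg <- raw$data[, (6000 - 375 - pad):(6000 + 374 + pad)]
  b <- bandpass(seg, 1, 40, sfreq_hz = sf)[, pad + (1:750)]
  expect_lt(max(abs(a$data[1, , ] - b)), 1e-6 * sd(raw$data))
})
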