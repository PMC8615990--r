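test_that("interval channel means average trials then samples per condition", {
  ep <- make_tiny_epochs(n_per_class = 2, n_channels = 3, n_samples = 10,
                         n_subjects = 2, seed = 51)
  ep$data[] <- 3
  m <- interval_channel_means(ep, c(0, 20))
  expect_equal(dim(m), c(2L, 3L, 2L))
  expect_true(all(m == 3))
  expect_equal(dimnames(m)[[3]], c("near", "far"))
  # single trial per condition: means equal the per-sample average directly
  ep1 <- make_tiny_epochs(n_per_class = 1, n_channels = 2, n_samples = 8,
                          n_subjects = 1, seed = 52)
  m1 <- interval_channel_means(ep1, c(8, 24))
  idx <- which(ep1$times_ms >= 8 & ep1$times_ms < 24)
  expect_equal(m1[1, , "near"],
               rowMeans(ep1$data[ep1$labels == 1, , idx][, ]),
               ignore_attr = TRUE)
  # a subject without far trials errors
  ep2 <- make_tiny_epochs(n_subjects = 2)
  drop <- which(ep2$subjects == "S02" & ep2$labels == -1L)
  ep3 <- eeg_epochs(ep2$data[-drop, , , drop = FALSE], ep2$times_ms,
                    ep2$labels[-drop], ep2$subjects[-drop], ep2$sfreq_hz)
  expect_error(interval_channel_means(ep3, c(0, 20)), "far")
})

test_that("paired t-test reproduces the hand formula and its symmetries", {
  # d = (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.4641, df = 2, p ~ 0.0742
  res <- paired_ttest(c(2, 3, 4), c(1, 1, 1))
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-sqrt(12), 2), tolerance = 1e-12)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  # agreement with the stock implementation
  set.seed(53)
  a <- rnorm(10); b <- rnorm(10)
  st <- t.test(a, b, paired = TRUE)
  mine <- paired_ttest(a, b)
  expect_equal(mine$t, unname(st$statistic), tolerance = 1e-12)
  expect_equal(mine$p, st$p.value, tolerance = 1e-12)
  # sign flip negates t, keeps p
  flip <- paired_ttest(b, a)
  expect_equal(flip$t, -mine$t, tolerance = 1e-12)
  expect_equal(flip$p, mine$p, tolerance = 1e-12)
  # identical inputs have undefined t
  expect_error(paired_ttest(1:3, 1:3), class = "erpdecode_invalid_argument")
  expect_error(paired_ttest(1:3, 1:2), class = "erpdecode_invalid_argument")
  expect_error(paired_ttest(1, 2), class = "erpdecode_invalid_argument")
})

test_that("topography statistics carry signed differences and flags", {
  set.seed(54)
  n_subj <- 8
  means <- array(rnorm(n_subj * 4 * 2, sd = 0.5), dim = c(n_subj, 4, 2),
                 dimnames = list(sprintf("S%02d", 1:n_subj),
                                 sprintf("E%03d", 1:4), c("near", "far")))
  means[, 2, "far"] <- means[, 2, "far"] + 5  # strong positive far - near
  ts <- topo_difference(structure(means, window_ms = c(0, 100),
                                  class = "channel_window_means"))
  expect_s3_class(ts, "topo_stats")
  expect_true(ts$significant[2])
  expect_gt(ts$diff_uv[2], 0)
  # t and difference share sign on every channel
  expect_true(all(sign(ts$t) == sign(ts$diff_uv) | ts$diff_uv == 0))
  # swapping the condition axis negates differences and t, keeps p
  swapped <- structure(means[, , c(2, 1)], window_ms = c(0, 100),
                       class = "channel_window_means")
  dimnames(swapped)[[3]] <- c("near", "far")
  ts2 <- topo_difference(swapped)
  expect_equal(ts2$diff_uv, -ts$diff_uv, tolerance = 1e-12)
  expect_equal(ts2$t, -ts$t, tolerance = 1e-12)
  expect_equal(ts2$p, ts$p, tolerance = 1e-12)
  # identical condition data: zero differences, nothing flagged
  same <- means
  same[, , "far"] <- same[, , "near"]
  ts3 <- topo_difference(structure(same, window_ms = c(0, 100),
                                   class = "channel_window_means"))
  expect_true(all(ts3$diff_uv == 0))
  expect_false(any(ts3$significant))
})

test_that("zero-effect data flags about the nominal alpha fraction", {
  set.seed(55)
  flags <- replicate(25, {
    means <- array(rnorm(8 * 16 * 2), dim = c(8, 16, 2),
                   dimnames = list(NULL, sprintf("E%03d", 1:16),
                                   c("near", "far")))
    topo_difference(structure(means, window_ms = c(0, 1),
                              class = "channel_window_means"))$significant
  })
  rate <- mean(flags)  # 400 channel tests at alpha = 0.05
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("recovered topography matches the injected pattern and sign", {
  head <- build_toy_headmodel(16, 8, seed = 1)
  fc <- nearest_source(head, "frontocentral")
  study <- make_small_study(n_subjects = 6, n_trials = 16, n_channels = 16,
                            effects = list(effect_spec(c(-550, -450), fc, 5)),
                            seed = 56, head = head)
  ep <- preprocess_study(study, min_epochs = 5)
  m <- interval_channel_means(ep, c(-550, -450))
  ts <- topo_difference(m)
  best <- which.max(head$gain[, fc])
  expect_gt(ts$diff_uv[best], 0)
  expect_true(ts$significant[best])
  # difference concentrates where the source projects: ordering agreement
  expect_gt(cor(ts$diff_uv, head$gain[, fc]), 0.8)
  # closed-form expectation: far - near on the best channel ~ gain x mean wave
  idx <- which(ep$times_ms >= -550 & ep$times_ms < -450)
  n_w <- 25
  expected <- 5 * head$gain[best, fc] *
    mean(0.5 * (1 - cos(2 * pi * seq(0, n_w) / n_w)))
  expect_lt(abs(ts$diff_uv[best] - expected), 3 * 0.75)
})

test_that("grand averages combine subject means and expose the difference", {
  ep <- make_tiny_epochs(n_per_class = 2, n_channels = 3, n_samples = 10,
                         n_subjects = 3, offset = 2, seed = 57)
  g_near <- grand_average_topography(ep, c(0, 20), "near")
  g_far <- grand_average_topography(ep, c(0, 20), "far")
  g_diff <- grand_average_topography(ep, c(0, 20), "difference")
  expect_equal(g_diff, g_far - g_near, tolerance = 1e-12)
  expect_gt(g_diff[[1]], 1)  # the offset channel
})
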