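test_that("empirical null matches exhaustive label enumeration on a toy set", {
  ep <- make_tiny_epochs(n_per_class = 3, n_channels = 2, n_samples = 2,
                         n_subjects = 1, seed = 41)
  perms <- oracle_balanced_assignments(6)  # all 20 balanced assignments
  null <- permutation_null(ep, cv = "trial",
                           window_ms = range(ep$times_ms) + c(0, 1),
                           shrinkage = 0.5, permutations = perms)
  fold <- seq_len(6)
  want <- t(vapply(seq_len(ncol(perms)), function(j) {
    rowMeans(oracle_cv_accuracy(ep$data, perms[, j], fold, 0.5))
  }, numeric(2)))
  expect_equal(null$values, want, tolerance = 1e-12)
  # percentiles of the enumerated null agree exactly
  for (pr in c(0.5, 0.95, 0.99)) {
    expect_equal(apply(null$values, 2, quantile, probs = pr, names = FALSE),
                 apply(want, 2, oracle_percentile, prob = pr),
                 tolerance = 1e-12)
  }
})

test_that("the null is deterministic given the seed and validates input", {
  ep <- make_tiny_epochs(n_per_class = 3, n_channels = 2, n_samples = 3,
                         n_subjects = 2, seed = 42)
  win <- range(ep$times_ms) + c(0, 1)
  suppressWarnings({
    a <- permutation_null(ep, n_perm = 12, seed = 5, window_ms = win)
    b <- permutation_null(ep, n_perm = 12, seed = 5, window_ms = win)
    c <- permutation_null(ep, n_perm = 12, seed = 6, window_ms = win)
  })
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_error(permutation_null(ep, n_perm = 0, window_ms = win),
               class = "erpdecode_invalid_argument")
  expect_warning(permutation_null(ep, n_perm = 5, window_ms = win),
                 "unstable")
  degen <- ep
  degen$labels[] <- 1L
  expect_error(permutation_null(degen, n_perm = 10, window_ms = win),
               class = "erpdecode_invalid_argument")
})

test_that("significance mask applies percentile and chance criteria jointly", {
  times <- seq(0, 36, by = 4)
  obs <- structure(tibble::tibble(time_ms = times,
                                  accuracy = rep(0.5, 10), se = 0),
                   class = c("accuracy_timecourse", "tbl_df", "tbl",
                             "data.frame"))
  null <- structure(list(values = matrix(runif(200, 0.3, 0.55), 20, 10),
                         times_ms = times, n_perm = 20, seed = 1,
                         cv_scheme = "trial"), class = "perm_null")
  # chance accuracy never exceeds the 60% threshold
  expect_false(any(significant_mask(obs, null)$significant))
  # a single supra-threshold point flags exactly once
  obs$accuracy[4] <- 0.9
  m <- significant_mask(obs, null)
  expect_equal(which(m$significant), 4L)
  # disabling the absolute threshold leaves the percentile criterion
  m2 <- significant_mask(obs, null, chance_threshold = NULL)
  expect_equal(which(m2$significant),
               which(obs$accuracy > apply(null$values, 2, oracle_percentile,
                                          prob = 0.99)))
  # axis mismatch errors
  null$times_ms <- times + 4
  expect_error(significant_mask(obs, null),
               class = "erpdecode_invalid_argument")
})

test_that("raising the percentile can only shrink the mask", {
  set.seed(43)
  times <- seq(0, 76, by = 4)
  obs <- structure(tibble::tibble(time_ms = times,
                                  accuracy = runif(20, 0.45, 0.75), se = 0),
                   class = c("accuracy_timecourse", "tbl_df", "tbl",
                             "data.frame"))
  null <- structure(list(values = matrix(runif(1000, 0.4, 0.7), 50, 20),
                         times_ms = times, n_perm = 50, seed = 1,
                         cv_scheme = "trial"), class = "perm_null")
  masks <- lapply(c(80, 95, 99), function(pc) {
    significant_mask(obs, null, percentile = pc,
                     chance_threshold = NULL)$significant
  })
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
})

test_that("interval extraction produces sorted half-open runs", {
  expect_equal(nrow(extract_intervals(rep(FALSE, 10), seq(0, 36, 4))), 0)
  # samples covering [-550, -450) at 250 Hz give back exactly that interval
  times <- seq(-650, -350, by = 4)
  mask <- times >= -550 & times < -450
  iv <- extract_intervals(mask, times)
  expect_equal(iv$start_ms, -550)
  expect_equal(iv$end_ms, -450)
  expect_equal(iv$n_samples, 25L)
  # two 1-sample runs (4 ms each) are discarded at min_duration_ms = 20
  mask2 <- rep(FALSE, length(times))
  mask2[c(5, 20)] <- TRUE
  expect_equal(nrow(extract_intervals(mask2, times, min_duration_ms = 20)), 0)
  expect_equal(nrow(extract_intervals(mask2, times)), 2)
  # intervals come back sorted with per-interval accuracy summaries
  df <- tibble::tibble(time_ms = times,
                       accuracy = seq(0.4, 0.8, length.out = length(times)),
                       significant = mask2)
  iv2 <- extract_intervals(df)
  expect_equal(iv2$start_ms, times[c(5, 20)])
  expect_equal(iv2$peak_accuracy, df$accuracy[c(5, 20)])
})
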