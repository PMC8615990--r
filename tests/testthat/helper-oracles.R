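# Independent oracles, coded without reference to the package internals.

# Welch power spectral density (Hann window, 50% overlap) and a log-log
# least-squares slope over a frequency band.
oracle_psd_slope <- function(x, sfreq, seg = 1024, band = c(1, 40)) {
  win <- 0.5 * (1 - cos(2 * pi * seq(0, seg - 1) / (seg - 1)))
  starts <- seq(1, length(x) - seg + 1, by = seg %/% 2)
  p <- rowMeans(vapply(starts, function(s) {
    Mod(stats::fft(x[s:(s + seg - 1)] * win))[2:(seg %/% 2)]^2
  }, numeric(seg %/% 2 - 1)))
  f <- (1:(seg %/% 2 - 1)) * sfreq / seg
  sel <- f >= band[1] & f <= band[2]
  unname(coef(stats::lm(log(p[sel]) ~ log(f[sel])))[2])
}

# Closed-form shrinkage-LDA solver: pseudo-inverse of
# (1 - lambda) * S + lambda * nu * I applied to the mean difference,
# with S the class-centered pooled covariance over n - 1.
oracle_lda <- function(x, y, lambda) {
  xp <- x[y == 1, , drop = FALSE]
  xm <- x[y == -1, , drop = FALSE]
  mup <- colMeans(xp)
  mum <- colMeans(xm)
  zc <- rbind(sweep(xp, 2, mup), sweep(xm, 2, mum))
  S <- t(zc) %*% zc / (nrow(x) - 1)
  nu <- mean(diag(S))
  sigma <- (1 - lambda) * S + lambda * nu * diag(ncol(x))
  w <- drop(MASS::ginv(sigma) %*% (mup - mum))
  list(w = w, b = -sum(w * (mup + mum)) / 2)
}

# Brute-force cross-validated accuracy time course at fixed shrinkage,
# written as plain loops over folds, time points and test trials.
oracle_cv_accuracy <- function(data, labels, fold, lambda) {
  n_times <- dim(data)[3]
  folds <- sort(unique(fold))
  acc <- matrix(NA_real_, n_times, length(folds))
  for (t in seq_len(n_times)) {
    xt <- data[, , t, drop = FALSE][, , 1, drop = FALSE]
    dim(xt) <- dim(data)[1:2]
    for (fi in seq_along(folds)) {
      tr <- fold != folds[fi]
      mod <- oracle_lda(xt[tr, , drop = FALSE], labels[tr], lambda)
      correct <- 0
      te <- which(!tr)
      for (k in te) {
        dv <- sum(mod$w * xt[k, ]) + mod$b
        pred <- if (dv >= 0) 1 else -1
        correct <- correct + (pred == labels[k])
      }
      acc[t, fi] <- correct / length(te)
    }
  }
  acc
}

# All distinct balanced label assignments for n trials (n/2 per class),
# as an n x choose(n, n/2) matrix of +1/-1.
oracle_balanced_assignments <- function(n) {
  pos_sets <- utils::combn(n, n / 2)
  apply(pos_sets, 2, function(idx) {
    y <- rep(-1, n)
    y[idx] <- 1
    y
  })
}

# Percentile by explicit order statistics with linear interpolation
# (the classic "type 7" definition, written out).
oracle_percentile <- function(x, prob) {
  xs <- sort(x)
  h <- (length(xs) - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
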