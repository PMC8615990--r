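# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_invalid <- function(msg) {
  abort(msg, class = "erpdecode_invalid_argument")
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number.", name))
  }
}

# Convert a time in ms (relative to the epoch time axis) to the index of the
# first sample at or after it. `times_ms` must be equally spaced.
ms_to_index <- function(t_ms, times_ms) {
  which(times_ms >= t_ms - 1e-9)[1]
}

# Indices of samples falling in the half-open window [start, end) ms.
window_indices <- function(times_ms, window_ms) {
  idx <- which(times_ms >= window_ms[1] - 1e-9 & times_ms < window_ms[2] - 1e-9)
  if (length(idx) == 0L) {
    stop_invalid(sprintf("window [%g, %g) ms contains no samples.",
                         window_ms[1], window_ms[2]))
  }
  idx
}

# Symmetric eigen-based pseudo-inverse for (possibly rank-deficient)
# symmetric positive semi-definite matrices.
pinv_sym <- function(m, tol = 1e-12) {
  e <- eigen(m, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  v <- e$vectors[, keep, drop = FALSE]
  v %*% (t(v) / e$values[keep])
}
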