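#' Build a toy spherical head model
#'
#' Constructs a parametric forward model on the unit head sphere: sensors are
#' placed quasi-uniformly on the upper hemisphere (Fibonacci lattice), sources
#' are scattered inside an inner ball, and the lead field (gain) entry for a
#' sensor/source pair decays as a Gaussian of their Euclidean distance. The
#' model is deliberately simple — it is injective for generic geometries,
#' which is all the distributed inverse solution requires — and stands in for
#' an anatomical volume-conductor model.
#'
#' Coordinates follow the usual EEG convention: x to the right ear, y to the
#' nasion (anterior), z to the vertex. Gain columns are scaled so the maximal
#' sensor sees 1 µV per unit source amplitude.
#'
#' @param n_channels Number of sensors (>= 2).
#' @param n_sources Number of sources (>= 1), placed in a ball of radius 0.6
#'   with a minimal pairwise separation so point sources stay distinguishable.
#' @param spread Gaussian decay scale of the lead field, in head-radius units.
#' @param seed Integer seed controlling source placement; the model is a
#'   deterministic function of its arguments.
#' @return A `head_model` with fields `sensor_positions` (n_channels x 3),
#'   `source_positions` (n_sources x 3) and `gain` (n_channels x n_sources,
#'   µV per unit source amplitude).
#' @examples
#' head <- build_toy_headmodel(n_channels = 16, n_sources = 8)
#' dim(head$gain)
#' @export
build_toy_headmodel <- function(n_channels = 128, n_sources = 16,
                                spread = 0.5, seed = 1) {
  assert_scalar_number(n_channels, "n_channels")
  assert_scalar_number(n_sources, "n_sources")
  assert_scalar_number(spread, "spread")
  if (n_channels < 2) stop_invalid("`n_channels` must be >= 2.")
  if (n_sources < 1) stop_invalid("`n_sources` must be >= 1.")
  if (spread <= 0) stop_invalid("`spread` must be > 0.")
  n_channels <- as.integer(n_channels)
  n_sources <- as.integer(n_sources)

  sensors <- fibonacci_hemisphere(n_channels)
  sources <- with_seed(seed, sample_ball(n_sources, radius = 0.6,
                                         min_dist = 0.25))

  d2 <- outer(seq_len(n_channels), seq_len(n_sources), function(i, j) {
    rowSums((sensors[i, , drop = FALSE] - sources[j, , drop = FALSE])^2)
  })
  gain <- exp(-d2 / (2 * spread^2))
  gain <- sweep(gain, 2, apply(gain, 2, max), "/")  # 1 µV peak per unit source
  rownames(gain) <- sprintf("E%03d", seq_len(n_channels))

  structure(
    list(sensor_positions = sensors, source_positions = sources, gain = gain,
         spread = spread, seed = seed),
    class = "head_model"
  )
}

# Quasi-uniform points on the upper unit hemisphere (golden-angle spiral).
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # heights in (0, 1): upper hemisphere
  phi <- i * pi * (3 - sqrt(5))    # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  rownames(pos) <- sprintf("E%03d", seq_len(n))
  pos
}

# Rejection-sample points in a ball with minimal pairwise separation
# (separation is relaxed if the ball gets crowded).
sample_ball <- function(n, radius, min_dist) {
  pts <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  k <- 0L
  tries <- 0L
  sep <- min_dist
  while (k < n) {
    p <- runif(3, -radius, radius)
    tries <- tries + 1L
    if (sum(p^2) > radius^2) next
    if (k > 0L) {
      d <- sqrt(rowSums((pts[seq_len(k), , drop = FALSE] -
                           matrix(p, k, 3, byrow = TRUE))^2))
      if (min(d) < sep) {
        if (tries > 2000L) { sep <- sep * 0.8; tries <- 0L }
        next
      }
    }
    k <- k + 1L
    pts[k, ] <- p
  }
  pts
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> %d channels, %d sources, spread %.2f\n",
              nrow(x$gain), ncol(x$gain), x$spread))
  invisible(x)
}

#' Pick the source closest to a target location
#'
#' Convenience for placing condition effects at named scalp regions of the
#' toy head model.
#'
#' @param head A `head_model`.
#' @param target Either a length-3 coordinate or one of `"frontocentral"`,
#'   `"posterior"`, `"vertex"`.
#' @return The index of the nearest source.
#' @export
nearest_source <- function(head, target) {
  if (is.character(target)) {
    target <- switch(match.arg(target, c("frontocentral", "posterior",
                                         "vertex")),
                     frontocentral = c(0, 0.35, 0.45),
                     posterior = c(0, -0.45, 0.30),
                     vertex = c(0, 0, 0.55))
  }
  d <- rowSums((head$source_positions -
                  matrix(target, nrow(head$source_positions), 3,
                         byrow = TRUE))^2)
  which.min(d)
}
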