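#' Fit a two-class shrinkage LDA classifier
#'
#' Linear discriminant analysis for labels `y` in `{+1, -1}` with a
#' shrinkage-regularized pooled covariance: `Sigma_hat = (1 - lambda) * S +
#' lambda * nu * I`, where `S` is the class-mean-centered pooled covariance
#' (normalized by `n - 1`) and `nu = mean(diag(S))`, so the regularization
#' target preserves total variance. `lambda` can be fixed in `[0, 1]` or
#' chosen analytically per fit (Ledoit-Wolf-style, `"auto"`), which keeps the
#' fit well-posed when channels outnumber trials. The weight vector is
#' `w = Sigma_hat^{-1} (mu_plus - mu_minus)` and the bias
#' `b = -w' (mu_plus + mu_minus) / 2` (equal class priors); a singular
#' `Sigma_hat` (possible at `lambda = 0`) is inverted in the least-squares
#' sense.
#'
#' @param x `trials x channels` numeric matrix (features at one time point).
#' @param y Labels, one per trial, in `{+1, -1}`; both classes required.
#' @param shrinkage `"auto"` or a number in `[0, 1]`.
#' @return An `lda_model` with fields `w`, `b`, `lambda`, `nu`,
#'   `mu_plus`, `mu_minus`.
#' @examples
#' x <- rbind(matrix(rnorm(20, 1), 10), matrix(rnorm(20, -1), 10))
#' fit <- fit_lda(x, rep(c(1, -1), each = 10))
#' predict(fit, x)
#' @export
fit_lda <- function(x, y, shrinkage = "auto") {
  x <- as.matrix(x)
  if (!all(y %in% c(-1, 1))) stop_invalid("`y` must be +1 or -1.")
  if (length(y) != nrow(x)) stop_invalid("`y` must have one label per row.")
  if (!all(c(-1, 1) %in% y)) stop_invalid("both classes must be present.")
  n <- nrow(x)
  p <- ncol(x)
  mu_p <- colMeans(x[y == 1, , drop = FALSE])
  mu_m <- colMeans(x[y == -1, , drop = FALSE])
  z <- x - rbind(mu_m, mu_p)[(y + 3) / 2, , drop = FALSE]
  P <- crossprod(z)
  S <- P / (n - 1)
  nu <- mean(diag(S))
  lambda <- if (identical(shrinkage, "auto")) {
    lw_lambda(z, P, S, nu)
  } else {
    assert_scalar_number(shrinkage, "shrinkage")
    if (shrinkage < 0 || shrinkage > 1) {
      stop_invalid("`shrinkage` must be in [0, 1] or \"auto\".")
    }
    shrinkage
  }
  sigma <- (1 - lambda) * S + diag(lambda * nu, p)
  d <- mu_p - mu_m
  w <- tryCatch(drop(solve(sigma, d)),
                error = function(e) drop(pinv_sym(sigma) %*% d))
  b <- -sum(w * (mu_p + mu_m)) / 2
  structure(list(w = setNames(w, colnames(x)), b = b, lambda = lambda,
                 nu = nu, mu_plus = mu_p, mu_minus = mu_m, n = n, p = p),
            class = "lda_model")
}

# Analytic (Ledoit-Wolf-style) shrinkage intensity toward nu * I, computed
# from the class-centered data z with P = z'z, S = P/(n-1).
lw_lambda <- function(z, P, S, nu) {
  n <- nrow(z)
  p <- ncol(z)
  if (nu == 0) return(1)
  q <- crossprod(z^2)
  var_s <- n / (n - 1)^2 * (q / n - (P / n)^2)
  target_dist <- sum((S - diag(nu, p))^2)
  if (target_dist <= 0) return(1)
  min(1, max(0, sum(var_s) / target_dist))
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d features, lambda = %.4f, b = %.4g\n",
              x$p, x$lambda, x$b))
  invisible(x)
}

#' Predict classes and decision values
#'
#' The decision value for a channel pattern `x` is `dval = w'x + b`;
#' the predicted class is `+1` (near) when `dval > 0` and `-1` (far) when
#' `dval < 0`. The measure-zero tie `dval = 0` maps to `+1`.
#'
#' @param object An `lda_model`.
#' @param newdata A channel pattern (vector) or `trials x channels` matrix.
#' @param ... Unused.
#' @return A tibble with columns `dval` and `class`.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$w)) {
    stop_invalid("`newdata` must have one column per model feature.")
  }
  dval <- drop(newdata %*% object$w) + object$b
  tibble(dval = dval, class = ifelse(dval >= 0, 1L, -1L))
}

#' @rdname predict.lda_model
#' @param model An `lda_model`.
#' @param x A channel pattern or matrix of patterns.
#' @export
lda_predict <- function(model, x) predict(model, x)

#' @export
tidy.lda_model <- function(x, ...) {
  tibble(channel = names(x$w) %||% sprintf("E%03d", seq_along(x$w)),
         weight = unname(x$w),
         mean_near = unname(x$mu_plus),
         mean_far = unname(x$mu_minus))
}

#' @export
glance.lda_model <- function(x, ...) {
  tibble(n = x$n, n_features = x$p, lambda = x$lambda, nu = x$nu, b = x$b)
}
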