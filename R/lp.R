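#' All-pole linear prediction and its temporally weighted variants
#'
#' Fits an order-`p` all-pole model of a (windowed) frame under one of four
#' criteria, with the positive-prediction sign convention
#' `x(n) = sum_i a_i x(n-i) + e(n)`:
#'
#' * `none` — classical autocorrelation method solved by Levinson-Durbin.
#' * `wlp` — weighted LP: minimizes `sum_n w(n) e(n)^2` with the short-time
#'   energy weight `w(n) = sum_{i=1..M} x(n-i)^2`, `M = order`, solved via
#'   weighted covariance normal equations.
#' * `swlp` — stabilized WLP: the lagged regressors carry partial weights
#'   built by the recursion `y_0(n) = sqrt(w(n)) x(n)`,
#'   `y_k(n) = m(n) y_{k-1}(n-1)` with `m(n) = sqrt(w(n)/w(n-1))` clamped
#'   at 1; any pole at or outside the unit circle is additionally reflected
#'   to its conjugate reciprocal and the gain recomputed, so the returned
#'   model is always stable.
#' * `xlp` — extended WLP: per-lag weights on a finer time scale,
#'   `z_k(n) = w_k(n) x(n-k)` with `w_k(n) = (|x(n)| + |x(n-k)|)/2`,
#'   solved by normal equations on the weighted regressors.
#'
#' Singular normal equations are regularized by a ridge of
#' `1e-8 * trace`, with a message.
#'
#' @param frame Numeric vector of (windowed) samples, longer than
#'   `2 * order`.
#' @param order Model order (default 38).
#' @param weighting One of `"none"`, `"wlp"`, `"swlp"`, `"xlp"`.
#' @param weights Optional explicit weight vector overriding the
#'   short-time-energy weights of `wlp`/`swlp` (same length as `frame`).
#' @return An `lp_model`: `order`, `a` (coefficients a_1..a_p), `weighting`,
#'   `gain` (residual RMS), `pole_radii`.
#' @export
lp_family <- function(frame, order = 38L, weighting = "none",
                      weights = NULL) {
  weighting <- match.arg(weighting, c("none", "wlp", "swlp", "xlp"))
  x <- as.numeric(frame)
  n <- length(x)
  if (n <= 2L * order) {
    stop("frame too short for order ", order, ": need more than ",
         2L * order, " samples, got ", n)
  }
  a <- switch(weighting,
    none = lp_autocorrelation(x, order),
    wlp = lp_weighted(x, order, ste_weights(x, order, weights)),
    swlp = lp_swlp(x, order, ste_weights(x, order, weights)),
    xlp = lp_xlp(x, order))
  radii <- lp_pole_radii(a)
  if (weighting == "swlp" && any(radii >= 1)) {
    a <- reflect_poles(a)
    radii <- lp_pole_radii(a)
  }
  e <- as.numeric(stats::filter(x, c(1, -a), method = "convolution",
                                sides = 1L))
  gain <- sqrt(mean(e[-seq_len(order)]^2))
  structure(list(order = as.integer(order), a = a, weighting = weighting,
                 gain = gain, pole_radii = radii),
            class = "lp_model")
}

ste_weights <- function(x, order, weights = NULL) {
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(x), all(weights >= 0))
    return(weights)
  }
  # w(n) = sum of the previous `order` squared samples (zero history
  # before the frame); floored to keep sqrt ratios defined
  csum <- cumsum(c(0, x^2))
  n <- length(x)
  idx_hi <- pmax(pmin(seq_len(n) - 1L, n), 0L)
  idx_lo <- pmax(seq_len(n) - 1L - order, 0L)
  pmax(csum[idx_hi + 1L] - csum[idx_lo + 1L], 1e-12)
}

lp_autocorrelation <- function(x, p) {
  r <- vapply(0:p, function(k) sum(x[seq_len(length(x) - k)] *
                                     x[seq_len(length(x) - k) + k]),
              numeric(1))
  if (r[1L] <= 0) return(numeric(p))
  levinson_durbin(r, p)
}

# Levinson-Durbin recursion on autocorrelations r[0..p]; returns a_1..a_p
# in the positive-prediction convention.
levinson_durbin <- function(r, p) {
  a <- numeric(p)
  err <- r[1L]
  for (i in seq_len(p)) {
    acc <- r[i + 1L]
    if (i > 1L) acc <- acc - sum(a[seq_len(i - 1L)] * r[i:2])
    k <- acc / err
    if (i > 1L) {
      a_prev <- a[seq_len(i - 1L)]
      a[seq_len(i - 1L)] <- a_prev - k * rev(a_prev)
    }
    a[i] <- k
    err <- err * (1 - k^2)
    if (err <= 0) break
  }
  a
}

lagged_matrix <- function(x, p) {
  n <- length(x)
  rows <- (p + 1L):n
  X <- matrix(0, length(rows), p)
  for (k in seq_len(p)) X[, k] <- x[rows - k]
  list(X = X, y = x[rows])
}

solve_normal <- function(R, rhs) {
  sol <- tryCatch(solve(R, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    message("singular normal equations; applying ridge 1e-8 * trace")
    ridge <- 1e-8 * sum(diag(R)) + 1e-30
    sol <- solve(R + diag(ridge, nrow(R)), rhs)
  }
  as.numeric(sol)
}

lp_weighted <- function(x, p, w) {
  lm <- lagged_matrix(x, p)
  sw <- sqrt(w[(p + 1L):length(x)])
  Xw <- lm$X * sw
  solve_normal(crossprod(Xw), crossprod(Xw, lm$y * sw))
}

lp_swlp <- function(x, p, w) {
  n <- length(x)
  m <- c(1, pmin(sqrt(w[-1L] / w[-n]), 1 / sqrt(.Machine$double.eps)))
  m <- pmax(m, 1) # clamp: only up-weighting ratios propagate
  Y <- matrix(0, n, p + 1L)
  Y[, 1L] <- sqrt(w) * x
  for (k in seq_len(p)) {
    Y[2:n, k + 1L] <- m[2:n] * Y[1:(n - 1L), k]
  }
  rows <- (p + 1L):n
  X <- Y[rows, -1L, drop = FALSE]
  solve_normal(crossprod(X), crossprod(X, Y[rows, 1L]))
}

lp_xlp <- function(x, p) {
  n <- length(x)
  rows <- (p + 1L):n
  ax <- abs(x)
  Z <- matrix(0, length(rows), p)
  for (k in seq_len(p)) {
    Z[, k] <- ((ax[rows] + ax[rows - k]) / 2) * x[rows - k]
  }
  z0 <- ax[rows] * x[rows]
  solve_normal(crossprod(Z), crossprod(Z, z0))
}

#' Pole radii of an all-pole model
#'
#' @param a Coefficients a_1..a_p (positive-prediction convention).
#' @return Moduli of the roots of `1 - sum a_i z^-i`.
#' @export
lp_pole_radii <- function(a) {
  if (!length(a) || all(a == 0)) return(numeric(0))
  # roots of z^p - a_1 z^(p-1) - ... - a_p
  Mod(polyroot(rev(c(1, -a))))
}

# Reflect poles with radius >= 1 to their conjugate reciprocals and
# rebuild the coefficient vector.
reflect_poles <- function(a) {
  roots <- polyroot(rev(c(1, -a)))
  r <- Mod(roots)
  bad <- r >= 1
  roots[bad] <- (1 - 1e-6) * roots[bad] / r[bad]^2  # 1/Conj(z), radius shrunk
  # expand prod (z - root_i) back into coefficients
  coef <- 1
  for (z in roots) coef <- c(coef, 0) - c(0, coef * z)
  -Re(coef[-1L])
}

#' LP spectral envelope in dB
#'
#' @param model An `lp_model`.
#' @param sample_rate Sampling rate in Hz.
#' @param n_points Number of frequency points on `[0, Nyquist]`.
#' @return Data frame with `freq_hz` and `level_db`.
#' @export
lp_envelope <- function(model, sample_rate, n_points = 512L) {
  f <- seq(0, sample_rate / 2, length.out = n_points)
  om <- 2 * pi * f / sample_rate
  k <- seq_len(model$order)
  denom <- 1 - exp(-1i * outer(om, k)) %*% model$a
  data.frame(freq_hz = f,
             level_db = 20 * log10(pmax(model$gain, 1e-12) / Mod(denom)))
}
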