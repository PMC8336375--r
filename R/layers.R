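# Layer-level forward/backward primitives used by the Sch-net graph.
# Tensors are (H, W, C, N) arrays; convolutions are stride-1 zero-padded.

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_conv <- function(k, c_in, c_out) {
  list(w = he_uniform(c(k, k, c_in, c_out), k * k * c_in),
       b = numeric(c_out))
}

init_bn <- function(c_out) {
  list(gamma = rep(1, c_out), beta = numeric(c_out))
}

init_bn_state <- function(c_out) {
  list(mean = numeric(c_out), var = rep(1, c_out))
}

init_fc <- function(n_in, n_out) {
  list(w = he_uniform(c(n_out, n_in), n_in), b = numeric(n_out))
}

# Convolutions run in single precision by default; set
# options(schnetr.conv_double = TRUE) for exact double-precision arithmetic
# (used when verifying gradients numerically).
conv_precision <- function() isTRUE(getOption("schnetr.conv_double", FALSE))

conv_forward <- function(x, p, pad) {
  cpp_conv2d_forward(x, p$w, p$b, pad, conv_precision())
}

conv_backward <- function(x, p, dy, pad) {
  cpp_conv2d_backward(x, p$w, dy, pad, conv_precision())
}

# One conv -> BN -> ReLU unit (the ordering used throughout the network).
# BN and ReLU run in a fused compiled kernel; in training mode batch
# statistics are used and the running statistics updated, in eval mode the
# stored running statistics apply.
cbr_forward <- function(x, conv_p, bn_p, bn_state, train, pad = 1L,
                        momentum = 0.1, eps = 1e-5) {
  z <- conv_forward(x, conv_p, pad)
  bn <- cpp_bnrelu_forward(z, bn_p$gamma, bn_p$beta, bn_state$mean,
                           bn_state$var, train, eps)
  if (train) {
    bn_state$mean <- (1 - momentum) * bn_state$mean + momentum * bn$mean
    bn_state$var <- (1 - momentum) * bn_state$var + momentum * bn$var
  }
  list(y = bn$y, state = bn_state,
       cache = list(x = x, xhat = bn$xhat, invstd = bn$invstd,
                    gamma = bn_p$gamma, y = bn$y, pad = pad))
}

cbr_backward <- function(dy, conv_p, cache) {
  bnb <- cpp_bnrelu_backward(dy, cache$y, cache$xhat, cache$gamma,
                             cache$invstd)
  cvb <- conv_backward(cache$x, conv_p, bnb$dx, cache$pad)
  list(dx = cvb$dx,
       g = list(conv = list(w = cvb$dw, b = cvb$db),
                bn = list(gamma = bnb$dgamma, beta = bnb$dbeta)))
}

# Channel-wise concatenation of (H, W, C_i, N) tensors.
concat_channels <- function(tensors) {
  d1 <- dim(tensors[[1]])
  cs <- vapply(tensors, function(t) dim(t)[3], integer(1))
  N <- d1[4]; hw <- d1[1] * d1[2]
  out <- array(0, c(d1[1], d1[2], sum(cs), N))
  om <- matrix(0, hw, sum(cs) * N)
  off <- cumsum(c(0L, cs))
  for (i in seq_along(tensors)) {
    tm <- tensors[[i]]
    dim(tm) <- c(hw, cs[i] * N)
    cols <- as.vector(outer(seq_len(cs[i]) + off[i], (seq_len(N) - 1L) * sum(cs), `+`))
    om[, cols] <- tm
  }
  dim(om) <- c(d1[1], d1[2], sum(cs), N)
  om
}

split_channels <- function(x, cs) {
  d <- dim(x)
  hw <- d[1] * d[2]; N <- d[4]; Ctot <- d[3]
  xm <- x
  dim(xm) <- c(hw, Ctot * N)
  off <- cumsum(c(0L, cs))
  lapply(seq_along(cs), function(i) {
    cols <- as.vector(outer(seq_len(cs[i]) + off[i], (seq_len(N) - 1L) * Ctot, `+`))
    t <- xm[, cols, drop = FALSE]
    dim(t) <- c(d[1], d[2], cs[i], N)
    t
  })
}

# Broadcast multiply: x (H,W,C,N) by per-channel weights m (C x N).
scale_by_channel <- function(x, m) {
  d <- dim(x)
  y <- x * rep(as.vector(m), each = d[1] * d[2])
  dim(y) <- d
  y
}

# Broadcast multiply: x (H,W,C,N) by a spatial map s (H x W x 1 x N).
scale_by_spatial <- function(x, s) {
  d <- dim(x)
  hw <- d[1] * d[2]
  sm <- matrix(s, hw, d[4])
  xm <- x
  dim(xm) <- c(hw, d[3] * d[4])
  y <- xm * sm[, rep(seq_len(d[4]), each = d[3])]
  dim(y) <- d
  y
}
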