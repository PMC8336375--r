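# The network's reverse pass is hand-derived; these tests pin it against
# central-difference numerical gradients with convolutions in exact double
# precision, and check the float fast path against the double path.

naive_conv2d <- function(x, w, b, pad) {
  d <- dim(x); k <- dim(w)[1]; cout <- dim(w)[4]
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  y <- array(0, c(d[1], d[2], cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(cout)) {
    acc <- matrix(b[co], d[1], d[2])
    for (ci in seq_len(d[3])) for (i in 1:k) for (j in 1:k) {
      acc <- acc + w[i, j, ci, co] *
        xp[(i - 1) + seq_len(d[1]), (j - 1) + seq_len(d[2]), ci, n]
    }
    y[, , co, n] <- acc
  }
  y
}

test_that("GEMM convolution matches a direct sliding-window computation", {
  set.seed(21)
  x <- array(rnorm(12 * 10 * 3 * 2), c(12, 10, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  ref <- naive_conv2d(x, w, b, 1L)
  expect_lt(max(abs(schnetr:::cpp_conv2d_forward(x, w, b, 1L, TRUE) - ref)),
            1e-12)
  expect_lt(max(abs(schnetr:::cpp_conv2d_forward(x, w, b, 1L, FALSE) - ref)),
            1e-5)
})

test_that("analytic gradients match numerical differentiation through the full graph", {
  withr::local_options(schnetr.conv_double = TRUE)
  set.seed(31)
  cfg <- schnet_config(width_scale = 1 / 16, input_shape = c(32, 32),
                       cbam_reduction_ratio = 4, seed = 5)
  m <- build_schnet(cfg)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 1, 2))
  labels <- c(0L, 1L)
  fw <- schnet_forward(m, x, train = TRUE, keep_cache = TRUE)
  ls <- schnetr:::xent_loss(fw$probs, labels)
  g <- schnet_backward(m, fw$cache, ls$dlogits)
  loss_at <- function(model) {
    schnetr:::xent_loss(schnet_forward(model, x, train = TRUE)$probs,
                        labels)$loss
  }
  eps <- 1e-5
  paths <- list(
    list(c("block1", "conv1", "w"), 3L), list(c("block2", "bn2", "gamma"), 2L),
    list(c("block4", "conv2", "w"), 11L), list(c("skip2", "conv", "w"), 5L),
    list(c("cbam", "W2"), 7L), list(c("cbam", "sp", "w"), 25L),
    list(c("fusion", "conv", "w"), 13L), list(c("head", "fc1", "w"), 40L),
    list(c("head", "fc2", "w"), 3L))
  for (pc in paths) {
    path <- pc[[1]]; idx <- pc[[2]]
    perturb <- function(delta) {
      mm <- m
      nav <- sprintf('mm$params%s[[%d]] <- mm$params%s[[%d]] + delta',
                     paste0(sprintf('[["%s"]]', path), collapse = ""), idx,
                     paste0(sprintf('[["%s"]]', path), collapse = ""), idx)
      eval(parse(text = nav))
      mm
    }
    num <- (loss_at(perturb(eps)) - loss_at(perturb(-eps))) / (2 * eps)
    ana <- g
    for (k in path) ana <- ana[[k]]
    expect_lt(abs(num - ana[idx]), 1e-6 + 1e-4 * abs(num),
              label = paste(paste(path, collapse = "$"), idx))
  }
})

test_that("fused BN+ReLU agrees with a plain R reference in both modes", {
  set.seed(41)
  x <- array(rnorm(6 * 4 * 3 * 5), c(6, 4, 3, 5))
  gamma <- runif(3, 0.5, 2); beta <- rnorm(3)
  rmean <- rnorm(3); rvar <- runif(3, 0.5, 2)
  # training mode: batch statistics over (H, W, N)
  out <- schnetr:::cpp_bnrelu_forward(x, gamma, beta, rmean, rvar, TRUE, 1e-5)
  for (c in 1:3) {
    v <- x[, , c, ]
    ref <- pmax(gamma[c] * (x[, , c, ] - mean(v)) /
                  sqrt(mean((v - mean(v))^2) + 1e-5) + beta[c], 0)
    expect_equal(out$y[, , c, ], ref, tolerance = 1e-12)
  }
  # eval mode: running statistics
  oe <- schnetr:::cpp_bnrelu_forward(x, gamma, beta, rmean, rvar, FALSE, 1e-5)
  for (c in 1:3) {
    ref <- pmax(gamma[c] * (x[, , c, ] - rmean[c]) / sqrt(rvar[c] + 1e-5) +
                  beta[c], 0)
    expect_equal(oe$y[, , c, ], ref, tolerance = 1e-12)
  }
})
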