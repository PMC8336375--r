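test_that("default configuration matches the published architecture", {
  cfg <- schnet_config()
  expect_equal(cfg$block_filters, c(64L, 128L, 256L, 512L))
  expect_equal(cfg$skip_filters, 512L)
  expect_equal(cfg$merged_channels, 2048L)
  expect_equal(cfg$fusion_filters, 512L)
  expect_equal(cfg$head_sizes, c(512L, 2L))
  expect_equal(schnet_conv_layer_count(cfg), 12L)
})

test_that("inconsistent configurations are rejected with the violated identity", {
  cfg <- schnet_config()
  cfg$merged_channels <- 1024L
  expect_error(build_schnet(cfg), "merged_channels")
  expect_error(schnet_config(input_shape = c(100L, 256L)), "divisible")
  expect_error(schnet_config(variant = "resnet"), "arg")
})

test_that("width-scaled models keep the topology and emit 2-way outputs", {
  cfg <- schnet_config(width_scale = 1 / 4)
  expect_equal(cfg$merged_channels, 512L)
  m <- build_schnet(cfg)
  p <- schnet_forward(m, rand_image(1))$probs
  expect_equal(dim(p), c(1L, 2L))
  expect_lt(abs(sum(p) - 1), 1e-6)
  expect_true(all(p > 0))
})

test_that("backbone taps and final maps have the documented shapes", {
  m <- fixture("m16", build_schnet(schnet_config(width_scale = 1 / 16)))
  x <- stack_images(list(rand_image(2), rand_image(3)))
  bb <- forward_backbone(m, x)
  expect_equal(dim(bb$taps[[1]]), c(64L, 128L, 4L, 2L))
  expect_equal(dim(bb$taps[[2]]), c(32L, 64L, 8L, 2L))
  expect_equal(dim(bb$taps[[3]]), c(16L, 32L, 16L, 2L))
  expect_equal(dim(bb$final), c(8L, 16L, 32L, 2L))
  expect_error(forward_backbone(m, array(0, c(64, 64, 1, 1))), "128")
})

test_that("a zero image maps to zero activations under freshly initialized BN", {
  m <- fixture("m16", build_schnet(schnet_config(width_scale = 1 / 16)))
  bb <- forward_backbone(m, array(0, c(128, 256, 1, 1)), train = FALSE)
  expect_equal(max(abs(bb$final)), 0)
  for (t in bb$taps) expect_equal(max(abs(t)), 0)
})

test_that("skip merging concatenates to 4x the per-branch width at 8x16", {
  m <- fixture("m16", build_schnet(schnet_config(width_scale = 1 / 16)))
  x <- stack_images(list(rand_image(4)))
  bb <- forward_backbone(m, x)
  sk <- apply_skip_connections(m, bb$final, bb$taps)
  expect_equal(dim(sk$merged), c(8L, 16L, 128L, 1L))
  # with zero taps, the trailing block carries the backbone output unchanged
  zero_taps <- lapply(bb$taps, function(t) array(0, dim(t)))
  sk0 <- apply_skip_connections(m, bb$final, zero_taps)
  expect_equal(sk0$merged[, , 97:128, , drop = FALSE], bb$final,
               ignore_attr = TRUE)
})

test_that("average pooling preserves spatially constant taps exactly", {
  x <- array(3.25, c(64, 128, 2, 1))
  pooled <- schnetr:::cpp_avgpool_forward(x, 8L)
  expect_equal(dim(pooled), c(8L, 16L, 2L, 1L))
  expect_true(all(pooled == 3.25))
})

test_that("CBAM with zero weights gates the input by exactly 1/4", {
  cfg <- schnet_config(width_scale = 1 / 16, cbam_reduction_ratio = 4)
  m <- build_schnet(cfg)
  m$params$cbam$W1[] <- 0; m$params$cbam$b1[] <- 0
  m$params$cbam$W2[] <- 0; m$params$cbam$b2[] <- 0
  m$params$cbam$sp$w[] <- 0; m$params$cbam$sp$b[] <- 0
  f <- array(rnorm(8 * 16 * 128), c(8, 16, 128, 1))
  out <- cbam(m, f)
  expect_true(all(abs(out$channel_weights - 0.5) < 1e-12))
  expect_true(all(abs(out$spatial_map - 0.5) < 1e-12))
  expect_lt(max(abs(out$refined - f / 4)), 1e-12)
})

test_that("CBAM attention respects its permutation symmetries", {
  m <- fixture("m16", build_schnet(schnet_config(width_scale = 1 / 16)))
  set.seed(5)
  f <- array(rnorm(8 * 16 * 128 * 2), c(8, 16, 128, 2))
  base <- cbam(m, f)

  # spatial permutation leaves channel weights untouched
  perm <- sample(8 * 16)
  fm <- matrix(f, 8 * 16, 128 * 2)[perm, ]
  dim(fm) <- dim(f)
  out_sp <- cbam(m, fm)
  expect_equal(out_sp$channel_weights, base$channel_weights, tolerance = 1e-12)

  # channel permutation: the pooling stages are channel-equivariant, so
  # with a channel-preserving (identity) MLP the channel weights permute
  # with the input and the spatial map is untouched
  mi <- build_schnet(schnet_config(width_scale = 1 / 16,
                                   cbam_reduction_ratio = 1))
  mi$params$cbam$W1 <- diag(128); mi$params$cbam$b1 <- rep(0, 128)
  mi$params$cbam$W2 <- diag(128); mi$params$cbam$b2 <- rep(0, 128)
  base_i <- cbam(mi, f)
  cperm <- sample(128)
  fc <- f[, , cperm, , drop = FALSE]
  out_cp <- cbam(mi, fc)
  expect_equal(out_cp$spatial_map, base_i$spatial_map, tolerance = 1e-12)
  expect_equal(out_cp$channel_weights, base_i$channel_weights[cperm, ],
               tolerance = 1e-12)
})

test_that("classification head produces a softmax and symmetric logits tie", {
  m <- build_schnet(schnet_config(width_scale = 1 / 16))
  f <- array(rnorm(8 * 16 * 128), c(8, 16, 128, 1))
  cl <- classify(m, f)
  expect_equal(sum(cl$probs), 1, tolerance = 1e-6)
  expect_true(all(cl$probs >= 0))
  # zeroed head: both logits identical, output is the (0.5, 0.5) tie
  m0 <- m
  m0$params$head$fc1$w[] <- 0; m0$params$head$fc1$b[] <- 0
  m0$params$head$fc2$w[] <- 0; m0$params$head$fc2$b[] <- 0
  expect_equal(as.numeric(classify(m0, f)$probs), c(0.5, 0.5))
  # sharpening the output layer moves the max probability toward 1
  m2 <- m
  m2$params$head$fc2$w <- m2$params$head$fc2$w * 4
  m2$params$head$fc2$b <- m2$params$head$fc2$b * 4
  expect_gt(max(classify(m2, f)$probs), max(cl$probs))
})

test_that("ablation variants alter only the intended stages", {
  x <- stack_images(list(rand_image(6)))
  for (v in c("backbone", "backbone_sc", "backbone_cbam", "schnet")) {
    m <- build_schnet(schnet_config(width_scale = 1 / 16, variant = v))
    fw <- schnet_forward(m, x)
    expect_equal(dim(fw$probs), c(1L, 2L))
    expect_lt(abs(sum(fw$probs) - 1), 1e-6)
    if (v %in% c("backbone", "backbone_sc")) {
      expect_null(fw$attention)
    } else {
      expect_false(is.null(fw$attention))
    }
  }
  expect_equal(schnet_conv_layer_count(schnet_config(variant = "backbone")), 9L)
})

test_that("parameter count at width 1 equals the frozen architecture total", {
  m <- fixture("m_full", build_schnet(schnet_config()))
  # backbone 8 convs + BN, 3 skip projections, CBAM (r=16), fusion, head
  expect_equal(schnet_num_params(m), 16986021)
})

test_that("eval-mode forward passes are deterministic and checkpoints round-trip", {
  m <- build_schnet(schnet_config(width_scale = 1 / 16, seed = 9))
  img <- rand_image(12)
  p1 <- schnet_forward(m, img)$probs
  p2 <- schnet_forward(m, img)$probs
  expect_identical(p1, p2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_schnet(m, path)
  m2 <- load_schnet(path)
  expect_identical(schnet_forward(m2, img)$probs, p1)
  expect_equal(m2$config$width_scale, 1 / 16)
  s <- schnet_summary(m)
  expect_equal(s$conv_layers, 12L)
  expect_equal(s$n_params, schnet_num_params(m))
})
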