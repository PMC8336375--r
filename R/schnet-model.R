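#' @useDynLib schnetr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

#' Build a Sch-net model
#'
#' Initializes all parameters of the configured architecture: four conv
#' blocks (conv-BN-ReLU twice, then 2x2 max pool), three skip projections
#' (average pool to the backbone output geometry, 3x3 conv, BN, ReLU),
#' CBAM channel+spatial attention, the 3x3 fusion convolution, and the
#' two-layer fully connected head with softmax output. Convolution and FC
#' weights use He-uniform initialization; BN starts at gamma 1, beta 0 with
#' identity running statistics.
#'
#' @param config A [schnet_config()].
#' @return A `schnet_model` list with `config`, `params` and BN running
#'   `state`.
#' @export
build_schnet <- function(config = schnet_config()) {
  validate_schnet_config(config)
  if (config$merge_mode == "add" &&
      config$skip_filters != config$block_filters[4]) {
    stop("config error: additive merging requires skip_filters == ",
         "block_filters[4]")
  }
  bf <- config$block_filters
  with_seed(config$seed, {
    params <- list()
    state <- list()
    c_in <- 1L
    for (i in 1:4) {
      params[[paste0("block", i)]] <- list(
        conv1 = init_conv(3L, c_in, bf[i]), bn1 = init_bn(bf[i]),
        conv2 = init_conv(3L, bf[i], bf[i]), bn2 = init_bn(bf[i]))
      state[[paste0("block", i)]] <- list(bn1 = init_bn_state(bf[i]),
                                          bn2 = init_bn_state(bf[i]))
      c_in <- bf[i]
    }
    if (config$variant %in% c("schnet", "backbone_sc")) {
      for (i in 1:3) {
        params[[paste0("skip", i)]] <- list(
          conv = init_conv(3L, bf[i], config$skip_filters),
          bn = init_bn(config$skip_filters))
        state[[paste0("skip", i)]] <- list(bn = init_bn_state(config$skip_filters))
      }
    }
    cbam_channels <- switch(config$variant,
      schnet = config$merged_channels,
      backbone_cbam = bf[4],
      NA_integer_)
    if (!is.na(cbam_channels)) {
      hidden <- max(1L, cbam_channels %/% config$cbam_reduction_ratio)
      if (cbam_channels < config$cbam_reduction_ratio) {
        warning("CBAM channel count ", cbam_channels,
                " below reduction ratio; MLP hidden size floored at 1")
      }
      k <- config$cbam_spatial_kernel
      params$cbam <- list(
        W1 = he_uniform(c(hidden, cbam_channels), cbam_channels),
        b1 = numeric(hidden),
        W2 = he_uniform(c(cbam_channels, hidden), hidden),
        b2 = numeric(cbam_channels),
        sp = init_conv(k, 2L, 1L))
    }
    fusion_in <- if (config$variant %in% c("schnet", "backbone_sc")) {
      config$merged_channels
    } else bf[4]
    params$fusion <- list(conv = init_conv(3L, fusion_in, config$fusion_filters),
                          bn = init_bn(config$fusion_filters))
    state$fusion <- list(bn = init_bn_state(config$fusion_filters))
    params$head <- list(
      fc1 = init_fc(config$fusion_filters, config$head_sizes[1]),
      fc2 = init_fc(config$head_sizes[1], config$head_sizes[2]))
    structure(list(config = config, params = params, state = state),
              class = "schnet_model")
  })
}

#' @export
print.schnet_model <- function(x, ...) {
  cat(sprintf("<schnet_model: %s, %d conv layers, %s parameters>\n",
              x$config$variant, schnet_conv_layer_count(x$config),
              format(schnet_num_params(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model A `schnet_model`.
#' @return Integer-valued count.
#' @export
schnet_num_params <- function(model) {
  sum(unlist(rapply(model$params, length, how = "unlist")))
}

#' Stack network input images into a batch tensor
#'
#' @param images A list of `net_input_image` matrices (or one matrix).
#' @return A `(H, W, 1, N)` array.
#' @export
stack_images <- function(images) {
  if (is.matrix(images)) images <- list(images)
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  x <- array(0, c(h, w, 1L, length(images)))
  for (i in seq_along(images)) x[, , 1L, i] <- unclass(images[[i]])
  x
}

check_input_shape <- function(model, x) {
  d <- dim(x)
  exp <- model$config$input_shape
  if (length(d) != 4L || d[1] != exp[1] || d[2] != exp[2] || d[3] != 1L) {
    stop("input shape mismatch: expected (", exp[1], ", ", exp[2],
         ") single-channel images, got (", paste(d, collapse = ", "), ")")
  }
}

#' Run the four-block convolutional backbone
#'
#' @param model A `schnet_model`.
#' @param x Input batch, `(H, W, 1, N)` array (see [stack_images()]).
#' @param train Use batch statistics and update BN running stats.
#' @param keep_cache Retain the per-layer caches needed for backprop.
#' @return A list with `final` (post-pool block-4 features, 512 channels at
#'   width 1, H/16 x W/16), `taps` (post-pool outputs of blocks 1-3),
#'   updated `state`, and optionally `cache`.
#' @export
forward_backbone <- function(model, x, train = FALSE, keep_cache = FALSE) {
  check_input_shape(model, x)
  P <- model$params; S <- model$state
  taps <- vector("list", 3L)
  cache <- list()
  h <- x
  for (i in 1:4) {
    bk <- paste0("block", i)
    u1 <- cbr_forward(h, P[[bk]]$conv1, P[[bk]]$bn1, S[[bk]]$bn1, train)
    u2 <- cbr_forward(u1$y, P[[bk]]$conv2, P[[bk]]$bn2, S[[bk]]$bn2, train)
    S[[bk]]$bn1 <- u1$state; S[[bk]]$bn2 <- u2$state
    mp <- cpp_maxpool2_forward(u2$y)
    h <- mp$y
    if (i < 4L) taps[[i]] <- h
    if (keep_cache) {
      cache[[bk]] <- list(u1 = u1$cache, u2 = u2$cache,
                          pool_idx = mp$idx, pre_pool_dim = dim(u2$y))
    }
  }
  list(final = h, taps = taps, state = S,
       cache = if (keep_cache) cache else NULL)
}

#' Merge backbone output with average-pooled skip projections
#'
#' Each tap is average-pooled to the backbone output geometry (strides 8,
#' 4, 2 for blocks 1-3), projected by its own 3x3 convolution to the skip
#' filter count with BN+ReLU, and concatenated channel-wise with the
#' backbone output (or added, under `merge_mode = "add"`).
#'
#' @param model A `schnet_model` whose variant includes skip connections.
#' @param final Backbone output tensor.
#' @param taps List of the three tap tensors from [forward_backbone()].
#' @inheritParams forward_backbone
#' @return List with `merged` (2048 channels at width 1), `state`, `cache`.
#' @export
apply_skip_connections <- function(model, final, taps, train = FALSE,
                                   keep_cache = FALSE) {
  P <- model$params; S <- model$state
  strides <- c(8L, 4L, 2L)
  proj <- vector("list", 3L)
  cache <- list(strides = strides)
  for (i in 1:3) {
    sk <- paste0("skip", i)
    pooled <- cpp_avgpool_forward(taps[[i]], strides[i])
    if (!all(dim(pooled)[1:2] == dim(final)[1:2])) {
      stop("internal consistency error: pooled skip ", i,
           " has spatial size ", paste(dim(pooled)[1:2], collapse = "x"),
           " but backbone output is ",
           paste(dim(final)[1:2], collapse = "x"))
    }
    u <- cbr_forward(pooled, P[[sk]]$conv, P[[sk]]$bn, S[[sk]]$bn, train)
    S[[sk]]$bn <- u$state
    proj[[i]] <- u$y
    if (keep_cache) cache[[sk]] <- u$cache
  }
  merged <- if (model$config$merge_mode == "concat") {
    concat_channels(c(proj, list(final)))
  } else {
    proj[[1]] + proj[[2]] + proj[[3]] + final
  }
  list(merged = merged, state = S, cache = if (keep_cache) cache else NULL)
}

# Spatial pooling statistics per channel: means, maxima and argmax of the
# (H*W) positions for every (channel, sample) pair.
channel_pool_stats <- function(f) {
  d <- dim(f)
  hw <- d[1] * d[2]
  fm <- f
  dim(fm) <- c(hw, d[3] * d[4])
  tm <- t(fm)
  amax <- max.col(tm, ties.method = "first")
  list(avg = matrix(.colMeans(fm, hw, ncol(fm)), d[3], d[4]),
       mx = matrix(tm[cbind(seq_len(nrow(tm)), amax)], d[3], d[4]),
       amax = amax)
}

# Channel pooling statistics per spatial position: mean/max over channels.
spatial_pool_stats <- function(f) {
  d <- dim(f)
  hw <- d[1] * d[2]
  B <- aperm(array(f, c(hw, d[3], d[4])), c(2L, 1L, 3L))
  Bm <- matrix(B, d[3], hw * d[4])
  tb <- t(Bm)
  amax <- max.col(tb, ties.method = "first")
  list(mean = matrix(.colMeans(Bm, d[3], ncol(Bm)), hw, d[4]),
       mx = matrix(tb[cbind(seq_len(nrow(tb)), amax)], hw, d[4]),
       amax = amax)
}

#' Convolutional block attention (channel then spatial)
#'
#' Channel attention: a shared two-layer MLP (bottleneck `C/r`) applied to
#' the spatial average- and max-pooled descriptors, summed and passed
#' through a sigmoid. Spatial attention: a `k x k` convolution over the
#' channel-wise mean and max maps of the channel-refined tensor, sigmoid
#' gated. The refined output is `f * Mc * Ms`.
#'
#' @param model A `schnet_model` whose variant includes CBAM.
#' @param f Input feature tensor `(H, W, C, N)`.
#' @param keep_cache Retain intermediates for backprop.
#' @return List with `channel_weights` (C x N, in (0,1)), `spatial_map`
#'   (H x W x 1 x N, in (0,1)), `refined`, and optionally `cache`.
#' @export
cbam <- function(model, f, keep_cache = FALSE) {
  pc <- model$params$cbam
  if (is.null(pc)) stop("model variant ", model$config$variant,
                        " has no CBAM stage")
  d <- dim(f)
  st <- channel_pool_stats(f)
  h_a <- pmax(pc$W1 %*% st$avg + pc$b1, 0)
  o_a <- pc$W2 %*% h_a + pc$b2
  h_m <- pmax(pc$W1 %*% st$mx + pc$b1, 0)
  o_m <- pc$W2 %*% h_m + pc$b2
  Mc <- sigmoid(o_a + o_m)
  f1 <- scale_by_channel(f, Mc)
  sp <- spatial_pool_stats(f1)
  sp_in <- array(0, c(d[1], d[2], 2L, d[4]))
  sp_in[, , 1L, ] <- sp$mean
  sp_in[, , 2L, ] <- sp$mx
  pad <- (model$config$cbam_spatial_kernel - 1L) %/% 2L
  z <- conv_forward(sp_in, pc$sp, pad)
  Ms <- sigmoid(z)
  refined <- scale_by_spatial(f1, Ms)
  list(channel_weights = Mc, spatial_map = Ms, refined = refined,
       cache = if (keep_cache) {
         list(f = f, st = st, h_a = h_a, h_m = h_m, Mc = Mc, f1 = f1,
              sp = sp, sp_in = sp_in, Ms = Ms, pad = pad, dims = d)
       } else NULL)
}

#' Fusion convolution, pooling and classification head
#'
#' The (attention-refined) feature tensor is convolved with the 512-filter
#' 3x3 fusion layer (BN+ReLU), globally average pooled, and passed through
#' FC 512 -> ReLU -> FC 2 -> softmax.
#'
#' @param model A `schnet_model`.
#' @param refined Feature tensor entering the fusion convolution.
#' @inheritParams forward_backbone
#' @return List with `probs` (N x 2), `logits`, `fusion_maps` (the post-ReLU
#'   fusion activations, the Grad-CAM target layer), `state`, `cache`.
#' @export
classify <- function(model, refined, train = FALSE, keep_cache = FALSE) {
  P <- model$params; S <- model$state
  fu <- cbr_forward(refined, P$fusion$conv, P$fusion$bn, S$fusion$bn, train)
  S$fusion$bn <- fu$state
  A <- fu$y
  d <- dim(A)
  hw <- d[1] * d[2]
  Am <- A
  dim(Am) <- c(hw, d[3] * d[4])
  g <- t(matrix(.colMeans(Am, hw, ncol(Am)), d[3], d[4]))   # N x C
  z1 <- g %*% t(P$head$fc1$w)
  z1 <- sweep(z1, 2L, P$head$fc1$b, `+`)
  h1 <- pmax(z1, 0)
  logits <- sweep(h1 %*% t(P$head$fc2$w), 2L, P$head$fc2$b, `+`)
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, fusion_maps = A, state = S,
       cache = if (keep_cache) {
         list(fu = fu$cache, g = g, h1 = h1, A_dim = d)
       } else NULL)
}

#' Full forward pass
#'
#' Composes backbone, skip connections, CBAM and the classification head
#' according to the configured ablation variant.
#'
#' @param model A `schnet_model`.
#' @param x Batch tensor `(H, W, 1, N)` or a list of images.
#' @inheritParams forward_backbone
#' @return List with `probs`, `logits`, `fusion_maps`, updated `state`, and
#'   optionally `cache` for [schnet_backward()].
#' @export
schnet_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  if (!is.array(x) || length(dim(x)) != 4L) x <- stack_images(x)
  variant <- model$config$variant
  bb <- forward_backbone(model, x, train, keep_cache)
  model$state <- bb$state
  merged <- bb$final
  sk <- NULL
  if (variant %in% c("schnet", "backbone_sc")) {
    sk <- apply_skip_connections(model, bb$final, bb$taps, train, keep_cache)
    model$state <- sk$state
    merged <- sk$merged
  }
  att <- NULL
  pre_fusion <- merged
  if (variant %in% c("schnet", "backbone_cbam")) {
    att <- cbam(model, merged, keep_cache)
    pre_fusion <- att$refined
  }
  cl <- classify(model, pre_fusion, train, keep_cache)
  model$state <- cl$state
  list(probs = cl$probs, logits = cl$logits, fusion_maps = cl$fusion_maps,
       attention = if (is.null(att)) NULL else {
         list(channel_weights = att$channel_weights,
              spatial_map = att$spatial_map)
       },
       state = model$state,
       cache = if (keep_cache) {
         list(x = x, backbone = bb$cache, taps = bb$taps, final = bb$final,
              skip = if (is.null(sk)) NULL else sk$cache,
              cbam = if (is.null(att)) NULL else att$cache,
              classify = cl$cache)
       } else NULL)
}

#' Class-probability predictions for a set of images
#'
#' @param model A `schnet_model`.
#' @param images List of `net_input_image` matrices or a batch tensor.
#' @param batch_size Evaluation batch size.
#' @return An N x 2 matrix of class probabilities (columns: control,
#'   patient).
#' @export
predict_schnet <- function(model, images, batch_size = 16L) {
  if (is.array(images) && length(dim(images)) == 4L) {
    n <- dim(images)[4]
    get <- function(idx) images[, , , idx, drop = FALSE]
  } else {
    if (is.matrix(images)) images <- list(images)
    n <- length(images)
    get <- function(idx) stack_images(images[idx])
  }
  out <- matrix(NA_real_, n, 2L)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- schnet_forward(model, get(idx), train = FALSE)$probs
  }
  colnames(out) <- c("control", "patient")
  out
}

#' Save / load a model checkpoint with its configuration embedded
#'
#' @param model A `schnet_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly; `load_schnet()` returns the model.
#' @export
save_schnet <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_schnet
#' @export
load_schnet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "schnet_model"))
  model
}

#' Architecture summary as a serializable list
#'
#' @param model A `schnet_model`.
#' @return A list (convertible to JSON) describing layers and shapes.
#' @export
schnet_summary <- function(model) {
  cfg <- model$config
  list(variant = cfg$variant, width_scale = cfg$width_scale,
       input_shape = cfg$input_shape,
       block_filters = cfg$block_filters,
       skip_filters = cfg$skip_filters,
       merged_channels = cfg$merged_channels,
       fusion_filters = cfg$fusion_filters,
       head_sizes = cfg$head_sizes,
       conv_layers = schnet_conv_layer_count(cfg),
       n_params = schnet_num_params(model))
}
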