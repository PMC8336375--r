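# Reverse-mode pass through the Sch-net graph. Gradients mirror the
# structure of model$params so the optimizer can walk both trees together.

cbam_backward <- function(model, cache, dref) {
  pc <- model$params$cbam
  d <- cache$dims
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]

  # refined = f1 * Ms  (Ms broadcast over channels)
  df1 <- scale_by_spatial(dref, cache$Ms)
  prod_m <- dref * cache$f1
  dim(prod_m) <- c(hw, C * N)
  # sum over channels at each (position, sample)
  pm <- aperm(array(prod_m, c(hw, C, N)), c(2L, 1L, 3L))
  dMs <- matrix(.colSums(matrix(pm, C, hw * N), C, hw * N), hw, N)
  dz <- dMs * as.vector(cache$Ms) * (1 - as.vector(cache$Ms))
  dz <- array(dz, c(d[1], d[2], 1L, N))
  cvb <- conv_backward(cache$sp_in, pc$sp, dz, cache$pad)
  dsp_in <- cvb$dx

  # channel-mean path: each channel receives dmean / C
  dmean <- matrix(dsp_in[, , 1L, ], hw, N)
  df1_m <- df1
  dim(df1_m) <- c(hw, C * N)
  df1_m <- df1_m + (dmean / C)[, rep(seq_len(N), each = C)]
  # channel-max path: scatter to the argmax channel
  dmx <- matrix(dsp_in[, , 2L, ], hw, N)
  pos <- seq_len(hw * N)
  row_i <- ((pos - 1L) %% hw) + 1L
  n_i <- ((pos - 1L) %/% hw) + 1L
  col_i <- cache$sp$amax + (n_i - 1L) * C
  df1_m[cbind(row_i, col_i)] <- df1_m[cbind(row_i, col_i)] + as.vector(dmx)
  dim(df1_m) <- d
  df1 <- df1_m

  # f1 = f * Mc
  df <- scale_by_channel(df1, cache$Mc)
  prod_c <- df1 * cache$f
  dim(prod_c) <- c(hw, C * N)
  dMc <- matrix(.colSums(prod_c, hw, C * N), C, N)
  dpre <- dMc * cache$Mc * (1 - cache$Mc)

  # shared MLP, average branch
  dh_a <- crossprod(pc$W2, dpre)
  dh_a[cache$h_a <= 0] <- 0
  dsa <- crossprod(pc$W1, dh_a)
  # shared MLP, max branch
  dh_m <- crossprod(pc$W2, dpre)
  dh_m[cache$h_m <= 0] <- 0
  dsm <- crossprod(pc$W1, dh_m)

  g <- list(
    W1 = dh_a %*% t(cache$st$avg) + dh_m %*% t(cache$st$mx),
    b1 = rowSums(dh_a) + rowSums(dh_m),
    W2 = dpre %*% t(cache$h_a) + dpre %*% t(cache$h_m),
    b2 = 2 * rowSums(dpre),
    sp = list(w = cvb$dw, b = cvb$db))

  # spatial average pooling spreads dsa / hw uniformly; the max descriptor
  # routes dsm to the argmax position of each (channel, sample)
  dfm <- df
  dim(dfm) <- c(hw, C * N)
  dfm <- dfm + matrix(rep(as.vector(dsa) / hw, each = hw), hw)
  dfm[cbind(cache$st$amax, seq_len(C * N))] <-
    dfm[cbind(cache$st$amax, seq_len(C * N))] + as.vector(dsm)
  dim(dfm) <- d
  list(df = dfm, g = g)
}

classify_backward <- function(model, cache, dlogits) {
  P <- model$params
  h1 <- cache$h1; g <- cache$g
  dW2 <- t(dlogits) %*% h1
  db2 <- colSums(dlogits)
  dh1 <- dlogits %*% P$head$fc2$w
  dh1[h1 <= 0] <- 0
  dW1 <- t(dh1) %*% g
  db1 <- colSums(dh1)
  dg <- dh1 %*% P$head$fc1$w          # N x C
  d <- cache$A_dim
  hw <- d[1] * d[2]
  dA <- array(rep(as.vector(t(dg)) / hw, each = hw), d)
  fb <- cbr_backward(dA, P$fusion$conv, cache$fu)
  list(dref = fb$dx,
       g = list(fusion = fb$g,
                head = list(fc1 = list(w = dW1, b = db1),
                            fc2 = list(w = dW2, b = db2))))
}

backbone_backward <- function(model, cache, dfinal, dtaps) {
  P <- model$params
  g <- list()
  dh <- dfinal
  for (i in 4:1) {
    bk <- paste0("block", i)
    ck <- cache[[bk]]
    if (i < 4L && !is.null(dtaps[[i]])) dh <- dh + dtaps[[i]]
    dpre <- cpp_maxpool2_backward(dh, ck$pool_idx, ck$pre_pool_dim)
    b2 <- cbr_backward(dpre, P[[bk]]$conv2, ck$u2)
    b1 <- cbr_backward(b2$dx, P[[bk]]$conv1, ck$u1)
    g[[bk]] <- list(conv1 = b1$g$conv, bn1 = b1$g$bn,
                    conv2 = b2$g$conv, bn2 = b2$g$bn)
    dh <- b1$dx
  }
  list(g = g, dx = dh)
}

#' Backward pass: gradients of the loss w.r.t. all parameters
#'
#' @param model A `schnet_model`.
#' @param cache Cache from `schnet_forward(..., keep_cache = TRUE)` run in
#'   training mode.
#' @param dlogits Gradient of the loss w.r.t. the logits (N x 2).
#' @return A nested gradient list mirroring `model$params`.
#' @export
schnet_backward <- function(model, cache, dlogits) {
  variant <- model$config$variant
  cb <- classify_backward(model, cache$classify, dlogits)
  grads <- cb$g
  dmerged <- cb$dref
  if (variant %in% c("schnet", "backbone_cbam")) {
    ab <- cbam_backward(model, cache$cbam, dmerged)
    grads$cbam <- ab$g
    dmerged <- ab$df
  }
  dtaps <- vector("list", 3L)
  if (variant %in% c("schnet", "backbone_sc")) {
    cs <- c(rep(model$config$skip_filters, 3L), dim(cache$final)[3])
    parts <- if (model$config$merge_mode == "concat") {
      split_channels(dmerged, cs)
    } else {
      list(dmerged, dmerged, dmerged, dmerged)
    }
    dfinal <- parts[[4]]
    strides <- cache$skip$strides
    for (i in 1:3) {
      sk <- paste0("skip", i)
      sb <- cbr_backward(parts[[i]], model$params[[sk]]$conv, cache$skip[[sk]])
      grads[[sk]] <- list(conv = sb$g$conv, bn = sb$g$bn)
      dtaps[[i]] <- cpp_avgpool_backward(sb$dx, strides[i])
    }
  } else {
    dfinal <- dmerged
  }
  bb <- backbone_backward(model, cache$backbone, dfinal, dtaps)
  grads[c("block1", "block2", "block3", "block4")] <-
    bb$g[c("block1", "block2", "block3", "block4")]
  grads
}
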