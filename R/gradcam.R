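#' Grad-CAM heatmap from the fusion convolution
#'
#' The target layer is the network's last convolutional stage: the 512-filter
#' fusion convolution output after BN+ReLU. The class score is the
#' pre-softmax logit of `target_class`. Because the head is a global average
#' pool followed by two FC layers, the gradient of the logit w.r.t. the
#' activation map of channel k is spatially constant and the channel weight
#' is alpha_k = (dlogit/dg_k) / (H*W), where g is the pooled vector; the
#' heatmap is ReLU(sum_k alpha_k A_k), bilinearly upsampled to the input
#' geometry.
#'
#' @param model A trained `schnet_model`.
#' @param img A `net_input_image` (single image).
#' @param target_class 0 (control) or 1 (patient); default: predicted class.
#' @return A `gradcam_heatmap`: `values` (last-conv resolution, >= 0),
#'   `upsampled` (input-geometry raw values), `norm` (upsampled, scaled to
#'   `[0, 1]` for rendering), `target_class`, `probs`.
#' @export
grad_cam <- function(model, img, target_class = NULL) {
  fw <- schnet_forward(model, stack_images(img), train = FALSE)
  if (is.null(target_class)) {
    target_class <- which.max(fw$probs[1L, ]) - 1L
  }
  if (!target_class %in% c(0L, 1L)) {
    stop("target_class out of range: must be 0 or 1, got ", target_class)
  }
  hm <- gradcam_core(fw$fusion_maps, model$params$head, target_class,
                     model$config$input_shape)
  hm$probs <- fw$probs[1L, ]
  hm
}

#' Grad-CAM core: heatmap from target-layer activations and head weights
#'
#' Computes the class-activation map given the last-conv activations `A`
#' and the pooled head (GAP, FC+ReLU, FC). Exposed separately so the
#' closed-form behavior can be verified on hand-constructed heads.
#'
#' @param A Activation tensor `(H, W, C, 1)` of the target layer.
#' @param head List with `fc1 = list(w, b)` and `fc2 = list(w, b)`.
#' @param target_class 0 or 1 (row `target_class + 1` of `fc2$w`).
#' @param out_shape Upsampled geometry `(rows, cols)`.
#' @return A `gradcam_heatmap` (without `probs`).
#' @export
gradcam_core <- function(A, head, target_class, out_shape = c(128L, 256L)) {
  d <- dim(A)
  hw <- d[1] * d[2]
  g <- matrix(.colMeans(matrix(A, hw, d[3]), hw, d[3]), 1L)   # 1 x C pooled
  h1 <- pmax(g %*% t(head$fc1$w) + rep(head$fc1$b, each = 1L), 0)
  w2c <- head$fc2$w[target_class + 1L, ]
  dh1 <- w2c * (h1[1L, ] > 0)
  dg <- as.numeric(t(head$fc1$w) %*% dh1)      # dlogit / dg, length C
  alpha <- dg / hw
  hm <- matrix(0, d[1], d[2])
  hm[] <- pmax(matrix(A, hw, d[3]) %*% alpha, 0)
  ups <- if (all(dim(hm) == out_shape)) hm else {
    matrix(as.numeric(EBImage::resize(hm, w = out_shape[1],
                                      h = out_shape[2])),
           out_shape[1], out_shape[2])
  }
  ups <- pmax(ups, 0)
  mx <- max(ups)
  structure(list(values = hm, upsampled = ups,
                 norm = if (mx > 0) ups / mx else ups,
                 target_class = as.integer(target_class)),
            class = "gradcam_heatmap")
}

#' Fraction of Grad-CAM heat above a frequency cutoff
#'
#' Heatmap rows map linearly to frequency (row 1 = 0 Hz, last row =
#' Nyquist, matching the network input geometry).
#'
#' @param hm A `gradcam_heatmap` (or non-negative matrix with frequency
#'   rows).
#' @param cutoff_hz Frequency cutoff, within the Nyquist range.
#' @param sample_rate Sampling rate defining the Nyquist frequency.
#' @return Fraction of total heat mass at frequencies above the cutoff;
#'   0 (with a warning) for an all-zero heatmap.
#' @export
band_energy_share <- function(hm, cutoff_hz, sample_rate = 44100) {
  v <- if (inherits(hm, "gradcam_heatmap")) hm$upsampled else hm
  nyq <- sample_rate / 2
  stopifnot(cutoff_hz >= 0, cutoff_hz <= nyq)
  total <- sum(v)
  if (total <= 0) {
    warning("all-zero heatmap: band energy share defined as 0")
    return(0)
  }
  freq <- seq(0, nyq, length.out = nrow(v))
  sum(v[freq > cutoff_hz, , drop = FALSE]) / total
}

viridis_ramp <- function(n = 256L) {
  grDevices::colorRamp(c("#440154", "#31688E", "#35B779", "#FDE725"))(
    seq(0, 1, length.out = n)) / 255
}

#' Render a spectrogram image and its Grad-CAM overlay side by side
#'
#' Grayscale input on the left, input blended with a perceptually ordered
#' colormap of the heatmap at 40% alpha on the right; low frequencies at
#' the bottom.
#'
#' @param img The `net_input_image` the heatmap was computed from.
#' @param hm A `gradcam_heatmap`.
#' @param path Output PNG path.
#' @param alpha Overlay opacity.
#' @return `path`, invisibly.
#' @export
gradcam_overlay <- function(img, hm, path, alpha = 0.4) {
  g <- unclass(img)
  g <- (g - min(g)) / max(max(g) - min(g), 1e-12)
  ramp <- viridis_ramp()
  idx <- pmin(pmax(round(hm$norm * 255) + 1L, 1L), 256L)
  h <- nrow(g); w <- ncol(g)
  rgb_right <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    rgb_right[, , ch] <- (1 - alpha) * g + alpha * matrix(ramp[idx, ch], h, w)
  }
  out <- array(0, c(h, 2L * w + 4L, 3L))
  for (ch in 1:3) {
    out[, seq_len(w), ch] <- g
    out[, w + 4L + seq_len(w), ch] <- rgb_right[, , ch]
  }
  png::writePNG(out[rev(seq_len(h)), , ], path)
  invisible(path)
}

#' Band-localization study over a set of clips
#'
#' Computes the above-cutoff Grad-CAM heat share for every image and tests
#' whether control-class clips place more heat above the cutoff than
#' patient-class clips (one-sided Wilcoxon rank-sum test), mirroring the
#' qualitative finding that pathological speech concentrates its
#' discriminative energy below 5 kHz.
#'
#' @param model A trained `schnet_model`.
#' @param images List of `net_input_image` matrices.
#' @param labels 0/1 labels.
#' @param cutoff_hz Band cutoff (default 5000 Hz).
#' @param sample_rate Sampling rate of the source audio.
#' @param target Heatmap class: `"predicted"` (default) or `"label"`.
#' @return A list with `shares` data frame (label, share), class means,
#'   and the one-sided `p_value` for control > patient.
#' @export
gradcam_band_study <- function(model, images, labels, cutoff_hz = 5000,
                               sample_rate = 44100, target = "predicted") {
  target <- match.arg(target, c("predicted", "label"))
  shares <- vapply(seq_along(images), function(i) {
    tc <- if (target == "label") as.integer(labels[i]) else NULL
    hm <- grad_cam(model, images[[i]], target_class = tc)
    band_energy_share(hm, cutoff_hz, sample_rate)
  }, numeric(1))
  s0 <- shares[labels == 0L]; s1 <- shares[labels == 1L]
  pv <- stats::wilcox.test(s0, s1, alternative = "greater", exact = FALSE)$p.value
  list(shares = data.frame(label = as.integer(labels), share = shares),
       mean_control = mean(s0), mean_patient = mean(s1), p_value = pv)
}
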