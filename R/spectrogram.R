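#' Compute a log-magnitude STFT spectrogram
#'
#' Frames the waveform (no centering; frames start at sample 1 and advance
#' by `hop_length`), applies the window, takes the FFT of each frame, and
#' returns the one-sided magnitude spectrum in dB, floored at
#' `max(values) - floor_db`.
#'
#' @param clip An [audio_clip].
#' @param n_fft FFT size; power of two, at least 256.
#' @param hop_length Hop between frame starts, in samples.
#' @param window_name `"hann"` (default), `"hamming"` or `"rect"`.
#' @param floor_db Dynamic range below the maximum retained before flooring.
#' @return A `spectrogram` object: `values` (`n_fft/2 + 1` frequency rows by
#'   `n_frames` time columns, dB), `freq_axis` (Hz per row), `time_axis`
#'   (frame-center seconds), and `stft_params`.
#' @export
compute_spectrogram <- function(clip, n_fft = 2048L, hop_length = 512L,
                                window_name = "hann", floor_db = 80) {
  stopifnot(inherits(clip, "audio_clip"), hop_length >= 1)
  if (n_fft < 256 || bitwAnd(n_fft, n_fft - 1L) != 0) {
    stop("n_fft must be a power of two >= 256, got ", n_fft)
  }
  x <- clip$samples
  if (length(x) < n_fft) {
    stop("clip too short for STFT: ", length(x), " samples, need at least ",
         n_fft)
  }
  win <- switch(window_name,
    hann = signal::hanning(n_fft),
    hamming = signal::hamming(n_fft),
    rect = rep(1, n_fft),
    stop("unknown window: ", window_name)
  )
  n_frames <- 1L + (length(x) - n_fft) %/% hop_length
  starts <- (seq_len(n_frames) - 1L) * hop_length
  frames <- matrix(x[outer(seq_len(n_fft), starts, `+`)], nrow = n_fft)
  spec <- stats::mvfft(frames * win)[seq_len(n_fft / 2L + 1L), , drop = FALSE]
  mag_db <- 20 * log10(pmax(Mod(spec), 1e-12))
  mag_db <- pmax(mag_db, max(mag_db) - floor_db)
  structure(
    list(values = mag_db,
         freq_axis = (0:(n_fft / 2L)) * clip$sample_rate / n_fft,
         time_axis = (starts + n_fft / 2) / clip$sample_rate,
         stft_params = list(n_fft = n_fft, hop_length = hop_length,
                            window_name = window_name,
                            sample_rate = clip$sample_rate),
         id = clip$id),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d bins x %d frames, n_fft=%d hop=%d @ %d Hz>\n",
              nrow(x$values), ncol(x$values), x$stft_params$n_fft,
              x$stft_params$hop_length, x$stft_params$sample_rate))
  invisible(x)
}

#' Convert a spectrogram to the fixed network input image
#'
#' Bilinear resize of the dB matrix to 128 frequency rows by 256 time
#' columns, then per-image standardization to zero mean and unit variance.
#' A constant image standardizes to all zeros.
#'
#' @param spec A `spectrogram`.
#' @param height,width Network input geometry (frequency x time).
#' @return A `net_input_image`: a `height x width` matrix with attributes
#'   `provenance` (clip id) and `freq_axis` (Hz per row).
#' @export
to_net_input <- function(spec, height = 128L, width = 256L) {
  stopifnot(inherits(spec, "spectrogram"))
  v <- spec$values
  px <- if (all(dim(v) == c(height, width))) v else {
    EBImage::resize(v, w = height, h = width)
  }
  s <- stats::sd(px)
  px <- if (s < 1e-12) matrix(0, height, width) else (px - mean(px)) / s
  structure(px, class = c("net_input_image", "matrix"),
            provenance = spec$id,
            freq_axis = seq(0, max(spec$freq_axis), length.out = height))
}

#' Default augmentation policy
#'
#' The six training-time transforms: pad-and-random-crop, random rotation,
#' random rescale, additive Gaussian noise, frequency masking and time
#' masking. Magnitudes default to mild perturbations; masks are filled with
#' the image mean (about zero on standardized inputs).
#'
#' @param crop_pad_px Padding before the random crop, in pixels.
#' @param rotation_max_deg Rotation drawn uniformly in `[-max, max]` degrees.
#' @param rescale_range Scale factor range `(lo, hi)`.
#' @param gauss_sigma Noise sd as a fraction of the image sd.
#' @param freq_mask_max_F Maximum frequency-mask height in rows.
#' @param time_mask_max_T Maximum time-mask width in columns.
#' @param n_freq_masks,n_time_masks Number of masks of each kind.
#' @param enabled If `FALSE`, [augment()] is the identity.
#' @param rng_seed Seed controlling every random draw of the policy.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(crop_pad_px = 8L, rotation_max_deg = 5,
                                rescale_range = c(0.9, 1.1),
                                gauss_sigma = 0.05,
                                freq_mask_max_F = 16L, time_mask_max_T = 32L,
                                n_freq_masks = 1L, n_time_masks = 1L,
                                enabled = TRUE, rng_seed = 1L) {
  stopifnot(crop_pad_px >= 0, rotation_max_deg >= 0, gauss_sigma >= 0,
            rescale_range[1] <= rescale_range[2],
            freq_mask_max_F >= 0, time_mask_max_T >= 0)
  structure(list(crop_pad_px = as.integer(crop_pad_px),
                 rotation_max_deg = rotation_max_deg,
                 rescale_range = rescale_range, gauss_sigma = gauss_sigma,
                 freq_mask_max_F = as.integer(freq_mask_max_F),
                 time_mask_max_T = as.integer(time_mask_max_T),
                 n_freq_masks = as.integer(n_freq_masks),
                 n_time_masks = as.integer(n_time_masks),
                 enabled = enabled, rng_seed = rng_seed),
            class = "augmentation_policy")
}

pad_center_crop <- function(m, height, width, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, height, width)
  src_r <- seq_len(min(h, height)) + max(0L, (h - height) %/% 2L)
  src_c <- seq_len(min(w, width)) + max(0L, (w - width) %/% 2L)
  dst_r <- seq_len(min(h, height)) + max(0L, (height - h) %/% 2L)
  dst_c <- seq_len(min(w, width)) + max(0L, (width - w) %/% 2L)
  out[dst_r, dst_c] <- m[src_r, src_c]
  out
}

#' Apply the augmentation policy to a network input image
#'
#' Transforms are applied in a fixed order: crop, rotation, rescale,
#' Gaussian noise, frequency masks, time masks. All randomness derives from
#' `policy$rng_seed`; a disabled policy returns the input unchanged. The
#' output geometry always equals the input geometry.
#'
#' @param img A `net_input_image` (or plain matrix).
#' @param policy An [augmentation_policy()].
#' @return The augmented image, same class and shape.
#' @export
augment <- function(img, policy) {
  stopifnot(inherits(policy, "augmentation_policy"))
  if (!policy$enabled) return(img)
  h <- nrow(img); w <- ncol(img)
  att <- attributes(img)
  m <- unclass(img)
  attributes(m) <- list(dim = c(h, w))
  fill <- mean(m)
  with_seed(policy$rng_seed, {
    if (policy$crop_pad_px > 0) {
      p <- policy$crop_pad_px
      padded <- matrix(fill, h + 2L * p, w + 2L * p)
      padded[p + seq_len(h), p + seq_len(w)] <- m
      r0 <- sample.int(2L * p + 1L, 1L) - 1L
      c0 <- sample.int(2L * p + 1L, 1L) - 1L
      m <- padded[r0 + seq_len(h), c0 + seq_len(w)]
    }
    if (policy$rotation_max_deg > 0) {
      ang <- stats::runif(1, -policy$rotation_max_deg, policy$rotation_max_deg)
      m <- EBImage::rotate(m, ang, output.dim = c(h, w), bg.col = fill)
      m <- matrix(as.numeric(m), h, w)
    }
    if (diff(policy$rescale_range) > 0 || any(policy$rescale_range != 1)) {
      f <- stats::runif(1, policy$rescale_range[1], policy$rescale_range[2])
      if (abs(f - 1) > 1e-9) {
        nh <- max(1L, round(h * f)); nw <- max(1L, round(w * f))
        m <- matrix(as.numeric(EBImage::resize(m, w = nh, h = nw)), nh, nw)
        m <- pad_center_crop(m, h, w, fill)
      }
    }
    if (policy$gauss_sigma > 0) {
      m <- m + stats::rnorm(length(m), sd = policy$gauss_sigma * stats::sd(m))
    }
    if (policy$n_freq_masks > 0 && policy$freq_mask_max_F > 0) {
      for (i in seq_len(policy$n_freq_masks)) {
        fw <- sample.int(policy$freq_mask_max_F + 1L, 1L) - 1L
        if (fw > 0) {
          r0 <- sample.int(h - fw + 1L, 1L)
          m[r0:(r0 + fw - 1L), ] <- fill
        }
      }
    }
    if (policy$n_time_masks > 0 && policy$time_mask_max_T > 0) {
      for (i in seq_len(policy$n_time_masks)) {
        tw <- sample.int(policy$time_mask_max_T + 1L, 1L) - 1L
        if (tw > 0) {
          c0 <- sample.int(w - tw + 1L, 1L)
          m[, c0:(c0 + tw - 1L)] <- fill
        }
      }
    }
  })
  attributes(m) <- att
  m
}

#' Export a spectrogram or image matrix as a PNG for inspection
#'
#' @param m A `spectrogram`, `net_input_image`, or matrix (frequency rows
#'   ascending from row 1).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_png <- function(m, path) {
  v <- if (inherits(m, "spectrogram")) m$values else unclass(m)
  v <- (v - min(v)) / max(max(v) - min(v), 1e-12)
  # flip so low frequencies render at the bottom
  png::writePNG(v[rev(seq_len(nrow(v))), , drop = FALSE], path)
  invisible(path)
}
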