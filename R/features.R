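#' Frame analysis configuration
#'
#' @param frame_length_s Frame length in seconds (default 25 ms).
#' @param hop_s Hop between frame starts (default 10 ms).
#' @param window_name `"hamming"`, `"hann"` or `"rect"`.
#' @return A `frame_spec` list.
#' @export
frame_spec <- function(frame_length_s = 0.025, hop_s = 0.010,
                       window_name = "hamming") {
  stopifnot(hop_s <= frame_length_s, hop_s > 0)
  structure(list(frame_length_s = frame_length_s, hop_s = hop_s,
                 window_name = window_name),
            class = "frame_spec")
}

frame_window <- function(n, window_name) {
  switch(window_name,
         hamming = as.numeric(signal::hamming(n)),
         hann = as.numeric(signal::hanning(n)),
         rect = rep(1, n),
         stop("unknown window: ", window_name))
}

# Slice a clip into a (frame_len x n_frames) matrix plus frame-start times.
frame_signal <- function(clip, fs) {
  sr <- clip$sample_rate
  flen <- max(2L, round(fs$frame_length_s * sr))
  hop <- max(1L, round(fs$hop_s * sr))
  x <- clip$samples
  if (length(x) < flen) {
    stop("clip too short for framing: ", length(x), " samples, need ", flen)
  }
  n_frames <- 1L + (length(x) - flen) %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  list(frames = matrix(x[outer(seq_len(flen), starts, `+`)], nrow = flen),
       times = starts / sr, frame_len = flen, hop = hop, sr = sr)
}

#' Short-term energy per frame with distribution summary
#'
#' Frame energy is the sum of squared (windowed) samples. The summary
#' vector holds mean, sd, max, min, skewness and excess kurtosis of the
#' per-frame energies.
#'
#' @param clip An [audio_clip].
#' @param fs A [frame_spec()] (rectangular window by default, so energies
#'   are raw sums of squares).
#' @return List with `energies`, `times`, `summary` (named length-6 vector).
#' @export
short_term_energy <- function(clip, fs = frame_spec(window_name = "rect")) {
  fr <- frame_signal(clip, fs)
  w <- frame_window(fr$frame_len, fs$window_name)
  e <- .colSums((fr$frames * w)^2, fr$frame_len, ncol(fr$frames))
  list(energies = e, times = fr$times,
       summary = c(mean = mean(e), sd = stats::sd(e), max = max(e),
                   min = min(e), skewness = sample_skewness(e),
                   kurtosis = sample_kurtosis(e)))
}

#' Autocorrelation pitch track
#'
#' Per frame, the normalized autocorrelation is evaluated over the lag band
#' corresponding to `f0_range`; the frame is voiced when the peak exceeds
#' 0.3 (and carries non-negligible energy), with F0 the sampling rate over
#' the peak lag. Unvoiced frames report 0.
#'
#' @param clip An [audio_clip].
#' @param fs A [frame_spec()].
#' @param f0_range Fundamental-frequency search range in Hz.
#' @param voicing_threshold Normalized-autocorrelation voicing threshold.
#' @return List with `f0` (per frame; 0 = unvoiced), `times`, and
#'   `summary` = (mean, sd, range, voiced fraction) over voiced frames.
#' @export
pitch_track <- function(clip, fs = frame_spec(window_name = "rect"),
                        f0_range = c(75, 500), voicing_threshold = 0.3) {
  sr <- clip$sample_rate
  stopifnot(f0_range[2] <= sr / 2, f0_range[1] > 0)
  fr <- frame_signal(clip, fs)
  lag_min <- max(2L, floor(sr / f0_range[2]))
  lag_max <- min(fr$frame_len - 1L, ceiling(sr / f0_range[1]))
  if (lag_max <= lag_min) stop("f0_range incompatible with frame length")
  frames <- fr$frames - rep(colMeans(fr$frames), each = fr$frame_len)
  nfft <- 2^ceiling(log2(2L * fr$frame_len))
  padded <- rbind(frames, matrix(0, nfft - fr$frame_len, ncol(frames)))
  ac <- Re(stats::mvfft(Mod(stats::mvfft(padded))^2, inverse = TRUE)) / nfft
  r0 <- ac[1L, ]
  band <- ac[(lag_min:lag_max) + 1L, , drop = FALSE]
  peak_rel <- max.col(t(band), ties.method = "first")
  peak_val <- band[cbind(peak_rel, seq_len(ncol(band)))] / pmax(r0, 1e-20)
  energy <- r0 / fr$frame_len
  voiced <- peak_val >= voicing_threshold & energy > 1e-8
  f0 <- ifelse(voiced, sr / (lag_min + peak_rel - 1L), 0)
  vf <- mean(voiced)
  summ <- if (!any(voiced)) {
    warning("no voiced frames detected; pitch summary is all zeros")
    c(mean = 0, sd = 0, range = 0, voiced_fraction = 0)
  } else {
    v <- f0[voiced]
    c(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
      range = diff(range(v)), voiced_fraction = vf)
  }
  list(f0 = f0, times = fr$times, summary = summ)
}

#' Energy-based voice activity detection
#'
#' Non-overlapping 10 ms frames are classified as speech when their energy
#' exceeds `threshold_db` relative to the loudest frame; pauses shorter
#' than `min_pause_s` are closed (absorbed into speech) and speech runs
#' shorter than `min_segment_s` removed, then contiguous runs become the
#' voiced segments and pauses.
#'
#' @param clip An [audio_clip].
#' @param threshold_db Speech threshold in dB relative to the maximum frame.
#' @param min_segment_s Minimum voiced-segment duration retained.
#' @param min_pause_s Minimum pause duration retained.
#' @param frame_s VAD frame length (= hop; frames do not overlap).
#' @return A `vad_segmentation`: `voiced_segments` and `pauses` (two-column
#'   start/end matrices in seconds), `frame_speech`, `frame_energy_db`,
#'   `frame_times`, `duration_s`, and the parameters used.
#' @export
vad_segment <- function(clip, threshold_db = -35, min_segment_s = 0.1,
                        min_pause_s = 0.15, frame_s = 0.010) {
  sr <- clip$sample_rate
  flen <- max(1L, round(frame_s * sr))
  n_frames <- max(1L, length(clip$samples) %/% flen)
  x <- clip$samples[seq_len(n_frames * flen)]
  e <- .colSums(matrix(x^2, flen, n_frames), flen, n_frames)
  e_db <- 10 * log10(pmax(e, 1e-20) / max(max(e), 1e-20))
  # a clip that never rises above the numerical floor is all silence
  speech <- if (max(e) / flen < 1e-10) rep(FALSE, n_frames)
            else e_db > threshold_db
  speech <- close_runs(speech, FALSE, round(min_pause_s / frame_s))
  speech <- close_runs(speech, TRUE, round(min_segment_s / frame_s))
  dur <- length(clip$samples) / sr
  segs <- runs_to_segments(speech, frame_s, dur)
  structure(list(voiced_segments = segs$on, pauses = segs$off,
                 frame_speech = speech, frame_energy_db = e_db,
                 frame_times = (seq_len(n_frames) - 1L) * frame_s,
                 duration_s = dur,
                 params = list(threshold_db = threshold_db,
                               min_segment_s = min_segment_s,
                               min_pause_s = min_pause_s, frame_s = frame_s)),
            class = "vad_segmentation")
}

# Flip runs of value `val` shorter than min_len to the other state.
close_runs <- function(flags, val, min_len) {
  if (min_len <= 1L || length(flags) == 0L) return(flags)
  r <- rle(flags)
  interior <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
  flip <- r$values == val & r$lengths < min_len &
    (val == TRUE | interior)  # leading/trailing silence is never closed
  r$values[flip] <- !val
  inverse.rle(r)
}

runs_to_segments <- function(flags, frame_s, duration_s) {
  r <- rle(flags)
  ends_frame <- cumsum(r$lengths)
  starts_frame <- ends_frame - r$lengths
  start_s <- starts_frame * frame_s
  end_s <- pmin(ends_frame * frame_s, duration_s)
  # the final frame block extends to the true clip end
  end_s[length(end_s)] <- duration_s
  on <- cbind(start = start_s[r$values], end = end_s[r$values])
  off <- cbind(start = start_s[!r$values], end = end_s[!r$values])
  list(on = on, off = off)
}

#' The five fluency features
#'
#' Total recording time, total voiced length, voiced ratio, maximum pause
#' duration, and mean syllable length (total voiced time over the count of
#' syllable nuclei, which are prominent peaks of the smoothed frame-energy
#' contour inside voiced segments: minimum prominence 3 dB, minimum
#' separation 0.1 s).
#'
#' @param seg A `vad_segmentation` from [vad_segment()].
#' @return Named length-5 numeric vector.
#' @export
fluency_features <- function(seg) {
  total <- seg$duration_s
  voiced <- if (nrow(seg$voiced_segments)) {
    sum(seg$voiced_segments[, 2L] - seg$voiced_segments[, 1L])
  } else 0
  max_pause <- if (nrow(seg$pauses)) {
    max(seg$pauses[, 2L] - seg$pauses[, 1L])
  } else 0
  nuc <- count_syllable_nuclei(seg)
  mean_syll <- if (nuc == 0L) {
    if (voiced > 0) warning("no syllable nuclei found; mean syllable length 0")
    0
  } else voiced / nuc
  c(total_time = total, voiced_time = voiced,
    voiced_ratio = voiced / total, max_pause = max_pause,
    mean_syllable = mean_syll)
}

# Syllable nuclei: energy humps of the smoothed contour inside each voiced
# segment. A segment is split at interior energy valleys at least
# `min_prominence_db` below the flanking maxima (and at least
# `min_distance_s` apart); each resulting hump is one nucleus, so a
# retained voiced segment always carries at least one syllable.
count_syllable_nuclei <- function(seg, min_prominence_db = 3,
                                  min_distance_s = 0.1) {
  e <- seg$frame_energy_db
  if (length(e) < 1L || !any(seg$frame_speech)) return(0L)
  sm <- stats::filter(e, rep(1 / 5, 5L), sides = 2L)
  sm[is.na(sm)] <- e[is.na(sm)]
  sm <- as.numeric(sm)
  min_gap <- max(1L, round(min_distance_s / seg$params$frame_s))
  r <- rle(seg$frame_speech)
  seg_ends <- cumsum(r$lengths)
  seg_starts <- seg_ends - r$lengths + 1L
  total <- 0L
  for (si in which(r$values)) {
    s <- sm[seg_starts[si]:seg_ends[si]]
    m <- length(s)
    valleys <- integer(0)
    if (m >= 3L) {
      cand <- which(diff(sign(diff(s))) > 0) + 1L    # interior local minima
      depth <- vapply(cand, function(v) {
        min(max(s[1:v]), max(s[v:m])) - s[v]
      }, numeric(1))
      cand <- cand[depth >= min_prominence_db]
      if (length(cand)) {
        # deepest valley first; suppress close neighbours
        cand <- cand[order(s[cand])]
        kept <- integer(0)
        for (v in cand) {
          if (!length(kept) || all(abs(kept - v) >= min_gap)) {
            kept <- c(kept, v)
          }
        }
        valleys <- kept
      }
    }
    total <- total + length(valleys) + 1L
  }
  total
}

#' Long-term average spectrum
#'
#' The time average of the dB spectrogram, reduced to `n_bins_out`
#' frequency bands by averaging groups of adjacent bins.
#'
#' @param spec A `spectrogram`.
#' @param n_bins_out Number of output bands.
#' @return Named numeric vector of band-averaged dB levels; names carry the
#'   band-center frequencies.
#' @export
ltas <- function(spec, n_bins_out = 128L) {
  stopifnot(inherits(spec, "spectrogram"), ncol(spec$values) >= 1L)
  avg <- rowMeans(spec$values)
  grp <- ceiling(seq_along(avg) / (length(avg) / n_bins_out))
  grp <- pmin(grp, n_bins_out)
  out <- as.numeric(tapply(avg, grp, mean))
  centers <- as.numeric(tapply(spec$freq_axis, grp, mean))
  stats::setNames(out, sprintf("ltas_%.0fHz", centers))
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#' @noRd
mel_filterbank <- function(n_filters, n_fft, sr, fmin = 0, fmax = sr / 2) {
  mels <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2L)
  hz <- mel_to_hz(mels)
  bins <- (0:(n_fft / 2L)) * sr / n_fft
  fb <- matrix(0, n_filters, length(bins))
  for (i in seq_len(n_filters)) {
    lo <- hz[i]; ce <- hz[i + 1L]; hi <- hz[i + 2L]
    up <- (bins - lo) / max(ce - lo, 1e-9)
    down <- (hi - bins) / max(hi - ce, 1e-9)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Orthonormal DCT-II matrix (first `n_coeffs` rows)
#' @noRd
dct_matrix <- function(n_coeffs, n_in) {
  M <- sqrt(2 / n_in) * outer(0:(n_coeffs - 1L), seq_len(n_in) - 0.5,
                              function(i, j) cos(pi * i * j / n_in))
  M[1L, ] <- M[1L, ] / sqrt(2)
  M
}

frame_power_spectrum <- function(clip, fs, n_fft = 2048L) {
  fr <- frame_signal(clip, fs)
  w <- frame_window(fr$frame_len, fs$window_name)
  padded <- rbind(fr$frames * w, matrix(0, n_fft - fr$frame_len,
                                        ncol(fr$frames)))
  pw <- Mod(stats::mvfft(padded)[seq_len(n_fft / 2L + 1L), , drop = FALSE])^2
  list(power = pw, sr = fr$sr, n_fft = n_fft)
}

#' Mel-frequency cepstral coefficients
#'
#' Frame power spectra pass through a triangular mel filterbank, log
#' compression, and an orthonormal DCT-II; the first `n_coeffs`
#' coefficients are kept. The per-clip summary stacks the mean and sd of
#' each coefficient across frames.
#'
#' @param clip An [audio_clip].
#' @param n_filters Number of mel filters.
#' @param n_coeffs Number of cepstral coefficients retained.
#' @param fs A [frame_spec()].
#' @return List with `coeffs` (n_coeffs x n_frames) and `summary`
#'   (length `2 * n_coeffs`).
#' @export
mfcc <- function(clip, n_filters = 26L, n_coeffs = 13L, fs = frame_spec()) {
  ps <- frame_power_spectrum(clip, fs)
  fb <- mel_filterbank(n_filters, ps$n_fft, ps$sr)
  loge <- log(pmax(fb %*% ps$power, 1e-10))
  cc <- dct_matrix(n_coeffs, n_filters) %*% loge
  rownames(cc) <- paste0("c", seq_len(n_coeffs))
  summarize_coeffs(cc, "mfcc")
}

#' Equivalent rectangular bandwidth at frequency `f` (Glasberg-Moore)
#'
#' `ERB(f) = 24.7 (4.37 f / 1000 + 1)` Hz.
#'
#' @param f Frequency in Hz.
#' @return Bandwidth in Hz.
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

hz_to_erb_rate <- function(f) 21.4 * log10(0.00437 * f + 1)
erb_rate_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' ERB-spaced gammatone center frequencies
#'
#' @param n_filters Number of filters.
#' @param fmin,fmax Frequency range covered.
#' @return Strictly increasing center frequencies in Hz.
#' @export
gammatone_centers <- function(n_filters, fmin = 50, fmax = 22050) {
  erb_rate_to_hz(seq(hz_to_erb_rate(fmin), hz_to_erb_rate(fmax),
                     length.out = n_filters))
}

#' Gammatone (4th order) magnitude-squared filterbank on FFT bins
#' @noRd
gammatone_filterbank <- function(n_filters, n_fft, sr, fmin = 50) {
  centers <- gammatone_centers(n_filters, fmin, sr / 2)
  bins <- (0:(n_fft / 2L)) * sr / n_fft
  fb <- matrix(0, n_filters, length(bins))
  for (i in seq_len(n_filters)) {
    b <- 1.019 * erb_bandwidth(centers[i])
    fb[i, ] <- (1 + ((bins - centers[i]) / b)^2)^(-4)  # |H|^2, order 4
  }
  list(fb = fb, centers = centers)
}

#' Gammatone cepstral coefficients
#'
#' Like [mfcc()] but with a 4th-order gammatone filterbank whose center
#' frequencies are ERB-rate spaced on `[50, Nyquist]` and whose bandwidths
#' follow `1.019 * ERB(fc)`.
#'
#' @inheritParams mfcc
#' @return List with `coeffs`, `centers` and `summary`.
#' @export
gtcc <- function(clip, n_filters = 64L, n_coeffs = 13L, fs = frame_spec()) {
  ps <- frame_power_spectrum(clip, fs)
  gb <- gammatone_filterbank(n_filters, ps$n_fft, ps$sr)
  loge <- log(pmax(gb$fb %*% ps$power, 1e-10))
  cc <- dct_matrix(n_coeffs, n_filters) %*% loge
  rownames(cc) <- paste0("c", seq_len(n_coeffs))
  out <- summarize_coeffs(cc, "gtcc")
  out$centers <- gb$centers
  out
}

summarize_coeffs <- function(cc, prefix) {
  mu <- rowMeans(cc)
  sdv <- apply(cc, 1L, stats::sd)
  s <- c(mu, sdv)
  names(s) <- c(paste0(prefix, "_mean_", seq_len(nrow(cc))),
                paste0(prefix, "_sd_", seq_len(nrow(cc))))
  list(coeffs = cc, summary = s)
}
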