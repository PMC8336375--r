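#' Construct an audio clip
#'
#' The universal input record of the pipeline: a mono waveform in `[-1, 1]`
#' with its sampling rate. Stereo input is mixed down by channel averaging.
#'
#' @param samples Numeric vector (mono) or channels-by-n matrix.
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @param id Optional clip identifier carried through to derived artifacts.
#' @return An object of class `audio_clip` with fields `samples`,
#'   `sample_rate`, `n_channels` (before mixdown) and `duration_s`.
#' @export
audio_clip <- function(samples, sample_rate, id = NULL) {
  n_channels <- if (is.null(dim(samples))) 1L else nrow(samples)
  if (!is.null(dim(samples))) samples <- colMeans(samples)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty audio: clip has no samples")
  stopifnot(sample_rate > 0)
  structure(
    list(samples = samples, sample_rate = as.integer(sample_rate),
         n_channels = as.integer(n_channels),
         duration_s = length(samples) / sample_rate,
         id = id),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip%s: %.3f s @ %d Hz, %d samples>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$duration_s, x$sample_rate, length(x$samples)))
  invisible(x)
}

#' Load a WAV file as a mono audio clip
#'
#' Decodes PCM WAV audio, averages stereo channels to mono, and resamples
#' to `target_rate` with a polyphase filter when the file rate differs.
#'
#' @param path Path to a WAV file.
#' @param target_rate Desired sampling rate in Hz (default 44100, the rate
#'   of the clinical recordings the pipeline targets).
#' @return An [audio_clip].
#' @export
load_audio <- function(path, target_rate = 44100L) {
  w <- read_wav(path)
  clip <- audio_clip(w$samples, w$sample_rate,
                     id = tools::file_path_sans_ext(basename(path)))
  if (clip$sample_rate != target_rate) {
    clip <- resample_clip(clip, target_rate)
  }
  clip
}

#' Resample a clip to a new rate
#'
#' @param clip An [audio_clip].
#' @param target_rate New sampling rate in Hz.
#' @return A resampled [audio_clip].
#' @export
resample_clip <- function(clip, target_rate) {
  if (clip$sample_rate == target_rate) return(clip)
  f <- MASS::fractions(target_rate / clip$sample_rate, cycles = 8)
  pq <- as.integer(strsplit(attr(f, "fracs"), "/")[[1]])
  if (length(pq) == 1L) pq <- c(pq, 1L)
  y <- signal::resample(clip$samples, pq[1], pq[2])
  audio_clip(as.numeric(y), target_rate, id = clip$id)
}
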