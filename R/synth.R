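#' Synthesis parameters for one class
#'
#' Defaults plant the reported pathological-vs-control contrasts: patients
#' (label 1) get strongly reduced pitch variability (F0 sd 4 Hz vs 30 Hz),
#' band-limited energy (low-pass 5 kHz vs 16 kHz), three times the pause
#' rate with twice the pause durations, and a 0.6 probability that an
#' unvoiced segment is realized voiced (articulatory devoicing errors).
#' Formant placement is identical for both classes — the contrast is not
#' in the vowel inventory.
#'
#' @param f0_mean_hz,f0_sd_hz Fundamental-frequency mean and (slow
#'   modulation) standard deviation.
#' @param formants List of `(center_hz, bandwidth_hz)` resonator pairs.
#' @param lowpass_cutoff_hz Global low-pass cutoff.
#' @param pause_rate_per_s Expected pauses per second.
#' @param pause_dur_range_s Pause duration range (uniform).
#' @param devoice_prob Probability an unvoiced segment is produced voiced.
#' @param segment_dur_range_s Speech segment duration range (uniform).
#' @param snr_db Level of the pause noise floor below speech RMS.
#' @return A `class_params` list.
#' @export
class_params <- function(f0_mean_hz = 120, f0_sd_hz = 30,
                         formants = list(c(700, 130), c(1220, 170),
                                         c(2600, 250), c(3500, 300)),
                         lowpass_cutoff_hz = 16000,
                         pause_rate_per_s = 0.2,
                         pause_dur_range_s = c(0.15, 0.4),
                         devoice_prob = 0,
                         segment_dur_range_s = c(0.12, 0.35),
                         snr_db = 60) {
  stopifnot(lowpass_cutoff_hz < 22050, devoice_prob >= 0, devoice_prob <= 1,
            all(pause_dur_range_s > 0), all(segment_dur_range_s > 0))
  structure(list(f0_mean_hz = f0_mean_hz, f0_sd_hz = f0_sd_hz,
                 formants = formants, lowpass_cutoff_hz = lowpass_cutoff_hz,
                 pause_rate_per_s = pause_rate_per_s,
                 pause_dur_range_s = pause_dur_range_s,
                 devoice_prob = devoice_prob,
                 segment_dur_range_s = segment_dur_range_s,
                 snr_db = snr_db),
            class = "class_params")
}

#' Default synthesis parameters for a class label
#'
#' @param label 0 (control) or 1 (patient).
#' @return A [class_params()] object.
#' @export
default_class_params <- function(label) {
  stopifnot(label %in% c(0L, 1L))
  if (label == 0L) {
    class_params()
  } else {
    class_params(f0_sd_hz = 4, lowpass_cutoff_hz = 5000,
                 pause_rate_per_s = 0.6, pause_dur_range_s = c(0.3, 0.8),
                 devoice_prob = 0.6)
  }
}

ou_contour <- function(n, dt, mean, sd, theta = 4) {
  f <- numeric(n)
  f[1L] <- stats::rnorm(1L, mean, sd)
  if (n > 1L) {
    noise <- stats::rnorm(n - 1L, 0, sd * sqrt(2 * theta * dt))
    for (i in 2:n) {
      f[i] <- f[i - 1L] + theta * (mean - f[i - 1L]) * dt + noise[i - 1L]
    }
  }
  pmin(pmax(f, 50), 400)
}

voiced_excitation <- function(n, sr, f0_mean, f0_sd) {
  f0 <- ou_contour(n, 1 / sr, f0_mean, f0_sd)
  phase <- cumsum(f0 / sr)
  pulses <- as.numeric(diff(c(0, floor(phase))) > 0)
  # -12 dB/octave glottal tilt: two one-pole low-pass stages
  x <- stats::filter(pulses, 0.98, method = "recursive")
  x <- as.numeric(stats::filter(x, 0.98, method = "recursive"))
  list(x = x, f0 = f0)
}

apply_formants <- function(x, formants, sr) {
  for (fm in formants) {
    r <- exp(-pi * fm[2] / sr)
    theta <- 2 * pi * fm[1] / sr
    x <- as.numeric(signal::filter((1 - r), c(1, -2 * r * cos(theta), r^2), x))
  }
  x
}

set_rms <- function(x, target) {
  r <- sqrt(mean(x^2))
  if (r < 1e-12) x else x * (target / r)
}

taper_edges <- function(x, n_taper) {
  n <- length(x)
  k <- min(n_taper, n %/% 2L)
  if (k > 1L) {
    ramp <- seq(0, 1, length.out = k)
    x[seq_len(k)] <- x[seq_len(k)] * ramp
    x[(n - k + 1L):n] <- x[(n - k + 1L):n] * rev(ramp)
  }
  x
}

#' Synthesize one labelled clip with ground-truth annotations
#'
#' Source-filter synthesis: alternating voiced segments (impulse train at a
#' slowly wandering F0 with -12 dB/octave source tilt, shaped by formant
#' resonators), unvoiced segments (white noise high-passed at 3 kHz,
#' realized voiced with probability `devoice_prob`), and near-silent
#' pauses, concatenated with 10 ms edge crossfades, globally low-passed at
#' the class cutoff and peak-normalized to 0.9.
#'
#' @param params A [class_params()].
#' @param duration_s Clip duration in seconds (>= 1; default 5, long
#'   enough for stable pause statistics at the class pause rates).
#' @param seed RNG seed; identical `(params, duration_s, seed)` yield
#'   identical waveforms.
#' @param label Label recorded in the output (0/1).
#' @param sample_rate Output sampling rate.
#' @param id Clip identifier.
#' @return A `synth_clip`: `clip` ([audio_clip]), `label`, and `truth`
#'   (list with `segments` data frame, `f0_times`, `f0`).
#' @export
synthesize_clip <- function(params, duration_s = 5, seed = 1L, label = NA,
                            sample_rate = 44100L, id = NULL) {
  stopifnot(duration_s >= 1)
  sr <- sample_rate
  n_total <- round(duration_s * sr)
  with_seed(seed, {
    speech_rms <- 0.15
    p_pause <- min(0.9, params$pause_rate_per_s *
                     mean(c(params$segment_dur_range_s,
                            params$pause_dur_range_s)))
    x <- numeric(0)
    f0_full <- numeric(0)
    segs <- list()
    first <- TRUE
    while (length(x) < n_total) {
      type <- if (first) "voiced" else if (stats::runif(1) < p_pause) {
        "pause"
      } else if (stats::runif(1) < 0.65) "voiced" else "unvoiced"
      first <- FALSE
      dur <- if (type == "pause") {
        stats::runif(1, params$pause_dur_range_s[1], params$pause_dur_range_s[2])
      } else {
        stats::runif(1, params$segment_dur_range_s[1],
                     params$segment_dur_range_s[2])
      }
      n <- min(round(dur * sr), n_total - length(x))
      if (n < sr %/% 100L) break
      voiced_realized <- type == "voiced" ||
        (type == "unvoiced" && stats::runif(1) < params$devoice_prob)
      if (type == "pause") {
        seg <- stats::rnorm(n) * speech_rms * 10^(-params$snr_db / 20)
        f0seg <- numeric(n)
      } else if (voiced_realized) {
        ex <- voiced_excitation(n, sr, params$f0_mean_hz, params$f0_sd_hz)
        seg <- set_rms(apply_formants(ex$x, params$formants, sr), speech_rms)
        f0seg <- ex$f0
      } else {
        bt <- signal::butter(4, 3000 / (sr / 2), "high")
        seg <- stats::rnorm(n)
        if (n > 30L) seg <- signal::filtfilt(bt, seg)
        seg <- set_rms(seg, speech_rms * 0.5)
        f0seg <- numeric(n)
      }
      seg <- taper_edges(seg, round(0.010 * sr))
      segs[[length(segs) + 1L]] <- data.frame(
        start = length(x) / sr, end = (length(x) + n) / sr,
        type = type, voiced = voiced_realized)
      x <- c(x, seg)
      f0_full <- c(f0_full, f0seg)
    }
    if (params$lowpass_cutoff_hz < 0.98 * sr / 2) {
      bt <- signal::butter(6, params$lowpass_cutoff_hz / (sr / 2), "low")
      x <- signal::filtfilt(bt, x)
    }
    x <- x / max(abs(x)) * 0.9
    grid <- seq(1L, length(x), by = sr %/% 100L)
    structure(
      list(clip = audio_clip(x, sr, id = id), label = label,
           truth = list(segments = do.call(rbind, segs),
                        f0_times = (grid - 1L) / sr, f0 = f0_full[grid])),
      class = "synth_clip")
  })
}

#' Generate a balanced labelled synthetic dataset
#'
#' Clips are grouped into subjects (`clips_per_subject` each, mirroring a
#' protocol of several recordings per speaker) with a mild per-subject F0
#' jitter; per-clip seeds derive from the master seed. Optionally writes
#' 16-bit WAV files, a `manifest.csv` (columns `clip_path,label,subject_id`)
#' and a `truth.json`.
#'
#' @param n_per_class Clips per class.
#' @param duration_s Clip duration.
#' @param seed Master seed.
#' @param dir Output directory; `NULL` keeps everything in memory.
#' @param clips_per_subject Recordings per simulated speaker.
#' @return A `synth_dataset`: `manifest` data frame, `clips` (list of
#'   [audio_clip]), `labels`, `subjects`, `truths`.
#' @export
generate_dataset <- function(n_per_class = 50L, duration_s = 5, seed = 1L,
                             dir = NULL, clips_per_subject = 4L) {
  stopifnot(n_per_class >= 1L)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "wav"), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(file.path(dir, "wav"))) {
      stop("cannot write dataset: directory not writable: ", dir)
    }
  }
  clips <- list(); labels <- integer(0); subjects <- character(0)
  truths <- list(); paths <- character(0)
  i <- 0L
  for (label in c(0L, 1L)) {
    n_subj <- ceiling(n_per_class / clips_per_subject)
    for (s in seq_len(n_subj)) {
      subj_id <- sprintf("S%d_%02d", label, s)
      jitter <- with_seed(derive_seed(seed, label * 100000 + s),
                          stats::runif(1, 0.9, 1.1))
      n_clips <- min(clips_per_subject, n_per_class - (s - 1L) * clips_per_subject)
      for (k in seq_len(n_clips)) {
        i <- i + 1L
        params <- default_class_params(label)
        params$f0_mean_hz <- params$f0_mean_hz * jitter
        clip_id <- sprintf("%s_clip%02d", subj_id, k)
        sc <- synthesize_clip(params, duration_s,
                              seed = derive_seed(seed, i), label = label,
                              id = clip_id)
        clips[[i]] <- sc$clip
        labels[i] <- label
        subjects[i] <- subj_id
        truths[[clip_id]] <- sc$truth
        if (!is.null(dir)) {
          p <- file.path(dir, "wav", paste0(clip_id, ".wav"))
          write_wav(sc$clip$samples, sc$clip$sample_rate, p)
          paths[i] <- p
        } else {
          paths[i] <- NA_character_
        }
      }
    }
  }
  manifest <- data.frame(clip_path = paths, label = labels,
                         subject_id = subjects,
                         clip_id = names(truths)[seq_along(labels)])
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(truths, function(t) {
        list(segments = t$segments, f0_times = t$f0_times, f0 = t$f0)
      }),
      file.path(dir, "truth.json"), dataframe = "rows", digits = 6)
  }
  structure(list(manifest = manifest, clips = clips, labels = labels,
                 subjects = subjects, truths = truths),
            class = "synth_dataset")
}
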