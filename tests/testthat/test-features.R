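test_that("short-term energy follows its closed-form behaviors", {
  sr <- 44100
  dc <- audio_clip(rep(1, sr), sr)
  ste <- short_term_energy(dc)
  flen <- round(0.025 * sr)
  expect_true(all(abs(ste$energies - flen) < 1e-9))
  expect_equal(unname(ste$summary["sd"]), 0)

  silence <- audio_clip(rep(0, sr), sr)
  expect_true(all(short_term_energy(silence)$energies == 0))

  clip <- noise_clip(0.5, seed = 2)
  doubled <- audio_clip(2 * clip$samples, clip$sample_rate)
  expect_equal(short_term_energy(doubled)$energies,
               4 * short_term_energy(clip)$energies, tolerance = 1e-12)
})

test_that("autocorrelation pitch tracking recovers known fundamentals", {
  pt <- pitch_track(saw_clip(200))
  expect_lt(abs(median(pt$f0[pt$f0 > 0]) - 200), 3)
  expect_gt(pt$summary[["voiced_fraction"]], 0.9)
  expect_lt(pt$summary[["sd"]], 1)        # constant-F0 clip

  wn <- suppressWarnings(pitch_track(noise_clip(1, seed = 12)))
  expect_lt(wn$summary[["voiced_fraction"]], 0.2)

  silent <- audio_clip(rep(0, 44100), 44100)
  expect_warning(ps <- pitch_track(silent), "no voiced frames")
  expect_true(all(ps$summary == 0))
})

test_that("VAD recovers constructed speech/pause structure to frame accuracy", {
  sr <- 44100
  sp <- sin(2 * pi * 150 * (0:(2 * sr - 1)) / sr)
  clip <- audio_clip(c(sp, numeric(sr), sp), sr)
  seg <- vad_segment(clip)
  expect_equal(nrow(seg$pauses), 1L)
  expect_equal(unname(seg$pauses[1, "end"] - seg$pauses[1, "start"]), 1.0,
               tolerance = 0.011)

  silence <- audio_clip(rep(0, sr), sr)
  vs <- vad_segment(silence)
  expect_equal(nrow(vs$voiced_segments), 0L)
  expect_equal(nrow(vs$pauses), 1L)
  expect_equal(unname(vs$pauses[1, ]), c(0, 1))

  tone <- vad_segment(tone_clip(300, 1))
  expect_equal(nrow(tone$voiced_segments), 1L)
  expect_equal(nrow(tone$pauses), 0L)
})

test_that("the five fluency features match constructed ground truth", {
  sr <- 44100
  sp <- sin(2 * pi * 150 * (0:(2 * sr - 1)) / sr)
  clip <- audio_clip(c(sp, numeric(sr), sp), sr)
  f <- suppressWarnings(fluency_features(vad_segment(clip)))
  expect_equal(unname(f["total_time"]), 5.0)
  expect_equal(unname(f["voiced_time"]), 4.0, tolerance = 0.011)
  expect_equal(unname(f["voiced_ratio"]), 0.8, tolerance = 0.011)
  expect_equal(unname(f["max_pause"]), 1.0, tolerance = 0.011)

  silent <- audio_clip(rep(0, 2 * sr), sr)
  fs <- suppressWarnings(fluency_features(vad_segment(silent)))
  expect_equal(unname(fs), c(2, 0, 0, 2, 0))
  expect_true(f[["voiced_ratio"]] >= 0 && f[["voiced_ratio"]] <= 1)
})

test_that("syllable nuclei count energy peaks within voiced regions", {
  sr <- 44100
  # five 200 ms bursts separated by 150 ms of silence: five nuclei
  burst <- sin(2 * pi * 180 * (0:(round(0.2 * sr) - 1)) / sr)
  gap <- numeric(round(0.15 * sr))
  clip <- audio_clip(rep(c(burst, gap), 5), sr)
  seg <- vad_segment(clip, min_pause_s = 0.05, min_segment_s = 0.05)
  f <- fluency_features(seg)
  n_nuclei <- f[["voiced_time"]] / f[["mean_syllable"]]
  expect_equal(round(n_nuclei), 5)
})

test_that("LTAS averages the spectrogram over time into frequency bands", {
  sp <- compute_spectrogram(noise_clip(5, seed = 8), n_fft = 2048L)
  lt <- ltas(sp)
  expect_length(lt, 128L)
  expect_lt(diff(range(lt)), 3)          # flat for stationary white noise

  tone_sp <- compute_spectrogram(tone_clip(4000, 1))
  tl <- ltas(tone_sp)
  expect_lte(abs(unname(which.max(tl)) - (round(4000 / (22050 / 128)) + 1L)),
             1L)

  # time-constant spectrogram: LTAS equals any single frame
  spc <- sp
  spc$values <- matrix(spc$values[, 1], nrow(spc$values), 5)
  expect_equal(unname(ltas(spc, n_bins_out = nrow(spc$values))),
               unname(spc$values[, 1]))
})

test_that("MFCC construction is orthonormal and flat spectra collapse to c1", {
  M <- schnetr:::dct_matrix(13, 26)
  expect_lt(max(abs(M %*% t(M) - diag(13))), 1e-10)
  silence <- audio_clip(rep(0, 44100), 44100)  # digital zero: flat log floor
  mf <- mfcc(silence)
  expect_equal(dim(mf$coeffs), c(13L, 98L))
  expect_lt(max(abs(mf$coeffs[2:13, ])), 1e-6)
  expect_gt(abs(mf$coeffs[1, 1]), 1)
  expect_length(mf$summary, 26L)
})

test_that("gammatone filterbank follows the ERB design", {
  expect_equal(erb_bandwidth(1000), 24.7 * (4.37 + 1))
  expect_equal(erb_bandwidth(1000), 132.639, tolerance = 1e-3)
  ctr <- gammatone_centers(64, 50, 22050)
  expect_true(all(diff(ctr) > 0))
  expect_equal(ctr[1], 50, tolerance = 1e-6)
  expect_equal(ctr[64], 22050, tolerance = 1e-6)
  # a tone at a filter's center maximizes that filter's output
  g <- gtcc(tone_clip(ctr[40], 0.5))
  fb <- schnetr:::gammatone_filterbank(64, 2048, 44100)
  pw <- schnetr:::frame_power_spectrum(tone_clip(ctr[40], 0.5), frame_spec())
  expect_equal(which.max(rowMeans(fb$fb %*% pw$power)), 40L)
  expect_length(g$summary, 26L)
})

test_that("gain invariance holds where the features are scale-free", {
  clip <- small_synth()$clips[[1]]
  louder <- audio_clip(pmin(pmax(3 * clip$samples, -1), 1) / 3 * 3,
                       clip$sample_rate)
  louder$samples <- 3 * clip$samples
  p1 <- suppressWarnings(pitch_track(clip)$summary)
  p2 <- suppressWarnings(pitch_track(louder)$summary)
  expect_equal(p1, p2, tolerance = 1e-6)
  f1 <- suppressWarnings(fluency_features(vad_segment(clip)))
  f2 <- suppressWarnings(fluency_features(vad_segment(louder)))
  expect_equal(f1, f2, tolerance = 1e-6)
  a1 <- lp_family(clip$samples[10000:12000], 12)$a
  a2 <- lp_family(3 * clip$samples[10000:12000], 12)$a
  expect_equal(a1, a2, tolerance = 1e-6)
})
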