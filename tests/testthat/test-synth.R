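test_that("class parameter defaults encode the planted clinical contrasts", {
  p0 <- default_class_params(0)
  p1 <- default_class_params(1)
  expect_equal(p0$lowpass_cutoff_hz, 16000)
  expect_equal(p1$lowpass_cutoff_hz, 5000)
  expect_gt(p0$f0_sd_hz, p1$f0_sd_hz)
  expect_lt(p0$pause_rate_per_s, p1$pause_rate_per_s)
  expect_equal(p0$devoice_prob, 0)
  expect_equal(p1$devoice_prob, 0.6)
  expect_identical(p0$formants, p1$formants)
  expect_error(default_class_params(2))
})

test_that("synthesis is deterministic and annotated consistently", {
  p <- default_class_params(1)
  a <- synthesize_clip(p, 3, seed = 5, label = 1)
  b <- synthesize_clip(p, 3, seed = 5, label = 1)
  expect_identical(a$clip$samples, b$clip$samples)
  expect_identical(a$truth$segments, b$truth$segments)
  expect_lte(max(a$truth$segments$end), a$clip$duration_s + 1e-9)
  expect_lte(max(abs(a$clip$samples)), 0.9 + 1e-9)
  expect_equal(a$label, 1)
  c2 <- synthesize_clip(p, 3, seed = 6, label = 1)
  expect_false(identical(a$clip$samples, c2$clip$samples))
})

test_that("patient clips concentrate energy below 5 kHz", {
  for (seed in 1:4) {
    sc <- synthesize_clip(default_class_params(1), 3, seed = seed)
    sp <- compute_spectrogram(sc$clip)
    pw <- 10^(sp$values / 10)
    frac_hi <- sum(pw[sp$freq_axis > 5000, ]) / sum(pw)
    expect_lt(frac_hi, 0.05)
  }
})

test_that("a zero pause rate produces pause-free truth", {
  p <- default_class_params(0)
  p$pause_rate_per_s <- 0
  sc <- synthesize_clip(p, 3, seed = 9)
  expect_equal(sum(sc$truth$segments$type == "pause"), 0L)
})

test_that("generated datasets are balanced, grouped by subject, and on disk", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(n_per_class = 6, duration_s = 3, seed = 21,
                         dir = dir, clips_per_subject = 3L)
  expect_equal(length(ds$clips), 12L)
  expect_equal(sum(ds$labels == 0), 6L)
  expect_equal(sum(ds$labels == 1), 6L)
  expect_equal(length(unique(ds$subjects)), 4L)
  expect_equal(nrow(ds$manifest), 12L)
  expect_true(all(file.exists(ds$manifest$clip_path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  # manifest round-trips through the loader interface
  m <- read_manifest(file.path(dir, "manifest.csv"))
  clip <- load_audio(m$clip_path[1])
  expect_equal(clip$sample_rate, 44100L)
  expect_equal(length(clip$samples), length(ds$clips[[1]]$samples))
})

test_that("population contrasts separate the classes in the planted direction", {
  ds <- fixture("pop_synth",
                generate_dataset(n_per_class = 25, seed = 77))
  max_pause <- vapply(ds$clips, function(cl) {
    suppressWarnings(fluency_features(vad_segment(cl))[["max_pause"]])
  }, numeric(1))
  p_pause <- stats::wilcox.test(max_pause[ds$labels == 1],
                                max_pause[ds$labels == 0],
                                alternative = "greater",
                                exact = FALSE)$p.value
  expect_lt(p_pause, 0.01)

  f0_sd <- vapply(names(ds$truths), function(id) {
    f0 <- ds$truths[[id]]$f0
    stats::sd(f0[f0 > 0])
  }, numeric(1))
  p_f0 <- stats::wilcox.test(f0_sd[ds$labels == 0], f0_sd[ds$labels == 1],
                             alternative = "greater",
                             exact = FALSE)$p.value
  expect_lt(p_f0, 0.01)

  # above-5 kHz energy fraction is stochastically larger for controls
  frac_hi <- vapply(ds$clips, function(cl) {
    sp <- compute_spectrogram(cl)
    pw <- 10^(sp$values / 10)
    sum(pw[sp$freq_axis > 5000, ]) / sum(pw)
  }, numeric(1))
  p_band <- stats::wilcox.test(frac_hi[ds$labels == 0],
                               frac_hi[ds$labels == 1],
                               alternative = "greater",
                               exact = FALSE)$p.value
  expect_lt(p_band, 0.01)
})
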