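# Shared fixtures, built in code and memoized so expensive objects are
# constructed once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tone_clip <- function(freq, duration_s = 1, sr = 44100, amp = 0.8) {
  t <- (0:(round(duration_s * sr) - 1)) / sr
  audio_clip(amp * sin(2 * pi * freq * t), sr)
}

saw_clip <- function(freq, duration_s = 1, sr = 44100) {
  t <- (0:(round(duration_s * sr) - 1)) / sr
  audio_clip(2 * ((t * freq) %% 1) - 1, sr)
}

noise_clip <- function(duration_s = 1, sr = 44100, seed = 1, amp = 0.3) {
  withr::with_seed(seed, audio_clip(amp * stats::rnorm(round(duration_s * sr)), sr))
}

rand_image <- function(seed = 1, h = 128L, w = 256L) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(h * w), h, w)
    structure((m - mean(m)) / stats::sd(m),
              class = c("net_input_image", "matrix"))
  })
}

# Linearly separable image classes: class 1 carries energy in the top
# (high-frequency) half, class 0 in the bottom half.
separable_images <- function(n_per_class, seed = 1, h = 128L, w = 256L) {
  withr::with_seed(seed, {
    images <- list()
    labels <- integer(0)
    for (i in seq_len(2 * n_per_class)) {
      lab <- (i - 1L) %% 2L
      m <- matrix(stats::rnorm(h * w, sd = 0.1), h, w)
      band <- if (lab == 1L) (h / 2 + 1):h else 1:(h / 2)
      m[band, ] <- m[band, ] + 1.5
      images[[i]] <- structure((m - mean(m)) / stats::sd(m),
                               class = c("net_input_image", "matrix"))
      labels[i] <- lab
    }
    list(images = images, labels = labels)
  })
}

# Small synthetic dataset reused across feature / baseline tests.
small_synth <- function() {
  fixture("small_synth", generate_dataset(n_per_class = 12, duration_s = 3,
                                          seed = 301))
}
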