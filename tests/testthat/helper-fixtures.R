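# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# low-noise subject with strong lateralised desynchronization
strong_profile <- function() {
  subject_profile(iaf = 10, a0 = 20, a_task = 0.6 * 20, eta = 0.04,
                  lam = 0.01, a_max = 40, noise_scale = 2, blink_rate = 0,
                  seed = 99L)
}

# 36-trial low-noise MI session reused across spectral/mi tests
mi_fixture <- function() fixture("mi_small", function() {
  generate_mi_session(strong_profile(), trials_per_task = 4, n_runs = 3,
                      seed = 7L)
})

mi_trials_filtered <- function() fixture("mi_trials_filt", function() {
  scalp <- select_channels(mi_fixture(), montage()$scalp)
  epoch_trials(fir_bandpass(scalp), 0, 4)
})

# tiled 1 s window: a baseline whose windowed ARP equals the window ARP
# exactly, so replaying the same window gives a dARP of exactly zero
tiled_baseline <- function(n_tiles = 60) fixture("tiled", function() {
  set.seed(5)
  t <- seq_len(500) / 500
  front <- montage()$frontal16
  win <- t(vapply(seq_along(front), function(i)
    4 * sin(2 * pi * 10 * t + i) + 6 * sin(2 * pi * 3 * t + 2 * i) +
      rnorm(500, 0, 4), numeric(500)))
  list(window = win,
       rec = raw_recording(win[, rep(seq_len(500), n_tiles)], 500, front))
})

# the same tiled window with the alpha component boosted 1.3x: a constant,
# comfortably supra-threshold positive dARP stream
boosted_window <- function() fixture("boosted", function() {
  set.seed(5)
  t <- seq_len(500) / 500
  front <- montage()$frontal16
  t(vapply(seq_along(front), function(i)
    1.3 * 4 * sin(2 * pi * 10 * t + i) + 6 * sin(2 * pi * 3 * t + 2 * i) +
      rnorm(500, 0, 4), numeric(500)))
})

# simple sine-mixture recording helper
tone_recording <- function(freqs, amps, duration_s = 40, sfreq = 500,
                           channels = c("O1", "OZ", "O2", "POZ"),
                           noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  t <- seq_len(duration_s * sfreq) / sfreq
  base <- Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * t),
                          freqs, amps))
  data <- t(vapply(seq_along(channels), function(i)
    base + rnorm(length(t), 0, noise_sd), numeric(length(t))))
  raw_recording(data, sfreq, channels)
}
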