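test_that("DPSS tapers match the reference Slepian sequences", {
  # frozen from scipy.signal.windows.dpss(16, 2, 3)
  ref_row0 <- c(0.0166861972, 0.0474413151, 0.0968656002, 0.1631896253,
                0.2393767262, 0.3140174335, 0.3738438768, 0.4071727942)
  tap <- dpss_tapers(16, 2, 3)
  expect_equal(tap[1:8, 1], ref_row0, tolerance = 1e-9)
  expect_equal(tap[16:9, 1], ref_row0, tolerance = 1e-9)   # symmetric
  expect_equal(crossprod(tap), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # long-window path (tridiagonal bisection) stays orthonormal
  big <- dpss_tapers(4000, 8, 5)
  expect_equal(crossprod(big), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("multitaper PSD satisfies Parseval and localises tones", {
  set.seed(1)
  x <- matrix(rnorm(500 * 60), 1)
  est <- multitaper_psd(x, 500)
  expect_equal(band_power(est, 0, 250), stats::var(as.numeric(x)),
               tolerance = 0.05)
  t <- seq_len(5000) / 500
  tone <- matrix(sqrt(2) * sin(2 * pi * 10 * t), 1)
  e2 <- multitaper_psd(tone, 500)
  expect_gt(band_power(e2, 8, 12) / band_power(e2, 0.5, 250), 0.95)
  expect_true(all(multitaper_psd(matrix(0, 2, 1000), 500)$psd == 0))
  expect_error(multitaper_psd(matrix(0, 1, 100), 500), "short")
})

test_that("band_power arithmetic and partition additivity are exact", {
  flat <- spectral_estimate(seq(0, 60, by = 0.5), matrix(1, 1, 121))
  expect_equal(band_power(flat, 8, 12), 4)
  expect_equal(relative_power(flat, c(8, 12), c(1, 50)), 4 / 49)
  expect_error(band_power(flat, 12, 12), "empty")
  # five IAF-anchored bands sum exactly to the total for arbitrary PSDs
  set.seed(4)
  est <- spectral_estimate(seq(0, 60, by = 0.25),
                           matrix(rexp(3 * 241), 3, 241))
  for (iaf in c(8.3, 10, 11.7)) {
    bs <- band_set(iaf)
    parts <- vapply(bs, function(b) band_power(est, b[1], b[2]),
                    numeric(3))
    expect_equal(rowSums(parts), band_power(est, 1, 50), tolerance = 1e-12)
    rp <- vapply(bs, function(b) relative_power(est, b), numeric(3))
    expect_equal(rowSums(rp), c(1, 1, 1), tolerance = 1e-12)
  }
})

test_that("relative power is scale invariant and guards degenerate input", {
  set.seed(8)
  x <- matrix(rnorm(2 * 2000), 2)
  a <- relative_power(multitaper_psd(x, 500), c(8, 12))
  b <- relative_power(multitaper_psd(3.7 * x, 500), c(8, 12))
  expect_equal(a, b, tolerance = 1e-12)
  zero <- spectral_estimate(seq(0, 60, by = 0.5), matrix(0, 1, 121))
  expect_error(relative_power(zero, c(8, 12)), "zero total power")
})

test_that("delta_relative implements the proportional deviation", {
  expect_equal(delta_relative(0.2, 0.2), 0)
  expect_equal(delta_relative(0.24, 0.20), 0.2)
  expect_error(delta_relative(0.2, 0), "positive")
})

test_that("IAF is recovered across the alpha grid and falls back on noise", {
  errs <- vapply(c(8.5, 10, 11.5), function(iaf) {
    p <- subject_profile(iaf = iaf, noise_scale = 5,
                         seed = as.integer(iaf * 10))
    b <- generate_baseline(p, eyes = "closed", duration_s = 40)
    as.numeric(estimate_iaf(b)) - iaf
  }, 0)
  expect_lt(mean(abs(errs)), 0.25)
  # pure 1/f background: no admissible peak, documented fallback
  quiet <- generate_baseline(subject_profile(a0 = 0.001, a_task = 0.001,
                                             noise_scale = 10, seed = 7),
                             alpha_amp = 0.001, eyes = "closed",
                             duration_s = 40)
  expect_warning(iaf <- estimate_iaf(quiet), "falling back")
  expect_equal(as.numeric(iaf), 10)
  expect_true(attr(iaf, "fallback"))
  expect_error(estimate_iaf(select_channels(quiet, "FZ")), "posterior")
  expect_error(estimate_iaf(slice_interval(quiet, 0, 10)), "30 s")
})

test_that("near-tied alpha peaks resolve deterministically to the stronger,
           then lower, frequency", {
  rec1 <- tone_recording(c(9, 11), c(6, 4), noise_sd = 1, seed = 3)
  expect_lt(abs(as.numeric(estimate_iaf(rec1)) - 9), 0.4)
  rec2 <- tone_recording(c(9, 11), c(4, 6), noise_sd = 1, seed = 3)
  expect_lt(abs(as.numeric(estimate_iaf(rec2)) - 11), 0.4)
  # determinism
  expect_identical(estimate_iaf(rec1), estimate_iaf(rec1))
})

test_that("ERD arithmetic on constructed stage powers is exact", {
  # trial with task-stage amplitude sqrt(0.5) of the pre-task stage:
  # power halves, ERD = -0.5
  sf <- 500
  t_pre <- seq_len(3 * sf) / sf
  t_task <- seq_len(4 * sf) / sf
  mk <- function(amp_task) {
    e <- array(0, c(2, 1, 7 * sf))
    for (k in 1:2) {
      e[k, 1, ] <- c(2 * sin(2 * pi * 10 * t_pre + k),
                     amp_task * sin(2 * pi * 10 * t_task + k))
    }
    trial_set(e, c("left", "left"), sf, tmin = -3, channel_names = "C4")
  }
  erd0 <- compute_erd(mk(2), c(8, 12))
  expect_lt(abs(erd0["left", "C4"]), 0.02)
  erd_half <- compute_erd(mk(2 * sqrt(0.5)), c(8, 12))
  expect_equal(erd_half["left", "C4"], -0.5, tolerance = 0.02)
  short <- trial_set(array(0, c(1, 1, 100)), "left", sf, tmin = -3)
  expect_error(compute_erd(short, c(8, 12)), "span")
})

test_that("injected lateralised desynchronization is recovered by ERD", {
  scalp <- select_channels(mi_fixture(), montage()$scalp)
  erd <- compute_erd(epoch_trials(scalp, -3, 4), c(8, 12))
  expected <- 0.6^2 - 1                      # amplitude ratio 0.6
  expect_equal(erd["left", "C4"], expected, tolerance = 0.2 * abs(expected))
  expect_equal(erd["right", "C3"], expected, tolerance = 0.2 * abs(expected))
  expect_lt(abs(erd["idle", "C3"]), 0.15)    # no injected attenuation
  # desynchronization is lateralised: contralateral deeper than ipsilateral
  expect_lt(erd["left", "C4"], erd["left", "C3"])
  expect_lt(erd["right", "C3"], erd["right", "C4"])
})
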