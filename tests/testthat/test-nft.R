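test_that("engine config fixes the published operating point", {
  cfg <- nft_config()
  expect_equal(cfg$window_s, 1.0)
  expect_equal(cfg$update_s, 0.1)
  expect_equal(cfg$buffer_max, 100L)
  expect_equal(cfg$th_init, 0.10)
  expect_equal(cfg$th_stride, 0.01)
  expect_equal(cfg$th_floor, 0.01)
  expect_error(nft_config(th_floor = 0.2, th_init = 0.1))
})

test_that("init_engine reproduces the spectral-module baseline ARP", {
  tb <- tiled_baseline()
  st <- init_engine(tb$rec, 10)
  est <- windowed_psd(tb$rec)
  expect_equal(st$arp_baseline, mean(relative_power(est, c(8, 12))),
               tolerance = 1e-12)
  expect_equal(st$th, 0.10)
  expect_length(st$buffer, 0)
  expect_error(init_engine(slice_interval(tb$rec, 0, 10), 10), "30 s")
  # no alpha content at all -> degenerate baseline
  t <- seq_len(500 * 40) / 500
  tone40 <- raw_recording(t(vapply(1:16, function(i)
    sin(2 * pi * 40 * t + i), numeric(length(t)))), 500,
    montage()$frontal16)
  expect_error(init_engine(tone40, 10), "degenerate")
})

test_that("EOG artifact detection is a strict amplitude rule", {
  expect_false(detect_eog_artifact(numeric(500), 100))
  expect_true(detect_eog_artifact(c(numeric(250), 200, numeric(249)), 100))
  expect_false(detect_eog_artifact(rep(99, 500), 100))
  expect_false(detect_eog_artifact(rep(100, 500), 100))  # strict >
})

test_that("a zero-deviation stream drives the threshold stepwise to the floor", {
  tb <- tiled_baseline()
  st <- init_engine(tb$rec, 10)
  eog <- numeric(500)
  ths <- numeric(1100)
  for (k in seq_len(1100)) {
    res <- nft_step(st, tb$window, eog)
    st <- res$state
    ths[k] <- res$frame$th
    expect_lt(abs(res$frame$delta_arp), 1e-12)    # exact replay
  }
  expect_equal(st$smiley_count, 0L)
  # stepwise descent: one stride per full buffer, floored at exactly 0.01
  expect_equal(ths[c(99, 100, 200, 900, 1100)],
               c(0.10, 0.09, 0.08, 0.01, 0.01))
  expect_true(all(ths >= 0.01))
  expect_length(st$buffer, 100)                    # ring buffer saturated
})

test_that("a sustained high-alpha stream earns smileys and +0.01 raises", {
  tb <- tiled_baseline()
  st <- init_engine(tb$rec, 10)
  boosted <- boosted_window()
  eog <- numeric(500)
  ths <- numeric(95); smileys <- logical(95)
  for (k in seq_len(95)) {
    res <- nft_step(st, boosted, eog)
    st <- res$state
    ths[k] <- res$frame$th
    smileys[k] <- res$frame$smiley
    expect_gt(res$frame$delta_arp, 0)
    expect_identical(res$frame$color, "green")
  }
  expect_gte(st$smiley_count, 1L)
  expect_equal(which(smileys)[1:3], c(30, 60, 90))  # every 30 frames
  raises <- diff(ths[smileys | c(FALSE, smileys[-95])])
  expect_true(all(abs(diff(unique(ths)) - 0.01) < 1e-12))
  expect_equal(ths[30], 0.11)
  expect_equal(max(ths), 0.10 + 0.01 * st$smiley_count)
})

test_that("artifacts pause feedback without touching buffer or threshold", {
  tb <- tiled_baseline()
  st <- init_engine(tb$rec, 10)
  eog_clean <- numeric(500)
  for (k in 1:10) st <- nft_step(st, tb$window, eog_clean)$state
  buf_before <- st$buffer; th_before <- st$th
  eog_blink <- c(numeric(100), rep(250, 100), numeric(300))
  paused <- logical(7)
  for (k in 1:7) {
    res <- nft_step(st, tb$window, if (k == 1) eog_blink else eog_clean)
    st <- res$state
    paused[k] <- res$frame$paused
    if (res$frame$paused) {
      expect_identical(res$frame$color, "neutral")
      expect_true(is.na(res$frame$delta_arp))
    }
  }
  expect_equal(paused, c(rep(TRUE, 5), FALSE, FALSE))  # pause_frames = 5
  expect_identical(st$buffer[seq_along(buf_before)], buf_before)
  expect_length(st$buffer, length(buf_before) + 2)
  expect_equal(st$th, th_before)
  expect_error(nft_step(st, tb$window[, 1:250], eog_clean), "exactly")
})

test_that("closed-loop sessions emit the right frame count and respond to eta", {
  p <- subject_profile(eta = 0.05, lam = 0.01, noise_scale = 3,
                       blink_rate = 0, seed = 21)
  eo <- generate_baseline(p, eyes = "open", duration_s = 30)
  st <- init_engine(eo, 10)
  out <- run_nft_session(p, st, n_runs = 1, run_s = 180, seed = 3)
  expect_equal(nrow(out$frames), 1791)            # (180 s - 1 s)/0.1 s + 1
  expect_true(all(out$frames$th >= 0.01))
  expect_gt(out$final_amp, p$a0)
  # responder whose learning time constant spans the session: per-run mean
  # deviation grows from run 1 to run 6
  ps <- subject_profile(eta = 0.012, lam = 0.01, noise_scale = 3,
                        blink_rate = 0, seed = 23)
  eos <- generate_baseline(ps, eyes = "open", duration_s = 30)
  out6 <- run_nft_session(ps, init_engine(eos, 10), n_runs = 6, run_s = 20,
                          seed = 3)
  expect_gt(stats::cor(seq_len(6), out6$run_mean_delta_arp,
                       method = "spearman"), 0.7)
  # non-responder: amplitude pinned at a0, mean deviation near zero
  p0 <- subject_profile(eta = 0, noise_scale = 3, blink_rate = 0, seed = 22)
  eo0 <- generate_baseline(p0, eyes = "open", duration_s = 30)
  out0 <- run_nft_session(p0, init_engine(eo0, 10), n_runs = 2, run_s = 30,
                          seed = 4)
  expect_equal(out0$final_amp, p0$a0)
  expect_lt(max(abs(out0$run_mean_delta_arp)), 0.15)
})

test_that("final amplitude is non-decreasing in eta at shared seeds", {
  amps <- vapply(c(0, 0.01, 0.03, 0.06), function(eta) {
    p <- subject_profile(eta = eta, noise_scale = 3, blink_rate = 0,
                         seed = 50L)
    eo <- generate_baseline(p, eyes = "open", duration_s = 30)
    run_nft_session(p, init_engine(eo, 10), n_runs = 1, run_s = 60,
                    seed = 9L)$final_amp
  }, 0)
  expect_true(all(diff(amps) >= -1e-9))
})
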