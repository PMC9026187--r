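segments_from <- function(data, sfreq = 500, seg_s = 5) {
  segment_baseline(raw_recording(data, sfreq,
                                 paste0("CH", seq_len(nrow(data)))), seg_s)
}

test_that("baseline segmentation discards the remainder", {
  rec <- raw_recording(matrix(0, 2, 60 * 500), 500, c("C3", "C4"))
  expect_length(segment_baseline(rec), 12)
  rec13 <- raw_recording(matrix(0, 2, 13 * 500), 500, c("C3", "C4"))
  segs <- segment_baseline(rec13)
  expect_length(segs, 2)
  expect_equal(ncol(segs[[1]]), 2500)
  rec4 <- raw_recording(matrix(0, 2, 4 * 500), 500, c("C3", "C4"))
  expect_error(segment_baseline(rec4), "shorter")
})

test_that("PLI: zero for zero lag, one for a fixed 90-degree lag", {
  t <- seq_len(60 * 500) / 500
  s <- sin(2 * pi * 10 * t)
  zero_lag <- rbind(s, 0.5 * s)                  # same signal, gain only
  m0 <- pli_matrix(segments_from(zero_lag), c(8, 12), 500)
  expect_lt(m0$values[1, 2], 0.05)
  lagged <- rbind(s, sin(2 * pi * 10 * t + pi / 2))
  m1 <- pli_matrix(segments_from(lagged), c(8, 12), 500)
  expect_gt(m1$values[1, 2], 0.95)
  # symmetry / zero diagonal / range
  expect_identical(m1$values, t(m1$values))
  expect_equal(diag(m1$values), c(0, 0))
  expect_error(pli_matrix(segments_from(lagged), c(100, 300), 500),
               "Nyquist")
})

test_that("PLI is invariant to channel scaling and global time shift", {
  set.seed(6)
  x <- matrix(stats::rnorm(3 * 30 * 500), 3)
  m <- pli_matrix(segments_from(x), c(8, 12), 500)
  m_scaled <- pli_matrix(segments_from(x * c(2, 0.1, 5)), c(8, 12), 500)
  expect_equal(m$values, m_scaled$values, tolerance = 1e-10)
  shift <- 250
  m_shift <- pli_matrix(segments_from(x[, (shift + 1):(shift + 25 * 500)]),
                        c(8, 12), 500)
  m_orig <- pli_matrix(segments_from(x[, 1:(25 * 500)]), c(8, 12), 500)
  # same process, shifted window: statistics agree loosely
  expect_lt(max(abs(m_shift$values - m_orig$values)), 0.35)
})

test_that("independent noise PLI stays below a phase-scrambled null", {
  set.seed(7)
  x <- matrix(stats::rnorm(2 * 60 * 500), 2)
  obs <- pli_matrix(segments_from(x), c(8, 12), 500)$values[1, 2]
  # null: circularly shift one channel by random large offsets
  null <- vapply(1:39, function(k) {
    set.seed(100 + k)
    off <- sample(5000:25000, 1)
    xs <- rbind(x[1, ], x[2, c((off + 1):ncol(x), 1:off)])
    pli_matrix(segments_from(xs), c(8, 12), 500)$values[1, 2]
  }, 0)
  expect_lte(obs, sort(null)[ceiling(0.95 * length(null))])
})

test_that("imCoh: zero for shared zero-lag sources, one for 90-degree lag", {
  t <- seq_len(60 * 500) / 500
  set.seed(8)
  src <- sin(2 * pi * 10 * t) * (1 + 0.2 * sin(2 * pi * 0.2 * t))
  # volume-conduction surrogate: same source, different positive gains
  vc <- rbind(3 * src + stats::rnorm(length(t), 0, 0.01),
              0.5 * src + stats::rnorm(length(t), 0, 0.01))
  mi <- imcoh_matrix(segments_from(vc), c(8, 12), 500)
  expect_lt(mi$values[1, 2], 0.05)
  # while ordinary coherence on the same pair is ~1 (cross-spectrum real)
  est <- multitaper_psd(vc[, 1:2500], 500)
  # quick plain-coherence oracle at the 10 Hz bin via FFT of one segment
  f1 <- stats::fft(vc[1, 1:5000])[101]; f2 <- stats::fft(vc[2, 1:5000])[101]
  coh <- Mod(f1 * Conj(f2))^2 / (Mod(f1)^2 * Mod(f2)^2)
  expect_gt(coh, 0.99)
  lag <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t + pi / 2))
  ml <- imcoh_matrix(segments_from(lag), c(9, 11), 500)
  expect_gt(ml$values[1, 2], 0.9)
  expect_identical(ml$values, t(ml$values))
  expect_true(all(ml$values >= 0 & ml$values <= 1))
})

test_that("edge_contrast flags degenerate edges and catches injected coupling", {
  mk <- function(vals) connectivity_matrix(vals, "alpha", "PLI")
  set.seed(10)
  mats <- lapply(1:5, function(i) {
    v <- matrix(stats::runif(16), 4); v <- (v + t(v)) / 2; diag(v) <- 0
    mk(pmin(v, 1))
  })
  same <- edge_contrast(mats, mats)
  expect_true(all(same$degenerate))
  expect_false(any(same$sig_unc) || any(same$sig_fdr))
  expect_error(edge_contrast(mats, mats[1:3]), "mismatched")
  expect_error(edge_contrast(mats[1], mats[1]), "2 subjects")

  # cohort whose post-NFT baselines carry a 90-degree coupled pair:
  # the edge nearest the coupled sources should rise to the top
  n <- 6
  mont <- montage()
  pre <- list(); post <- list()
  for (i in seq_len(n)) {
    p0 <- subject_profile(noise_scale = 6, seed = 300L + i)
    pc <- subject_profile(noise_scale = 6, coupling = 14, seed = 300L + i)
    b_pre <- generate_baseline(p0, duration_s = 30, seed = 400L + i)
    b_post <- generate_baseline(pc, duration_s = 30, seed = 500L + i)
    pre[[i]] <- pli_matrix(segment_baseline(
      select_channels(b_pre, mont$lateral48)), c(8, 12), 500)
    post[[i]] <- pli_matrix(segment_baseline(
      select_channels(b_post, mont$lateral48)), c(8, 12), 500)
  }
  ec <- edge_contrast(pre, post)
  pos <- channel_positions(mont$lateral48)
  near <- function(xy) which.min((pos[, 1] - xy[1])^2 + (pos[, 2] - xy[2])^2)
  i_lf <- near(c(-0.5, 0.56)); i_rp <- near(c(0.55, -0.55))
  tgt <- ec[(ec$i == min(i_lf, i_rp)) & (ec$j == max(i_lf, i_rp)), ]
  # the edge between the coupled sources is unambiguously enhanced...
  expect_gt(tgt$t, stats::qt(0.999, df = n - 1))
  expect_true(tgt$sig_fdr)
  expect_equal(tgt$sign, 1)
  # ...and every top-1% edge links the left-frontal to the right-parietal
  # patch (the coupling leaks onto neighbouring sensors, so the named edge
  # need not be the single strongest)
  top <- ec[order(-ec$t)[seq_len(ceiling(0.01 * nrow(ec)))], ]
  is_lf <- pos[, 1] < 0 & pos[, 2] > 0.1
  is_rp <- pos[, 1] > 0 & pos[, 2] < -0.1
  expect_true(all((is_lf[top$i] & is_rp[top$j]) |
                    (is_rp[top$i] & is_lf[top$j])))
})
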