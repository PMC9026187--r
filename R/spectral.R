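# Multitaper spectral estimation and the derived band-power quantities:
# relative power, its deviation from baseline, IAF-anchored bands and
# event-related desynchronization.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-halfbandwidth
#' product `nw` from the standard symmetric tridiagonal eigenproblem, each
#' normalised to unit energy. Results are cached per `(n, nw, k)`.
#'
#' @param n taper length in samples.
#' @param nw time-halfbandwidth product (`W_hz * T_s`).
#' @param k number of tapers, at most `2*nw - 1` for good concentration.
#' @return an `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  hit <- .alphanft_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t <- seq_len(n) - 1
  d <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  e <- t[-1] * (n - t[-1]) / 2
  tap <- tridiag_topk_eigen(d, e, k)$vectors
  # fix sign convention: even-order tapers positive mean, odd-order positive
  # initial slope (matches the usual Slepian convention)
  for (j in seq_len(k)) {
    s <- if (j %% 2 == 1L) sum(tap[, j]) else sum(diff(tap[, j])[1:max(1L, n %/% 2)])
    if (s < 0) tap[, j] <- -tap[, j]
  }
  tap <- sweep(tap, 2L, sqrt(colSums(tap^2)), "/")
  .alphanft_cache[[key]] <- tap
  tap
}

#' Spectral estimate container
#' @param freqs strictly increasing frequency bin centres (Hz).
#' @param psd channels x freqs matrix of power spectral density (uV^2/Hz);
#'   must be non-negative.
#' @return an object of class `spectral_estimate`.
#' @export
spectral_estimate <- function(freqs, psd) {
  if (!is.matrix(psd)) psd <- matrix(psd, nrow = 1L)
  stopifnot(ncol(psd) == length(freqs), all(diff(freqs) > 0),
            all(psd >= 0 | is.na(psd)))
  structure(list(freqs = as.numeric(freqs), psd = psd),
            class = "spectral_estimate")
}

#' Multitaper power spectral density
#'
#' DPSS-taper averaged one-sided PSD. Satisfies the Parseval contract: the
#' integral of the PSD over all bins matches the segment variance to within
#' a few percent for stationary signals.
#'
#' @param x a [raw_recording()] or a channels x samples matrix.
#' @param sfreq sampling rate (Hz); taken from the recording if omitted.
#' @param half_bandwidth spectral half-bandwidth W in Hz (default 2).
#' @param max_tapers cap on the taper count (the admissible `2 NW - 1`
#'   grows with segment length; beyond ~8 tapers the variance gain is
#'   marginal while cost grows).
#' @return a [spectral_estimate()].
#' @export
multitaper_psd <- function(x, sfreq = NULL, half_bandwidth = 2,
                           max_tapers = 8L) {
  if (inherits(x, "raw_recording")) {
    sfreq <- x$sfreq
    x <- x$data
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  if (is.null(sfreq)) stopf("sfreq required for matrix input")
  if (n < 0.5 * sfreq) stopf("segment too short for PSD: %d samples", n)
  nw <- half_bandwidth * n / sfreq
  k <- min(max(1L, floor(2 * nw - 1)), max_tapers)
  tap <- dpss_tapers(n, nw, k)
  xt <- t(x)
  xt <- xt - rep(colMeans(xt), each = n)
  nf <- n %/% 2 + 1L
  m <- ncol(xt)
  # pack two real channels per complex FFT and unscramble by symmetry
  odd <- seq(1L, m, by = 2L)
  even <- if (m >= 2L) seq(2L, m, by = 2L) else integer(0)
  Z <- xt[, odd, drop = FALSE] + 0i
  if (length(even)) Z[, seq_along(even)] <- Z[, seq_along(even)] +
      1i * xt[, even, drop = FALSE]
  iw <- c(1L, seq(n, n - nf + 2L))
  acc <- matrix(0, nf, m)
  for (j in seq_len(k)) {
    F <- stats::mvfft(Z * tap[, j])
    Fk <- F[seq_len(nf), , drop = FALSE]
    Fw <- Conj(F[iw, , drop = FALSE])
    acc[, odd] <- acc[, odd] + Mod((Fk + Fw) / 2)^2
    if (length(even))
      acc[, even] <- acc[, even] +
        Mod((Fk[, seq_along(even), drop = FALSE] -
               Fw[, seq_along(even), drop = FALSE]) / 2i)^2
  }
  psd <- t(acc) / (k * sfreq)
  # one-sided: double everything except DC and (if n even) Nyquist
  dbl <- rep(2, nf); dbl[1L] <- 1; if (n %% 2 == 0L) dbl[nf] <- 1
  psd <- sweep(psd, 2L, dbl, "*")
  freqs <- (seq_len(nf) - 1L) * sfreq / n
  spectral_estimate(freqs, psd)
}

#' Average multitaper PSD over non-overlapping windows
#'
#' The baseline/offline estimator: splits the recording into consecutive
#' `window_s`-second windows (remainder discarded) and averages their
#' multitaper PSDs, so offline quantities are numerically comparable to the
#' online 1 s engine windows.
#'
#' @inheritParams multitaper_psd
#' @param window_s window length in seconds (default 1).
#' @return a [spectral_estimate()].
#' @export
windowed_psd <- function(x, sfreq = NULL, half_bandwidth = 2, window_s = 1) {
  if (inherits(x, "raw_recording")) {
    sfreq <- x$sfreq
    x <- x$data
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  wlen <- as.integer(round(window_s * sfreq))
  nwin <- ncol(x) %/% wlen
  if (nwin < 1L) stopf("recording shorter than one %g s window", window_s)
  est <- NULL
  for (w in seq_len(nwin)) {
    seg <- x[, ((w - 1L) * wlen + 1L):(w * wlen), drop = FALSE]
    e <- multitaper_psd(seg, sfreq, half_bandwidth)
    est <- if (is.null(est)) e else spectral_estimate(e$freqs, est$psd + e$psd)
  }
  spectral_estimate(est$freqs, est$psd / nwin)
}

#' IAF-anchored frequency bands
#'
#' The five bands partition the total interval (1, 50) Hz exactly:
#' delta `[1, IAF-6)`, theta `[IAF-6, IAF-2)`, alpha `[IAF-2, IAF+2)`,
#' beta `[IAF+2, 30)`, gamma `[30, 50)`. Bands are half-open so the
#' partition is exact.
#'
#' @param iaf individual alpha frequency in Hz, inside `[8, 12]`.
#' @return an object of class `band_set`: named list of `c(lo, hi)` pairs
#'   plus attribute `total = c(1, 50)`.
#' @export
band_set <- function(iaf) {
  stopifnot(is.finite(iaf), iaf >= 8, iaf <= 12)
  bands <- list(delta = c(1, iaf - 6), theta = c(iaf - 6, iaf - 2),
                alpha = c(iaf - 2, iaf + 2), beta = c(iaf + 2, 30),
                gamma = c(30, 50))
  structure(bands, total = c(1, 50), iaf = iaf, class = "band_set")
}

#' Integrated band power
#'
#' Trapezoidal integral of the PSD over `[lo, hi)`, with linear
#' interpolation of the PSD at the band edges. Because adjacent bands share
#' their interpolated edge points, band powers are exactly additive over a
#' contiguous partition.
#'
#' @param est a [spectral_estimate()].
#' @param lo,hi band edges in Hz, `0 <= lo < hi <= max(freqs)`.
#' @return numeric vector of band power per channel (uV^2).
#' @export
band_power <- function(est, lo, hi) {
  if (hi <= lo) stopf("empty band [%g, %g)", lo, hi)
  f <- est$freqs
  if (lo < f[1L] || hi > f[length(f)])
    stopf("band [%g, %g) outside estimated range [%g, %g]",
          lo, hi, f[1L], f[length(f)])
  inner <- which(f > lo & f < hi)
  grid <- c(lo, f[inner], hi)
  vals <- cbind(interp_cols(est, lo),
                est$psd[, inner, drop = FALSE],
                interp_cols(est, hi))
  dw <- diff(grid)
  mid <- (vals[, -ncol(vals), drop = FALSE] + vals[, -1L, drop = FALSE]) / 2
  as.numeric(mid %*% dw)
}

interp_cols <- function(est, at) {
  f <- est$freqs
  i <- findInterval(at, f, all.inside = TRUE)
  w <- (at - f[i]) / (f[i + 1L] - f[i])
  (1 - w) * est$psd[, i] + w * est$psd[, i + 1L]
}

#' Relative band power
#'
#' `band_power(band) / band_power(total)` per channel; lies in `[0, 1]`
#' whenever `band` is contained in `total`. The alpha relative power (ARP)
#' of the feedback engine is this quantity with band = alpha, total =
#' (1, 50) Hz.
#'
#' @param est a [spectral_estimate()].
#' @param band `c(lo, hi)` numerator band (Hz).
#' @param total `c(lo, hi)` denominator band (Hz), default `c(1, 50)`.
#' @return numeric vector per channel.
#' @export
relative_power <- function(est, band, total = c(1, 50)) {
  pt <- band_power(est, total[1L], total[2L])
  if (any(pt <= 0)) stopf("zero total power in band [%g, %g)", total[1L], total[2L])
  band_power(est, band[1L], band[2L]) / pt
}

#' Proportional deviation from baseline
#'
#' `(value - baseline) / baseline`; the delta-ARP / delta-RP statistic.
#'
#' @param value current value(s).
#' @param baseline strictly positive baseline value(s).
#' @return deviation as a fraction of baseline.
#' @export
delta_relative <- function(value, baseline) {
  if (any(baseline <= 0)) stopf("baseline must be positive")
  (value - baseline) / baseline
}

#' Estimate the individual alpha frequency from an eyes-closed baseline
#'
#' Averages the windowed multitaper PSD over posterior channels (labels
#' starting P, PO or O), smooths it, and locates the largest local maximum
#' inside `search_range` whose height exceeds a robust 1/f background fit by
#' `margin`. Ties break to the lower frequency. When no qualifying peak
#' exists the fallback (10 Hz) is returned with attribute `fallback = TRUE`
#' and a warning.
#'
#' @param rec a [raw_recording()] of at least 30 s containing posterior
#'   channels.
#' @param search_range `c(lo, hi)` in Hz, default `c(7, 13)`.
#' @param fallback_hz value returned when no alpha peak is found.
#' @param margin multiplicative excess over the 1/f fit required of a peak.
#' @param half_bandwidth,window_s forwarded to [windowed_psd()].
#' @return IAF in Hz (scalar), with attribute `fallback`.
#' @export
estimate_iaf <- function(rec, search_range = c(7, 13), fallback_hz = 10,
                         margin = 1.5, half_bandwidth = 1, window_s = 4) {
  stopifnot(inherits(rec, "raw_recording"))
  if (duration(rec) < 30) stopf("need >= 30 s for IAF estimation")
  post <- grep("^(P|PO|O)[0-9Z]", rec$channel_names, value = TRUE)
  if (!length(post)) stopf("no posterior channels for IAF estimation")
  est <- windowed_psd(select_channels(rec, post), half_bandwidth = half_bandwidth,
                      window_s = window_s)
  p <- colMeans(est$psd)
  f <- est$freqs
  # moving-average smoothing over ~0.5 Hz
  kw <- max(1L, as.integer(round(0.5 / (f[2L] - f[1L]))))
  if (kw > 1L) p <- stats::filter(p, rep(1 / kw, kw), sides = 2)
  p <- as.numeric(p)
  # robust 1/f background: linear fit of log p vs log f outside the alpha range
  bgidx <- which(f >= 2 & f <= 40 & (f < search_range[1L] | f > search_range[2L]) &
                   !is.na(p) & p > 0)
  fit <- stats::lm(log(p[bgidx]) ~ log(f[bgidx]))
  idx <- which(f >= search_range[1L] & f <= search_range[2L] & !is.na(p))
  # flatten by the background fit so the 1/f tilt cannot bias the peak
  q <- rep(NA_real_, length(p))
  pos <- !is.na(p) & p > 0 & f > 0
  q[pos] <- p[pos] / exp(fit$coefficients[1L] + fit$coefficients[2L] * log(f[pos]))
  peak_iaf <- NA_real_
  if (length(idx) > 2L) {
    inner <- idx[-c(1L, length(idx))]
    is_peak <- q[inner] > q[inner - 1L] & q[inner] >= q[inner + 1L]
    cand <- inner[is_peak]
    if (length(cand)) {
      cand <- cand[q[cand] > margin]
      if (length(cand)) {
        pk <- cand[which.max(q[cand])]
        # sub-bin refinement: parabola through flattened log-power at the peak
        lp <- log(q[(pk - 1L):(pk + 1L)])
        denom <- lp[1L] - 2 * lp[2L] + lp[3L]
        shift <- if (is.finite(denom) && denom < 0)
          clip(0.5 * (lp[1L] - lp[3L]) / denom, -0.5, 0.5) else 0
        peak_iaf <- clip(f[pk] + shift * (f[2L] - f[1L]),
                         search_range[1L], search_range[2L])
      }
    }
  }
  if (is.na(peak_iaf)) {
    warning("no alpha peak above the 1/f background; falling back to ",
            fallback_hz, " Hz")
    return(structure(fallback_hz, fallback = TRUE))
  }
  structure(peak_iaf, fallback = FALSE)
}

#' Event-related desynchronization from epoched trials
#'
#' For each task label, averages the band power of the pre-task stage
#' `[-3, 0)` s and the task stage `[0, 4)` s over that label's trials (all
#' runs pooled), then forms `ERD = (P_task - P_pretask) / P_pretask`
#' per channel. Negative values indicate desynchronization.
#'
#' @param trials a [trial_set()] whose epochs span `[-3, 4)` s around onset.
#' @param band `c(lo, hi)` in Hz (the individual alpha band).
#' @param half_bandwidth spectral half-bandwidth (Hz).
#' @return matrix labels x channels of ERD fractions.
#' @export
compute_erd <- function(trials, band, half_bandwidth = 2) {
  stopifnot(inherits(trials, "trial_set"))
  sf <- trials$sfreq
  tmin <- trials$tmin
  npre <- as.integer(round(-tmin * sf))
  if (tmin > -3 + 1e-9 || dim(trials$epochs)[3L] < npre + 4 * sf)
    stopf("trials must span [-3, 4) s around onset (tmin = %g)", tmin)
  pre_idx <- seq_len(npre)
  task_idx <- npre + seq_len(as.integer(4 * sf))
  labs <- sort(unique(trials$labels))
  nch <- dim(trials$epochs)[2L]
  ntr <- dim(trials$epochs)[1L]
  # stage power = mean band power over the stage's non-overlapping 1 s
  # multitaper windows (the package-wide estimator), all trials batched
  # through one PSD call per stage
  wlen <- as.integer(sf)
  stage_power <- function(idx) {
    nwin <- length(idx) %/% wlen
    idx <- idx[seq_len(nwin * wlen)]
    A <- aperm(trials$epochs[, , idx, drop = FALSE], c(3L, 2L, 1L))
    X <- matrix(A, nrow = wlen)               # cols = (window, ch, trial)
    est <- multitaper_psd(t(X), sf, half_bandwidth)
    v <- band_power(est, band[1L], band[2L])
    matrix(colMeans(matrix(v, nrow = nwin)), nrow = nch, ncol = ntr)
  }
  p_pre <- stage_power(pre_idx)     # channels x trials
  p_task <- stage_power(task_idx)
  out <- matrix(NA_real_, length(labs), nch,
                dimnames = list(labs, trials$channel_names))
  for (li in seq_along(labs)) {
    tr <- trials$labels == labs[li]
    out[li, ] <- (rowMeans(p_task[, tr, drop = FALSE]) -
                    rowMeans(p_pre[, tr, drop = FALSE])) /
      rowMeans(p_pre[, tr, drop = FALSE])
  }
  out
}
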