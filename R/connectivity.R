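# Sensor-space functional connectivity on the 48 lateral electrodes:
# phase lag index (PLI) and imaginary coherence (imCoh) per IAF-anchored
# band, estimated on non-overlapping 5 s baseline segments, plus the
# edge-wise paired-t contrast between sessions.

#' Split a baseline recording into fixed-length segments
#'
#' Non-overlapping contiguous segments of `seg_s` seconds; the remainder is
#' discarded. A 1 min baseline yields exactly 12 five-second segments.
#'
#' @param rec a [raw_recording()].
#' @param seg_s segment length in seconds (default 5).
#' @return list of channels x samples matrices.
#' @export
segment_baseline <- function(rec, seg_s = 5) {
  wlen <- as.integer(round(seg_s * rec$sfreq))
  nseg <- ncol(rec$data) %/% wlen
  if (nseg < 1L)
    stopf("recording (%g s) shorter than one %g s segment",
          duration(rec), seg_s)
  lapply(seq_len(nseg), function(k)
    rec$data[, ((k - 1L) * wlen + 1L):(k * wlen), drop = FALSE])
}

# analytic band-limited signal by frequency-domain masking: zero negative
# frequencies, apply a cosine-tapered band mask on the positive axis.
# Chosen over FIR + Hilbert because a 2 Hz-transition FIR kernel for the
# delta band would outlast a 5 s segment.
analytic_band <- function(x, sfreq, lo, hi, taper_hz = 0.5) {
  n <- ncol(x)
  f <- (seq_len(n) - 1L) * sfreq / n
  mask <- numeric(n)
  pos <- f <= sfreq / 2
  m <- rep(0, n)
  ramp_up <- pos & f >= lo - taper_hz & f < lo
  ramp_dn <- pos & f > hi & f <= hi + taper_hz
  m[pos & f >= lo & f <= hi] <- 1
  m[ramp_up] <- 0.5 * (1 + cos(pi * (lo - f[ramp_up]) / taper_hz))
  m[ramp_dn] <- 0.5 * (1 + cos(pi * (f[ramp_dn] - hi) / taper_hz))
  X <- stats::mvfft(t(x))
  A <- t(stats::mvfft(X * (2 * m), inverse = TRUE)) / n
  A          # complex channels x samples
}

#' Connectivity matrix container
#' @param values symmetric channels x channels matrix with zero diagonal,
#'   entries in `[0, 1]`.
#' @param band band name. @param measure `"PLI"` or `"imCoh"`.
#' @param channel_names channel labels.
#' @return an object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, band, measure, channel_names = NULL) {
  stopifnot(isSymmetric(unname(values), tol = 1e-8),
            all(abs(diag(values)) < 1e-12),
            all(values >= -1e-12 & values <= 1 + 1e-9))
  if (!is.null(channel_names)) dimnames(values) <- list(channel_names,
                                                        channel_names)
  structure(list(values = values, band = band, measure = measure),
            class = "connectivity_matrix")
}

#' Phase lag index matrix
#'
#' Per segment, channels are band-limited and their instantaneous phases
#' extracted via the analytic signal; `PLI_ij = |mean_t sign(sin(phi_i -
#' phi_j))|`. Segment matrices are averaged. Insensitive to zero-lag
#' (volume-conducted) coupling: identical signals give PLI 0.
#'
#' @param segments list of channels x samples matrices
#'   (see [segment_baseline()]).
#' @param band `c(lo, hi)` in Hz.
#' @param sfreq sampling rate (Hz).
#' @param band_name label stored on the result.
#' @param channel_names labels stored on the result.
#' @return a [connectivity_matrix()].
#' @export
pli_matrix <- function(segments, band, sfreq, band_name = "band",
                       channel_names = NULL) {
  check_band(band, sfreq)
  nch <- nrow(segments[[1L]])
  acc <- matrix(0, nch, nch)
  for (seg in segments) {
    A <- analytic_band(seg, sfreq, band[1L], band[2L])
    P <- A / pmax(Mod(A), .Machine$double.xmin)     # unit phasors
    PT <- t(P)                                      # time x channels
    M <- matrix(0, nch, nch)
    for (i in seq_len(nch - 1L)) {
      # sign(sin(phi_i - phi_j)) = sign(Im(p_i * Conj(p_j))); column-wise
      # recycling of the time vector is exact in this orientation
      s <- sign(Im(PT[, i] * Conj(PT[, (i + 1L):nch, drop = FALSE])))
      M[i, (i + 1L):nch] <- abs(colMeans(s))
    }
    acc <- acc + M + t(M)
  }
  connectivity_matrix(acc / length(segments), band_name, "PLI", channel_names)
}

#' Imaginary coherence matrix
#'
#' Cross-spectra are estimated with the package's 1 s multitaper windows
#' within each segment; `imCoh_ij = |Im(S_ij)| / sqrt(S_ii S_jj)` is formed
#' per frequency bin, averaged over the band's bins, then over segments.
#' Magnitude convention: entries lie in `[0, 1]`.
#'
#' @inheritParams pli_matrix
#' @param half_bandwidth multitaper half-bandwidth (Hz).
#' @param window_s cross-spectral window length (s).
#' @return a [connectivity_matrix()].
#' @export
imcoh_matrix <- function(segments, band, sfreq, band_name = "band",
                         channel_names = NULL, half_bandwidth = 2,
                         window_s = 1) {
  check_band(band, sfreq)
  nch <- nrow(segments[[1L]])
  wlen <- as.integer(round(window_s * sfreq))
  nw <- half_bandwidth * wlen / sfreq
  k <- max(1L, floor(2 * nw - 1))
  tap <- dpss_tapers(wlen, nw, k)
  freqs <- (seq_len(wlen %/% 2 + 1L) - 1L) * sfreq / wlen
  bins <- which(freqs >= band[1L] & freqs < band[2L])
  if (!length(bins)) stopf("band [%g, %g) contains no frequency bins",
                           band[1L], band[2L])
  acc <- matrix(0, nch, nch)
  for (seg in segments) {
    nwin <- ncol(seg) %/% wlen
    S <- array(0, c(nch, nch, length(bins)))
    for (w in seq_len(nwin)) {
      x <- seg[, ((w - 1L) * wlen + 1L):(w * wlen), drop = FALSE]
      x <- x - rowMeans(x)
      for (j in seq_len(k)) {
        F <- stats::mvfft(t(x) * tap[, j])[bins, , drop = FALSE]
        for (b in seq_along(bins)) {
          v <- F[b, ]
          S[, , b] <- S[, , b] + v %o% Conj(v)
        }
      }
    }
    seg_acc <- matrix(0, nch, nch)
    for (b in seq_along(bins)) {
      Sb <- S[, , b]
      d <- Re(diag(Sb))
      seg_acc <- seg_acc + abs(Im(Sb)) / sqrt(pmax(d %o% d,
                                                   .Machine$double.xmin))
    }
    acc <- acc + seg_acc / length(bins)
  }
  vals <- acc / length(segments)
  diag(vals) <- 0
  connectivity_matrix(pmin(vals, 1), band_name, "imCoh", channel_names)
}

check_band <- function(band, sfreq) {
  if (band[2L] <= band[1L]) stopf("empty band")
  if (band[2L] > sfreq / 2) stopf("band [%g, %g) exceeds Nyquist (%g Hz)",
                                  band[1L], band[2L], sfreq / 2)
}

#' Edge-wise paired contrast of connectivity matrices
#'
#' Paired t-test per upper-triangle edge across matched subjects, with a
#' `p < 0.01` uncorrected mask and a Benjamini-Hochberg FDR mask. Edges
#' with zero difference variance are flagged (`degenerate`) and excluded
#' from both masks.
#'
#' @param pre_mats,post_mats lists of [connectivity_matrix()] (one per
#'   subject, same order and length).
#' @param alpha_unc uncorrected significance level (default 0.01).
#' @param alpha_fdr FDR level (default 0.05).
#' @return data frame with one row per edge: `i, j, t, p, p_fdr,
#'   sig_unc, sig_fdr, sign, degenerate`.
#' @export
edge_contrast <- function(pre_mats, post_mats, alpha_unc = 0.01,
                          alpha_fdr = 0.05) {
  if (length(pre_mats) != length(post_mats))
    stopf("mismatched subject lists (%d vs %d)",
          length(pre_mats), length(post_mats))
  n <- length(pre_mats)
  if (n < 2L) stopf("need at least 2 subjects")
  nch <- nrow(pre_mats[[1L]]$values)
  ut <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  D <- vapply(seq_len(n), function(s)
    (post_mats[[s]]$values - pre_mats[[s]]$values)[upper.tri(
      pre_mats[[s]]$values)], numeric(nrow(ut)))
  if (!is.matrix(D)) D <- matrix(D, nrow = 1L)
  m <- rowMeans(D)
  s <- apply(D, 1L, stats::sd)
  degen <- s == 0
  tval <- ifelse(degen, NA_real_, m / (s / sqrt(n)))
  p <- ifelse(degen, NA_real_, 2 * stats::pt(-abs(tval), df = n - 1L))
  p_fdr <- rep(NA_real_, length(p))
  ok <- !degen
  if (any(ok)) p_fdr[ok] <- fdr_bh(p[ok], alpha_fdr)$p_adjusted
  data.frame(i = ut[, 1L], j = ut[, 2L], t = tval, p = p, p_fdr = p_fdr,
             sig_unc = !degen & p < alpha_unc,
             sig_fdr = !degen & p_fdr <= alpha_fdr,
             sign = sign(m), degenerate = degen)
}
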