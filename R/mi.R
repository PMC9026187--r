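# Offline motor-imagery decoding: zero-phase FIR band-pass, epoching,
# one-versus-rest CSP spatial filtering, log-variance features and RBF-SVM
# with stratified 10-fold cross-validation.

#' Zero-phase FIR band-pass filter
#'
#' Linear-phase windowed-sinc (Hamming) design with a 2 Hz transition band,
#' applied forward and backward (FFT overlap-free convolution with
#' reflection padding) so the net phase response is zero. Single-pass
#' Hamming gives ~53 dB stopband attenuation; the two passes square the
#' magnitude response.
#'
#' @param rec a [raw_recording()] or channels x samples matrix.
#' @param lo,hi band edges in Hz (defaults 8 and 30).
#' @param sfreq sampling rate, required for matrix input; `hi` must be
#'   below Nyquist.
#' @param transition transition bandwidth in Hz.
#' @return same type as the input, filtered.
#' @export
fir_bandpass <- function(rec, lo = 8, hi = 30, sfreq = NULL, transition = 2) {
  is_rec <- inherits(rec, "raw_recording")
  x <- if (is_rec) rec$data else rec
  if (is_rec) sfreq <- rec$sfreq
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (is.null(sfreq)) stopf("sfreq required for matrix input")
  if (hi >= sfreq / 2) stopf("hi = %g Hz is not below Nyquist (%g Hz)",
                             hi, sfreq / 2)
  if (lo >= hi) stopf("need lo < hi")
  h <- fir_design(lo, hi, sfreq, transition)
  y <- filtfilt_fir(x, h)
  if (is_rec)
    raw_recording(y, sfreq, rec$channel_names, rec$channel_pos, rec$events)
  else y
}

#' @rdname fir_bandpass
#' @export
fir_design <- function(lo, hi, sfreq, transition = 2) {
  L <- as.integer(ceiling(3.3 * sfreq / transition))
  if (L %% 2L == 0L) L <- L + 1L
  m <- seq_len(L) - 1L - (L - 1L) / 2
  sinc <- function(fc) {
    out <- 2 * fc / sfreq * rep(1, L)
    nz <- m != 0
    out[nz] <- sin(2 * pi * fc / sfreq * m[nz]) / (pi * m[nz])
    out
  }
  h <- (sinc(hi) - sinc(lo)) *
    (0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1L) / (L - 1L)))
  # normalise to unit gain at band centre
  fc <- (lo + hi) / 2
  h / abs(sum(h * exp(-2i * pi * fc / sfreq * (seq_len(L) - 1L))))
}

# Zero-phase filtering. The kernel is symmetric, so the forward-backward
# cascade collapses to one convolution with the kernel autocorrelation
# g = h * h (zero phase, squared magnitude response). Channels are
# processed in blocks through one FFT each to keep memory bounded.
filtfilt_fir <- function(x, h) {
  g <- stats::convolve(h, h, type = "open")      # length 2L - 1, symmetric
  Lg <- length(g)
  half <- (Lg - 1L) %/% 2L
  n <- ncol(x)
  pad <- min(half, n)
  nfft <- stats::nextn(n + 2L * pad + Lg, c(2, 3, 5))
  G <- stats::fft(c(g, numeric(nfft - Lg)))
  out <- matrix(0, nrow(x), n)
  blocks <- split(seq_len(nrow(x)), ceiling(seq_len(nrow(x)) / 8))
  for (bl in blocks) {
    xp <- matrix(0, nfft, length(bl))
    xb <- t(x[bl, , drop = FALSE])
    xp[seq_len(pad), ] <- xb[pad:1, , drop = FALSE]
    xp[pad + seq_len(n), ] <- xb
    xp[pad + n + seq_len(pad), ] <- xb[n:(n - pad + 1L), , drop = FALSE]
    Y <- Re(stats::mvfft(stats::mvfft(xp) * G, inverse = TRUE)) / nfft
    out[bl, ] <- t(Y[half + pad + seq_len(n), , drop = FALSE])
  }
  out
}

#' Epoched trials container
#'
#' @param epochs trials x channels x samples array (uV).
#' @param labels per-trial task labels.
#' @param sfreq sampling rate (Hz).
#' @param tmin epoch start relative to the event onset (s).
#' @param channel_names channel labels.
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(epochs, labels, sfreq, tmin = 0,
                      channel_names = NULL) {
  stopifnot(length(dim(epochs)) == 3L, dim(epochs)[1L] == length(labels))
  structure(list(epochs = epochs, labels = as.character(labels),
                 sfreq = sfreq, tmin = tmin, channel_names = channel_names),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz [%s]\n",
              dim(x$epochs)[1L], dim(x$epochs)[2L], dim(x$epochs)[3L],
              x$sfreq, paste(names(table(x$labels)), table(x$labels),
                             sep = ":", collapse = " ")))
  invisible(x)
}

#' Cut trials around event onsets
#'
#' Extracts `[t0, t1)` s relative to every event onset, in event order.
#'
#' @param rec a [raw_recording()] with events.
#' @param t0,t1 epoch window relative to onset (s), default `[0, 4)`.
#' @return a [trial_set()] (empty when the recording has no events).
#' @export
epoch_trials <- function(rec, t0 = 0, t1 = 4) {
  sf <- rec$sfreq
  nspan <- as.integer(round(t1 * sf)) - as.integer(round(t0 * sf))
  ev <- rec$events
  if (!nrow(ev))
    return(trial_set(array(0, c(0L, nrow(rec$data), nspan)), character(0),
                     sf, t0, rec$channel_names))
  epochs <- array(NA_real_, c(nrow(ev), nrow(rec$data), nspan))
  for (k in seq_len(nrow(ev))) {
    i0 <- ev$onset[k] + as.integer(round(t0 * sf))
    i1 <- i0 + nspan
    if (i0 < 0L || i1 > ncol(rec$data))
      stopf("trial %d ('%s') at sample %d does not fit in the recording",
            k, ev$label[k], ev$onset[k])
    epochs[k, , ] <- rec$data[, (i0 + 1L):i1]
  }
  trial_set(epochs, ev$label, sf, t0, rec$channel_names)
}

# trace-normalised covariance of one epoch (channels x samples)
trial_cov <- function(e) {
  C <- tcrossprod(e - rowMeans(e))
  C / sum(diag(C))
}

#' Fit one-versus-rest common spatial patterns
#'
#' For each class (or the single pair when only two classes are present),
#' averages trace-normalised trial covariances for the class and the rest,
#' applies shrinkage regularisation, and solves the two-class CSP
#' generalised eigenproblem by whitening the composite covariance. The
#' `n_per_problem/2` filters from each eigenvalue extreme are kept.
#'
#' @param trials a [trial_set()] or trials x channels x samples array.
#' @param labels per-trial labels (taken from `trials` if a trial set).
#' @param n_per_problem filters kept per OVR subproblem (default 4).
#' @param shrinkage covariance shrinkage weight toward the scaled identity.
#' @return an object of class `csp_model` with one filter matrix
#'   (`n_per_problem` x channels) per subproblem.
#' @export
csp_fit <- function(trials, labels = NULL, n_per_problem = 4L,
                    shrinkage = 0.05) {
  if (inherits(trials, "trial_set")) {
    labels <- trials$labels
    trials <- trials$epochs
  }
  covs <- lapply(seq_len(dim(trials)[1L]), function(k)
    trial_cov(trials[k, , , drop = TRUE]))
  csp_fit_from_covs(covs, labels, n_per_problem, shrinkage)
}

# CSP from precomputed trace-normalised trial covariances
csp_fit_from_covs <- function(covs, labels, n_per_problem = 4L,
                              shrinkage = 0.05) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stopf("need at least 2 classes")
  if (any(table(labels) < 2L)) stopf("need at least 2 trials per class")
  nch <- nrow(covs[[1L]])
  class_cov <- function(idx) {
    C <- Reduce(`+`, covs[idx]) / length(idx)
    (1 - shrinkage) * C + shrinkage * (sum(diag(C)) / nch) * diag(nch)
  }
  problems <- if (length(classes) == 2L) list(classes[1L]) else as.list(classes)
  filters <- lapply(problems, function(cl) {
    C1 <- class_cov(which(labels == cl))
    C2 <- class_cov(which(labels != cl))
    csp_pair_filters(C1, C2, n_per_problem)
  })
  names(filters) <- vapply(problems, identity, "")
  structure(list(filters = filters, classes = classes, n_channels = nch,
                 n_per_problem = as.integer(n_per_problem)),
            class = "csp_model")
}

# two-class CSP: eigenvectors of whitened C1, extremes of the spectrum
csp_pair_filters <- function(C1, C2, n_keep) {
  Cc <- C1 + C2
  eg <- eigen(Cc, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values))
    stopf("rank-deficient composite covariance; increase shrinkage or channels")
  W <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  S <- W %*% C1 %*% t(W)
  eg2 <- eigen((S + t(S)) / 2, symmetric = TRUE)
  n_side <- n_keep %/% 2L
  pick <- c(seq_len(n_side), nrow(S) - seq_len(n_keep - n_side) + 1L)
  V <- eg2$vectors[, pick, drop = FALSE]
  t(V) %*% W                              # filters in rows
}

#' Log-variance CSP features
#'
#' Projects each epoch through every subproblem's spatial filters and takes
#' the log of the variance of each projected signal (variances are floored
#' at `1e-12` of the epoch's mean channel variance, so an all-zero epoch
#' errors rather than producing `-Inf`).
#'
#' @param model a `csp_model` from [csp_fit()].
#' @param trials a [trial_set()] or array fitted on the same channel set.
#' @return trials x features matrix (`n_problems * n_per_problem` columns).
#' @export
csp_features <- function(model, trials) {
  if (inherits(trials, "trial_set")) trials <- trials$epochs
  if (dim(trials)[2L] != model$n_channels)
    stopf("channel mismatch: model has %d, data has %d",
          model$n_channels, dim(trials)[2L])
  n <- dim(trials)[1L]
  F <- do.call(rbind, model$filters)
  out <- matrix(NA_real_, n, nrow(F))
  for (k in seq_len(n)) {
    e <- trials[k, , , drop = TRUE]
    tot <- mean(apply(e, 1L, stats::var))
    if (!is.finite(tot) || tot <= 0)
      stopf("epoch %d has zero variance", k)
    v <- apply(F %*% e, 1L, stats::var)
    out[k, ] <- log(pmax(v, 1e-12 * tot))
  }
  out
}

#' Cross-validated motor-imagery decoding accuracy
#'
#' Stratified 10-fold cross-validation of the full FIR -> CSP -> RBF-SVM
#' pipeline on pre-filtered epochs. CSP filters, feature standardisation
#' and the SVM (including its median-heuristic kernel width) are fitted
#' inside each training fold only. Accuracy is the mean over folds.
#'
#' @param trials a [trial_set()] of band-passed `[0, 4)` s epochs.
#' @param scheme `"three_class"`, `"L_vs_R"`, `"L_vs_I"` or `"R_vs_I"`.
#' @param seed RNG seed for fold assignment and the SVM.
#' @param folds number of folds (default 10).
#' @param n_per_problem CSP filters per OVR subproblem.
#' @return mean fold accuracy (fraction).
#' @export
evaluate_cv <- function(trials, scheme = c("three_class", "L_vs_R", "L_vs_I",
                                           "R_vs_I"),
                        seed = 1L, folds = 10L, n_per_problem = 4L) {
  scheme <- match.arg(scheme)
  keep_labels <- switch(scheme,
    three_class = c("left", "right", "idle"),
    L_vs_R = c("left", "right"),
    L_vs_I = c("left", "idle"),
    R_vs_I = c("right", "idle"))
  sel <- trials$labels %in% keep_labels
  epochs <- trials$epochs[sel, , , drop = FALSE]
  labels <- trials$labels[sel]
  counts <- table(labels)
  if (length(counts) < length(keep_labels) || any(counts < folds))
    stopf("need at least %d trials in every class", folds)
  fold_id <- with_seed(derive_seed(seed, "folds"), {
    id <- integer(length(labels))
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
  # trial covariances once; CSP fits and log-variance features are
  # quadratic forms in them, so folds reuse the same matrices
  nsamp <- dim(epochs)[3L]
  covs_raw <- lapply(seq_len(dim(epochs)[1L]), function(k) {
    e <- epochs[k, , , drop = TRUE]
    tcrossprod(e - rowMeans(e))
  })
  covs_norm <- lapply(covs_raw, function(C) C / sum(diag(C)))
  features_from_covs <- function(model, idx) {
    F <- do.call(rbind, model$filters)
    t(vapply(idx, function(k) {
      v <- rowSums((F %*% covs_raw[[k]]) * F) / (nsamp - 1L)
      tot <- mean(diag(covs_raw[[k]])) / (nsamp - 1L)
      if (!is.finite(tot) || tot <= 0) stopf("epoch %d has zero variance", k)
      log(pmax(v, 1e-12 * tot))
    }, numeric(length(model$filters) * model$n_per_problem)))
  }
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    model <- csp_fit_from_covs(covs_norm[tr], labels[tr], n_per_problem)
    Xtr <- features_from_covs(model, which(tr))
    Xte <- features_from_covs(model, which(!tr))
    mu <- colMeans(Xtr)
    sd <- apply(Xtr, 2L, stats::sd)
    sd[sd == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sd, "/")
    Xte <- sweep(sweep(Xte, 2L, mu), 2L, sd, "/")
    fit <- svm_fit(Xtr, labels[tr], seed = derive_seed(seed, paste0("svm", f)))
    mean(predict(fit, Xte) == labels[!tr])
  }, 0)
  mean(acc)
}
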