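#' Multichannel EEG recording container
#'
#' A `raw_recording` bundles a channels x samples signal matrix (microvolts)
#' with its sampling rate, upper-cased 10-10 channel labels, 2-D scalp layout
#' coordinates and event annotations. Events are stored as
#' `(onset, duration, label)` where onset and duration are in samples and
#' onsets are 0-based (onset 0 is the first sample), matching the half-open
#' `[t0, t1)` interval convention used throughout the package.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sfreq sampling rate in Hz, positive scalar.
#' @param channel_names character vector, one label per row of `data`.
#'   Labels are upper-cased on construction and must be unique.
#' @param channel_pos optional channels x 2 matrix of layout coordinates;
#'   computed from the standard 10-10 layout when `NULL`.
#' @param events data frame with columns `onset`, `duration` (samples) and
#'   `label`, or `NULL` for no events.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, sfreq, channel_names, channel_pos = NULL,
                          events = NULL) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  storage.mode(data) <- "double"
  if (length(sfreq) != 1L || !is.finite(sfreq) || sfreq <= 0)
    stopf("sfreq must be a positive scalar, got %s", format(sfreq))
  channel_names <- toupper(as.character(channel_names))
  if (nrow(data) != length(channel_names))
    stopf("data has %d rows but %d channel names", nrow(data),
          length(channel_names))
  if (anyDuplicated(channel_names))
    stopf("duplicate channel names: %s",
          paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (is.null(channel_pos)) channel_pos <- channel_positions(channel_names)
  channel_pos <- as.matrix(channel_pos)
  if (nrow(channel_pos) != nrow(data) || ncol(channel_pos) != 2L)
    stopf("channel_pos must be a %d x 2 matrix", nrow(data))
  if (is.null(events)) {
    events <- data.frame(onset = integer(0), duration = integer(0),
                         label = character(0), stringsAsFactors = FALSE)
  }
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "label") %in% names(events)))
  events$onset <- as.integer(round(events$onset))
  events$duration <- as.integer(round(events$duration))
  events$label <- as.character(events$label)
  n <- ncol(data)
  if (nrow(events) && (any(events$onset < 0L) || any(events$onset >= n)))
    stopf("event onsets must lie in [0, %d)", n)
  rownames(data) <- channel_names
  structure(list(data = data, sfreq = as.numeric(sfreq),
                 channel_names = channel_names, channel_pos = channel_pos,
                 events = events),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$sfreq,
              ncol(x$data) / x$sfreq, nrow(x$events)))
  invisible(x)
}

#' Number of samples and duration of a recording
#' @param rec a `raw_recording`.
#' @return `n_samples()`: integer sample count; `duration()`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration <- function(rec) ncol(rec$data) / rec$sfreq

#' Select a subset of channels
#'
#' Returns the sub-recording containing `names` in the requested order.
#' Events are untouched.
#'
#' @param rec a `raw_recording`.
#' @param names channel labels to keep (case-insensitive).
#' @return a `raw_recording` with `length(names)` channels.
#' @export
select_channels <- function(rec, names) {
  names <- toupper(names)
  idx <- match(names, rec$channel_names)
  if (anyNA(idx))
    stopf("unknown channel(s): %s", paste(names[is.na(idx)], collapse = ", "))
  raw_recording(rec$data[idx, , drop = FALSE], rec$sfreq,
                rec$channel_names[idx], rec$channel_pos[idx, , drop = FALSE],
                rec$events)
}

#' Extract a time slice of a recording
#'
#' Half-open sample interval `[round(t0 * sfreq), round(t1 * sfreq))`.
#' Events are shifted to the new time origin; events whose onset falls
#' outside the slice are dropped.
#'
#' @param rec a `raw_recording`.
#' @param t0,t1 slice boundaries in seconds, `0 <= t0 < t1 <= duration`.
#' @return a `raw_recording` of `round(t1*sfreq) - round(t0*sfreq)` samples.
#' @export
slice_interval <- function(rec, t0, t1) {
  if (t1 <= t0) stopf("t1 (%g) must exceed t0 (%g)", t1, t0)
  if (t0 < 0 || t1 > duration(rec) + 0.5 / rec$sfreq)
    stopf("slice [%g, %g) outside recording of %g s", t0, t1, duration(rec))
  i0 <- round(t0 * rec$sfreq)
  i1 <- round(t1 * rec$sfreq)
  keep <- rec$events$onset >= i0 & rec$events$onset < i1
  ev <- rec$events[keep, , drop = FALSE]
  ev$onset <- ev$onset - i0
  raw_recording(rec$data[, (i0 + 1L):i1, drop = FALSE], rec$sfreq,
                rec$channel_names, rec$channel_pos, ev)
}

#' Standard 2-D layout coordinates for 10-10 channel labels
#'
#' Produces an idealised top-view layout: anterior-posterior rows (Fp ... O)
#' map to decreasing y, the label digit maps to left (odd, negative x) or
#' right (even, positive x) positions. EOG channels are placed above the
#' scalp outline. Sufficient for Gaussian forward mixing and topographies;
#' not a digitised montage.
#'
#' @param names character vector of channel labels.
#' @return a `length(names)` x 2 matrix of (x, y) coordinates.
#' @export
channel_positions <- function(names) {
  names <- toupper(names)
  rows <- c(FP = 1.0, AF = 0.78, F = 0.55, FC = 0.28, C = 0.0,
            CP = -0.28, P = -0.55, PO = -0.78, O = -1.0)
  pos <- matrix(NA_real_, length(names), 2L,
                dimnames = list(names, c("x", "y")))
  for (i in seq_along(names)) {
    nm <- names[i]
    if (nm %in% c("HEOG", "VEOG", "EOG")) {
      pos[i, ] <- switch(nm, HEOG = c(0.55, 1.25), VEOG = c(-0.25, 1.2),
                         EOG = c(0, 1.25))
      next
    }
    if (nm %in% c("T7", "T8")) nm <- sub("T", "C", nm)   # T7/T8 = C7/C8 slot
    m <- regmatches(nm, regexec("^([A-Z]+)([0-9]|Z)$", nm))[[1]]
    if (length(m) != 3L || !(m[2] %in% names(rows))) {
      # non-10-10 label (external recordings): deterministic slot on a ring
      # outside the scalp outline
      ang <- 2 * pi * (sum(utf8ToInt(nm)) %% 360) / 360
      pos[i, ] <- 1.4 * c(cos(ang), sin(ang))
      next
    }
    y <- rows[[m[2]]]
    if (m[3] == "Z") {
      x <- 0
    } else {
      d <- as.integer(m[3])
      rank <- ceiling(d / 2)                 # 1,2 -> 1 ... 7,8 -> 4
      x <- (if (d %% 2 == 1L) -1 else 1) * rank * 0.22
    }
    # shrink lateral extent near the rim so everything stays in a disc
    pos[i, ] <- c(x * sqrt(max(0.15, 1 - 0.55 * y^2)) / 0.88, y * 0.9)
  }
  pos
}

#' Electrode montage: scalp set, midline, NFT target and EOG groups
#'
#' The montage fixes which of the recorded channels form the 56-channel
#' scalp set, the 8 midline electrodes excluded from lateralised
#' connectivity, the 16 frontal electrodes averaged by the neurofeedback
#' engine, and the EOG channels used for artifact detection. Counts are
#' invariant: 56 scalp, 8 midline (Fpz, Fz, FCz, Cz, CPz, Pz, POz, Oz
#' exactly), 16 frontal targets, all subsets of the scalp set.
#'
#' @param scalp 56 scalp channel labels.
#' @param frontal16 the 16 frontal NFT target labels (subset of `scalp`).
#' @param eog EOG channel labels (horizontal, vertical).
#' @return an object of class `montage` with fields `scalp`, `midline`,
#'   `frontal16`, `eog`, `lateral48`.
#' @export
montage <- function(scalp = default_scalp_names(),
                    frontal16 = default_frontal16_names(),
                    eog = c("HEOG", "VEOG")) {
  scalp <- toupper(scalp); frontal16 <- toupper(frontal16); eog <- toupper(eog)
  midline <- c("FPZ", "FZ", "FCZ", "CZ", "CPZ", "PZ", "POZ", "OZ")
  if (length(scalp) != 56L || anyDuplicated(scalp))
    stopf("scalp set must contain 56 unique labels, got %d", length(scalp))
  if (!all(midline %in% scalp))
    stopf("scalp set must contain the 8 midline electrodes")
  if (length(frontal16) != 16L || !all(frontal16 %in% scalp))
    stopf("frontal16 must be 16 labels contained in the scalp set")
  structure(list(scalp = scalp, midline = midline, frontal16 = frontal16,
                 eog = eog, lateral48 = setdiff(scalp, midline)),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d scalp / %d midline / %d frontal targets / EOG: %s\n",
              length(x$scalp), length(x$midline), length(x$frontal16),
              paste(x$eog, collapse = ", ")))
  invisible(x)
}

#' @rdname montage
#' @export
default_scalp_names <- function() {
  c("FP1", "FPZ", "FP2",
    "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
    "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6",
    "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6",
    "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POZ", "PO4", "PO8",
    "O1", "OZ", "O2")
}

#' @rdname montage
#' @export
default_frontal16_names <- function() {
  c("FP1", "FPZ", "FP2", "AF3", "AF4", "AF7", "AF8",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8")
}
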