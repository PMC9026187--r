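# Minimal EDF+C reader/writer.
#
# 16-bit European Data Format with one "EDF Annotations" signal carrying
# events as time-stamped annotation lists (TALs). Only the subset needed for
# interchange of this package's recordings is implemented: continuous
# recordings, physical dimension uV, one annotation channel. Record duration
# is 1 s when the recording length is an integer number of seconds, otherwise
# a single record spanning the whole recording is used (valid EDF, avoids
# padding that would break round-trip identity).

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

num_field <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 8)
  if (nchar(s) > width) s <- substr(format(x, scientific = FALSE), 1L, width)
  pad_field(s, width)
}

#' Write a recording to an EDF+ file
#'
#' Signals are stored as 16-bit integers with a per-channel symmetric
#' physical range covering the data (quantization step
#' `(pmax - pmin)/65534`); events go into an `EDF Annotations` channel as
#' onset/duration/label TALs in seconds.
#'
#' @param rec a [raw_recording()]; all samples must be finite.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  if (ncol(rec$data) == 0L || nrow(rec$data) == 0L)
    stopf("cannot write an empty recording")
  if (!all(is.finite(rec$data)))
    stopf("cannot write non-finite samples to EDF")
  nchan <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  if (nsamp %% rec$sfreq == 0) {
    rec_dur <- 1
    n_rec <- nsamp / rec$sfreq
  } else {
    rec_dur <- nsamp / rec$sfreq
    n_rec <- 1L
  }
  spr <- as.integer(round(rec_dur * rec$sfreq))   # samples per record/signal

  # physical scaling, symmetric per channel
  pmax <- pmax(apply(abs(rec$data), 1L, max), 1)
  pmax <- ceiling(pmax)
  dmax <- 32767

  # annotations: timestamp TAL per record + event TALs in their onset record
  ev <- rec$events
  tals <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    t0 <- (r - 1L) * rec_dur
    s <- sprintf("+%s\x14\x14", format(t0, scientific = FALSE))
    if (nrow(ev)) {
      in_rec <- which(ev$onset >= (r - 1L) * spr & ev$onset < r * spr)
      for (k in in_rec) {
        s <- paste0(s, sprintf("+%s\x15%s\x14%s\x14",
                               format(ev$onset[k] / rec$sfreq, scientific = FALSE),
                               format(ev$duration[k] / rec$sfreq, scientific = FALSE),
                               ev$label[k]))
      }
    }
    tals[[r]] <- s
  }
  ann_bytes <- max(vapply(tals, function(s) nchar(s, type = "bytes"), 0L)) + 2L
  ann_spr <- as.integer(ceiling(ann_bytes / 2))

  ns <- nchan + 1L
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field("X X X X", 80))
  wr(pad_field("Startdate 01-JAN-2026 X X X", 80))
  wr(pad_field("01.01.26", 8))
  wr(pad_field("00.00.00", 8))
  wr(num_field(header_bytes, 8))
  wr(pad_field("EDF+C", 44))
  wr(num_field(n_rec, 8))
  wr(num_field(rec_dur, 8))
  wr(num_field(ns, 4))
  labels <- c(rec$channel_names, "EDF Annotations")
  for (l in labels) wr(pad_field(l, 16))
  for (i in seq_len(ns)) wr(pad_field("", 80))                  # transducer
  wr(paste(vapply(seq_len(ns), function(i)
    pad_field(if (i <= nchan) "uV" else "", 8), ""), collapse = ""))
  for (i in seq_len(ns)) wr(num_field(if (i <= nchan) -pmax[i] else -1, 8))
  for (i in seq_len(ns)) wr(num_field(if (i <= nchan) pmax[i] else 1, 8))
  for (i in seq_len(ns)) wr(num_field(-dmax, 8))
  for (i in seq_len(ns)) wr(num_field(dmax, 8))
  for (i in seq_len(ns)) wr(pad_field("", 80))                  # prefilter
  for (i in seq_len(ns)) wr(num_field(if (i <= nchan) spr else ann_spr, 8))
  for (i in seq_len(ns)) wr(pad_field("", 32))

  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    block <- rec$data[, cols, drop = FALSE]
    dig <- round(sweep(block, 1L, pmax, "/") * dmax)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
    raw_tal <- charToRaw(tals[[r]])
    raw_tal <- c(raw_tal, raw(2L * ann_spr - length(raw_tal)))
    writeBin(raw_tal, con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into a recording
#'
#' Parses the signal headers, converts 16-bit samples back to physical
#' units, and decodes event annotations from any `EDF Annotations` channel.
#' All ordinary signals must share one sampling rate. A missing annotation
#' channel yields a recording with an empty event table and a warning.
#'
#' @param path path to an existing EDF file.
#' @return a [raw_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("cannot read EDF file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (nchar(s, type = "bytes") < n) stopf("truncated EDF header in %s", path)
    s
  }
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient/recording/date/time
  rd(8)                                   # header bytes
  rd(44)                                  # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stopf("invalid EDF signal count in %s", path)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  is_ann <- labels == "EDF Annotations"
  sig <- which(!is_ann)
  if (!length(sig)) stopf("EDF file %s contains no ordinary signals", path)
  sfreq <- spr[sig] / rec_dur
  if (length(unique(sfreq)) != 1L)
    stopf("mixed sampling rates in %s are not supported", path)
  sfreq <- sfreq[1L]

  data <- matrix(0, length(sig), n_rec * spr[sig[1L]])
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        bytes <- readBin(con, "raw", 2L * spr[i])
        ann_text <- c(ann_text, rawToChar(bytes[bytes != as.raw(0)]))
      } else {
        v <- readBin(con, "integer", spr[i], size = 2L, endian = "little")
        j <- match(i, sig)
        scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
        cols <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
        data[j, cols] <- pmin[i] + (v - dmin[i]) * scale
      }
    }
  }
  events <- parse_tals(paste(ann_text, collapse = ""), sfreq)
  if (!any(is_ann))
    warning("no annotation channel in ", path, "; returning empty events")
  raw_recording(data, sfreq, labels[sig], events = events)
}

# Decode "+onset[\x15dur]\x14label\x14" TALs; timestamp-only TALs (empty
# label) are record keepers, not events.
parse_tals <- function(text, sfreq) {
  out <- list()
  for (tal in strsplit(text, "\x14\x14|\x14(?=[+-])", perl = TRUE)[[1]]) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14")[[1]]
    head <- strsplit(parts[1L], "\x15")[[1]]
    onset_s <- suppressWarnings(as.numeric(head[1L]))
    if (is.na(onset_s)) next
    dur_s <- if (length(head) > 1L) as.numeric(head[2L]) else 0
    labs <- parts[-1L]
    labs <- labs[nzchar(labs)]
    for (lb in labs)
      out[[length(out) + 1L]] <- data.frame(
        onset = as.integer(round(onset_s * sfreq)),
        duration = as.integer(round(dur_s * sfreq)),
        label = lb, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(onset = integer(0), duration = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
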