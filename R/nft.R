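# Online closed-loop alpha neurofeedback engine.
#
# The continuous recording is segmented into 1 s epochs updated every
# 100 ms. Each epoch's frontal-mean alpha relative power (ARP) is compared
# with the fixed eyes-open baseline ARP; the proportional deviation (dARP)
# drives the feedback bar, and a dynamic threshold governs sparse smiley
# rewards: it rises by one stride when most recent epochs beat it, and falls
# (never below the floor) when the whole ring buffer elapses with too few.

#' Engine configuration
#'
#' Defaults fix the published operating point: 1 s windows updated every
#' 100 ms, ring buffer of 100 deviations (~10 s), initial threshold 10%,
#' stride 1%, floor 1%. The smiley window (30 frames = 3 s at 0.8 success
#' fraction) and the lowering rule (< 0.2 success over the full buffer)
#' are configurable implementation choices.
#'
#' @param window_s epoch length (s). @param update_s frame period (s).
#' @param buffer_max ring-buffer capacity (frames).
#' @param th_init,th_stride,th_floor threshold initial value, step, floor.
#' @param smiley_window_frames,smiley_fraction reward criterion: fraction of
#'   the trailing window whose dARP must exceed the threshold.
#' @param lower_fraction below this success fraction over a full buffer the
#'   threshold is lowered.
#' @param eog_abs_threshold absolute EOG amplitude (uV) flagging an artifact.
#' @param pause_frames frames of feedback pause after an artifact.
#' @param arp_min smallest admissible baseline ARP (degenerate-input guard).
#' @return an object of class `nft_config`.
#' @export
nft_config <- function(window_s = 1.0, update_s = 0.1, buffer_max = 100L,
                       th_init = 0.10, th_stride = 0.01, th_floor = 0.01,
                       smiley_window_frames = 30L, smiley_fraction = 0.8,
                       lower_fraction = 0.2, eog_abs_threshold = 100,
                       pause_frames = 5L, arp_min = 0.01) {
  stopifnot(th_floor <= th_init, buffer_max >= 1L,
            smiley_fraction > 0, smiley_fraction <= 1,
            window_s > 0, update_s > 0)
  structure(list(window_s = window_s, update_s = update_s,
                 buffer_max = as.integer(buffer_max), th_init = th_init,
                 th_stride = th_stride, th_floor = th_floor,
                 smiley_window_frames = as.integer(smiley_window_frames),
                 smiley_fraction = smiley_fraction,
                 lower_fraction = lower_fraction,
                 eog_abs_threshold = eog_abs_threshold,
                 pause_frames = as.integer(pause_frames), arp_min = arp_min),
            class = "nft_config")
}

#' Initialise the engine from an eyes-open baseline
#'
#' Computes the fixed session baseline `arp_baseline` as the mean over the
#' 16 frontal target channels of the baseline's alpha relative power
#' (alpha band `iaf +- 2` Hz over the total band (1, 50) Hz), estimated
#' with the same 1 s multitaper windows the online loop uses.
#'
#' @param eo_baseline_rec eyes-open baseline [raw_recording()], >= 30 s.
#' @param iaf individual alpha frequency (Hz) from the eyes-closed baseline.
#' @param config an [nft_config()].
#' @param mont a [montage()].
#' @return an `nft_state` list: fixed baseline, empty ring buffer, threshold
#'   at `th_init`.
#' @export
init_engine <- function(eo_baseline_rec, iaf, config = nft_config(),
                        mont = montage()) {
  if (duration(eo_baseline_rec) < 30)
    stopf("baseline must be at least 30 s")
  front <- select_channels(eo_baseline_rec, mont$frontal16)
  est <- windowed_psd(front, half_bandwidth = 2, window_s = config$window_s)
  arp <- mean(relative_power(est, c(iaf - 2, iaf + 2)))
  if (arp < config$arp_min)
    stopf("degenerate baseline: frontal ARP %.4g below %g", arp, config$arp_min)
  structure(list(arp_baseline = arp, iaf = iaf, buffer = numeric(0),
                 th = config$th_init, paused_remaining = 0L,
                 smiley_count = 0L, frame_index = 0L,
                 frames_since_smiley_eval = 0L, frames_since_lower_eval = 0L,
                 config = config, montage = mont),
            class = "nft_state")
}

#' EOG artifact detector
#'
#' Flags an artifact when any sample's absolute amplitude strictly exceeds
#' the configured threshold.
#'
#' @param eog_window numeric vector or matrix of EOG samples (uV).
#' @param threshold absolute amplitude threshold (uV).
#' @return logical flag.
#' @export
detect_eog_artifact <- function(eog_window, threshold = 100) {
  max(abs(eog_window)) > threshold
}

#' Advance the engine by one feedback frame
#'
#' With an artifact (or during a pause) a neutral paused frame is emitted
#' and neither the buffer nor the threshold changes. Otherwise the window's
#' frontal-mean ARP yields `dARP = (ARP - ARP_baseline)/ARP_baseline`, the
#' bar value is `clip(dARP / (2 th), -1, 1)`, the ring buffer is appended
#' (evicting the oldest entry beyond capacity) and the dynamic threshold
#' rule of [update_threshold()] runs.
#'
#' @param state an `nft_state` from [init_engine()].
#' @param window frontal-channels x samples matrix covering exactly one
#'   engine window (1 s).
#' @param eog_window EOG samples for the same window.
#' @param sfreq sampling rate (Hz).
#' @return `list(state = <updated state>, frame = <feedback_frame row>)`.
#' @export
nft_step <- function(state, window, eog_window, sfreq = 500) {
  cfg <- state$config
  if (ncol(window) != as.integer(round(cfg$window_s * sfreq)))
    stopf("window must contain exactly %g s of samples", cfg$window_s)
  state$frame_index <- state$frame_index + 1L
  t <- state$frame_index * cfg$update_s + (cfg$window_s - cfg$update_s)

  paused <- FALSE
  if (state$paused_remaining > 0L) {
    state$paused_remaining <- state$paused_remaining - 1L
    paused <- TRUE
  } else if (detect_eog_artifact(eog_window, cfg$eog_abs_threshold)) {
    state$paused_remaining <- cfg$pause_frames - 1L
    paused <- TRUE
  }
  if (paused) {
    frame <- feedback_frame(t, NA_real_, 0, "neutral", FALSE, TRUE, state$th)
    return(list(state = state, frame = frame))
  }

  est <- multitaper_psd(window, sfreq, half_bandwidth = 2)
  arp <- mean(relative_power(est, c(state$iaf - 2, state$iaf + 2)))
  d <- delta_relative(arp, state$arp_baseline)
  state$buffer <- c(state$buffer, d)
  if (length(state$buffer) > cfg$buffer_max)
    state$buffer <- state$buffer[-1L]
  state$frames_since_smiley_eval <- state$frames_since_smiley_eval + 1L
  state$frames_since_lower_eval <- state$frames_since_lower_eval + 1L

  upd <- update_threshold(state)
  state <- upd$state
  color <- if (d > 0) "green" else if (d < 0) "red" else "neutral"
  frame <- feedback_frame(t, d, clip(d / (2 * state$th), -1, 1), color,
                          upd$smiley, FALSE, state$th)
  list(state = state, frame = frame)
}

feedback_frame <- function(t, d, bar, color, smiley, paused, th) {
  data.frame(t = t, delta_arp = d, bar_value = bar, color = color,
             smiley = smiley, paused = paused, th = th,
             stringsAsFactors = FALSE)
}

#' Dynamic threshold update
#'
#' Reward rule: once at least `smiley_window_frames` frames have elapsed
#' since the last evaluation, if the fraction of those trailing frames with
#' `dARP > th` reaches `smiley_fraction`, a smiley is emitted, the threshold
#' rises by one stride, and the evaluation window restarts. Lowering rule:
#' if a full ring buffer (`buffer_max` frames) elapses with the success
#' fraction below `lower_fraction`, the threshold drops one stride, never
#' below the floor.
#'
#' @param state an `nft_state` whose buffer already contains the newest
#'   deviation.
#' @return `list(state, smiley)`.
#' @export
update_threshold <- function(state) {
  cfg <- state$config
  smiley <- FALSE
  if (state$frames_since_smiley_eval >= cfg$smiley_window_frames) {
    recent <- utils::tail(state$buffer, cfg$smiley_window_frames)
    if (mean(recent > state$th) >= cfg$smiley_fraction) {
      smiley <- TRUE
      state$smiley_count <- state$smiley_count + 1L
      state$th <- state$th + cfg$th_stride
      state$frames_since_smiley_eval <- 0L
      state$frames_since_lower_eval <- 0L
    }
  }
  if (state$frames_since_lower_eval >= cfg$buffer_max) {
    if (mean(state$buffer > state$th) < cfg$lower_fraction)
      state$th <- max(cfg$th_floor, state$th - cfg$th_stride)
    state$frames_since_lower_eval <- 0L
  }
  list(state = state, smiley = smiley)
}

#' Run a closed-loop neurofeedback session on a virtual subject
#'
#' Couples the streaming generator to the engine at the 10 Hz frame rate:
#' each frame the generator emits 100 ms of EEG at the subject's current
#' alpha amplitude, the engine evaluates the trailing 1 s window, and the
#' subject's amplitude is updated by [respond_to_feedback()] with reward 1
#' when the bar is green. The first frame fires at t = 1 s when the first
#' full window exists (no zero padding), giving 1791 frames for a 180 s run.
#'
#' @param profile a [subject_profile()].
#' @param state an initialised `nft_state` (see [init_engine()]).
#' @param n_runs number of runs (default 6).
#' @param run_s run length in seconds (default 180).
#' @param seed session RNG seed.
#' @param sfreq sampling rate (Hz).
#' @param a0 starting alpha amplitude; defaults to `profile$a0`.
#' @return list with `frames` (one data frame, column `run` added),
#'   `run_mean_delta_arp` (per-run mean dARP over non-paused frames),
#'   `final_amp` (uV) and `amp_track` (per-frame amplitude).
#' @export
run_nft_session <- function(profile, state, n_runs = 6, run_s = 180,
                            seed = derive_seed(profile$seed, "nftsession"),
                            sfreq = 500, a0 = profile$a0) {
  cfg <- state$config
  wlen <- as.integer(round(cfg$window_s * sfreq))
  step_n <- as.integer(round(cfg$update_s * sfreq))
  a <- a0
  all_frames <- vector("list", n_runs)
  amp_track <- list()
  for (r in seq_len(n_runs)) {
    stream <- nft_stream(profile, state$montage, run_s, sfreq,
                         seed = derive_seed(seed, paste0("run", r)))
    front_i <- match(state$montage$frontal16, stream$channels)
    veog_i <- match("VEOG", stream$channels)
    ring <- stream$emit(a, wlen)      # warm-up: first full window
    n_frames <- (stream$n_samples - wlen) %/% step_n + 1L
    frames <- vector("list", n_frames)
    amps <- numeric(n_frames)
    for (k in seq_len(n_frames)) {
      res <- nft_step(state, ring[front_i, , drop = FALSE],
                      ring[veog_i, ], sfreq)
      state <- res$state
      reward <- as.integer(!res$frame$paused && res$frame$color == "green")
      a <- respond_to_feedback(profile, a, reward, cfg$update_s)
      amps[k] <- a
      frames[[k]] <- res$frame
      if (k < n_frames) {
        chunk <- stream$emit(a, step_n)
        ring <- cbind(ring[, -seq_len(step_n), drop = FALSE], chunk)
      }
    }
    fr <- do.call(rbind, frames)
    fr$run <- r
    fr$frame <- seq_len(nrow(fr))
    all_frames[[r]] <- fr
    amp_track[[r]] <- amps
  }
  frames <- do.call(rbind, all_frames)
  run_means <- vapply(split(frames$delta_arp[!frames$paused],
                            frames$run[!frames$paused]), mean, 0)
  list(frames = frames, run_mean_delta_arp = run_means, final_amp = a,
       amp_track = unlist(amp_track))
}
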