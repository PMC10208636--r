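#' Detection parameters for ripple-band event classes
#'
#' Bands and thresholds for the three high-frequency event classes detected
#' on the pyramidal-layer LFP: sharp-wave ripples (100-250 Hz, 3 SD, >= 50
#' ms), high gamma (80-120 Hz, 1 SD) and HFO (110-160 Hz, 1 SD). The
#' rectified z-scored band signal is smoothed with a secondary 1-20 Hz
#' bandpass before thresholding, event edges extend to the 1 SD crossing, and
#' events closer than 125 ms are merged.
#'
#' @param label one of "SWR", "highGamma", "HFO", or "custom".
#' @param band length-2 numeric (Hz).
#' @param threshold_sd detection threshold in SD above the mean envelope.
#' @param edge_sd event boundary level in SD.
#' @param min_duration minimum event duration in seconds (0 disables).
#' @param merge_gap events with gaps below this (seconds) are merged.
#' @param smooth_band secondary bandpass applied to the rectified z-score.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(label = c("SWR", "highGamma", "HFO", "custom"),
                             band = NULL, threshold_sd = NULL,
                             edge_sd = 1, min_duration = NULL,
                             merge_gap = 0.125, smooth_band = c(1, 20)) {
  label <- match.arg(label)
  defaults <- list(
    SWR       = list(band = c(100, 250), threshold_sd = 3, min_duration = 0.05),
    highGamma = list(band = c(80, 120),  threshold_sd = 1, min_duration = 0),
    HFO       = list(band = c(110, 160), threshold_sd = 1, min_duration = 0),
    custom    = list(band = c(100, 250), threshold_sd = 3, min_duration = 0.05))
  d <- defaults[[label]]
  out <- list(label = label,
              band = if (is.null(band)) d$band else band,
              threshold_sd = if (is.null(threshold_sd)) d$threshold_sd
                             else threshold_sd,
              edge_sd = edge_sd,
              min_duration = if (is.null(min_duration)) d$min_duration
                             else min_duration,
              merge_gap = merge_gap, smooth_band = smooth_band,
              smooth_order = 2)
  if (any(out$band <= 0) || out$threshold_sd <= 0)
    stop("band edges and thresholds must be positive")
  structure(out, class = "detection_params")
}

# smoothed detection envelope: bandpass -> z-score -> rectify -> 1-20 Hz
swr_envelope <- function(lfp, fs, params) {
  filt <- bandpass_filter(lfp, fs, params$band[1],
                          min(params$band[2], fs / 2 - 1))
  z <- abs((filt - mean(filt)) / stats::sd(filt))
  # low-order smoother: higher orders ring on brief ripple bursts and split
  # the envelope bump into sub-50 ms lobes
  bandpass_filter(z, fs, params$smooth_band[1], params$smooth_band[2],
                  order = params$smooth_order)
}

# candidate intervals on one envelope: exceed threshold_sd, edges at edge_sd
envelope_events <- function(env, fs, params) {
  # robust location/scale: with mean/SD the events themselves inflate the
  # scale (a few percent duty cycle at 5-7 SD raises SD by ~25%), making the
  # threshold depend on event density; median/MAD matches mean/SD on the
  # event-free background
  mu <- stats::median(env)
  sdv <- stats::mad(env)
  zenv <- (env - mu) / sdv
  above_edge <- zenv > params$edge_sd
  runs <- logical_runs(above_edge)
  if (!nrow(runs)) return(NULL)
  # amplitude-and-duration criterion on the suprathreshold core: the envelope
  # must spend at least min_duration above threshold_sd within the event
  # (total, so a one-sample dip does not reset the clock); the event then
  # extends outward to the edge_sd crossings
  min_core <- max(1, round(params$min_duration * fs))
  keep <- vapply(seq_len(nrow(runs)), function(r)
    sum(zenv[runs[r, 1]:runs[r, 2]] >= params$threshold_sd) >= min_core,
    logical(1))
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  peak <- vapply(seq_len(nrow(runs)), function(r)
    runs[r, 1] - 1 + which.max(zenv[runs[r, 1]:runs[r, 2]]), numeric(1))
  data.frame(start = (runs[, 1] - 1) / fs, peak = (peak - 1) / fs,
             end = runs[, 2] / fs,
             amp_sd = zenv[peak])
}

merge_close_events <- function(ev, gap) {
  if (is.null(ev) || nrow(ev) < 2) return(ev)
  ev <- ev[order(ev$start), ]
  out <- ev[1, ]
  for (i in 2:nrow(ev)) {
    last <- nrow(out)
    if (ev$start[i] - out$end[last] < gap) {
      out$end[last] <- max(out$end[last], ev$end[i])
      if (ev$amp_sd[i] > out$amp_sd[last]) {
        out$amp_sd[last] <- ev$amp_sd[i]
        out$peak[last] <- ev$peak[i]
      }
    } else {
      out <- rbind(out, ev[i, ])
    }
  }
  out
}

overlaps <- function(a_start, a_end, b_start, b_end) {
  vapply(seq_along(a_start), function(i)
    any(a_start[i] <= b_end & a_end[i] >= b_start), logical(1))
}

#' Detect ripple-band events with noise-channel artifact rejection
#'
#' Pipeline per the event class in `params`: zero-phase Butterworth bandpass,
#' z-score, rectify, secondary 1-20 Hz bandpass to form the detection
#' envelope; events must exceed `threshold_sd` SDs above the mean envelope,
#' extend to the `edge_sd` crossings, and (for SWRs) last at least 50 ms.
#' Events closer than the merge gap are fused. Candidates that temporally
#' overlap an event detected the same way on the noise channel (a channel
#' away from the ripple layer, where true SWRs are absent but broadband
#' artifacts are shared) are removed.
#'
#' @param lfp ripple-layer LFP vector.
#' @param noise_lfp noise-channel LFP (same length/fs), or NULL to skip
#'   artifact rejection.
#' @param fs sampling rate (Hz).
#' @param params a [detection_params()].
#' @return data.frame of class `ripple_events` with `label`, `start`, `peak`,
#'   `end`, `amp_sd`, sorted by start time.
#' @export
detect_events <- function(lfp, noise_lfp, fs, params = detection_params("SWR")) {
  if (!is.null(noise_lfp) && length(noise_lfp) != length(lfp))
    stop("lfp and noise channel must have the same length")
  if (params$band[2] >= fs / 2)
    stop("filter band beyond Nyquist")
  env <- swr_envelope(lfp, fs, params)
  ev <- envelope_events(env, fs, params)
  empty <- data.frame(label = character(), start = numeric(),
                      peak = numeric(), end = numeric(), amp_sd = numeric())
  if (is.null(ev)) return(structure(empty, class = c("ripple_events",
                                                     "data.frame")))
  ev <- merge_close_events(ev, params$merge_gap)
  if (nrow(ev) && !is.null(noise_lfp)) {
    nenv <- swr_envelope(noise_lfp, fs, params)
    nev <- envelope_events(nenv, fs, params)
    if (!is.null(nev) && nrow(nev)) {
      bad <- overlaps(ev$start, ev$end, nev$start, nev$end)
      ev <- ev[!bad, , drop = FALSE]
    }
  }
  if (!nrow(ev)) return(structure(empty, class = c("ripple_events",
                                                   "data.frame")))
  ev <- data.frame(label = params$label, ev[order(ev$start), ],
                   row.names = NULL)
  structure(ev, class = c("ripple_events", "data.frame"))
}

#' Consolidate duplicate events across bands
#'
#' High gamma and HFO events that temporally overlap an SWR (directly or
#' through a chain of overlaps) are relabeled as that SWR; disjoint events
#' keep their labels. Returns one row per consolidated event.
#'
#' @param events_by_band list of `ripple_events` data.frames (any mix of
#'   labels; at most one SWR table).
#' @return single `ripple_events` data.frame, sorted by start.
#' @export
label_duplicates <- function(events_by_band) {
  ev <- do.call(rbind, lapply(events_by_band, as.data.frame))
  if (is.null(ev) || !nrow(ev))
    return(structure(data.frame(label = character(), start = numeric(),
                                peak = numeric(), end = numeric(),
                                amp_sd = numeric()),
                     class = c("ripple_events", "data.frame")))
  ev <- ev[order(ev$start), ]
  # transitive grouping of overlapping intervals: sweep by running max end
  grp <- integer(nrow(ev))
  g <- 0L
  run_end <- -Inf
  for (i in seq_len(nrow(ev))) {
    if (ev$start[i] > run_end) g <- g + 1L
    grp[i] <- g
    run_end <- max(run_end, ev$end[i])
  }
  rows <- lapply(split(seq_len(nrow(ev)), grp), function(ix) {
    sub <- ev[ix, ]
    if (any(sub$label == "SWR")) {
      # the whole overlap chain collapses into the SWR
      lead <- sub[sub$label == "SWR", ][which.max(sub$amp_sd[sub$label == "SWR"]), ]
      data.frame(label = "SWR", start = min(sub$start),
                 peak = lead$peak, end = max(sub$end),
                 amp_sd = max(sub$amp_sd))
    } else {
      sub[which.max(sub$amp_sd), c("label", "start", "peak", "end", "amp_sd")]
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out[order(out$start), ], class = c("ripple_events", "data.frame"))
}
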