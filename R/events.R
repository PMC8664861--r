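# Event detection and dual-channel discrimination: voltage deflections,
# calcium transients, spiking/subthreshold classification, per-event
# metrics, interictal event counting and pre-ictal window statistics.

empty_event_table <- function() {
  data.frame(roi = character(0), onset = numeric(0), peak_time = numeric(0),
             amplitude = numeric(0), area = numeric(0), label = character(0),
             channel = character(0), stringsAsFactors = FALSE)
}

# Baseline noise SD from first differences: white measurement noise passes
# through diff() with variance doubled, while slow physiological events
# contribute almost nothing, so the estimate stays honest even when events
# occupy a large fraction of the trace.
noise_sd_diff <- function(y) robust_sd(diff(y)) / sqrt(2)

# samples spanning at least min_dur at this rate (guarding float jitter in
# rates reconstructed from time stamps)
min_dur_samples <- function(min_dur, rate) {
  max(1L, as.integer(ceiling(min_dur * rate - 1e-6)))
}

# threshold-crossing run detector shared by both channels.
# polarity +1: events are positive-going in d = polarity * y.
detect_runs <- function(tr, threshold_sd, min_dur, polarity, channel,
                        baseline_sd = NULL) {
  y <- tr$y
  d <- polarity * y
  s <- baseline_sd %||% noise_sd_diff(d)
  if (is.na(s) || s == 0) stopf("baseline SD is zero")
  thr <- threshold_sd * s
  above <- d > thr
  if (!any(above)) return(empty_event_table())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_dur_samples(min_dur, tr$rate))
  if (!length(keep)) return(empty_event_table())
  dt <- 1 / tr$rate
  out <- lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    pk <- idx[which.max(d[idx])]
    data.frame(roi = tr$label, onset = tr$t[starts[i]], peak_time = tr$t[pk],
               amplitude = y[pk], area = sum(y[idx]) * dt, label = NA_character_,
               channel = channel, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect depolarizing events in a voltage-channel dF/F trace
#'
#' Contiguous excursions beyond `threshold_sd` baseline SDs in the
#' depolarizing direction (negative dF/F for a negative-going indicator)
#' lasting at least `min_dur` become events with onset (first crossing),
#' peak, signed amplitude and area. The baseline SD is a robust (MAD)
#' estimate over the whole detrended trace unless supplied.
#'
#' @param trace detrended dF/F [dv_trace()].
#' @param threshold_sd detection threshold in baseline-SD units (default 3).
#' @param min_dur minimum event duration, s (default 0.1).
#' @param polarity response direction of the channel (default -1).
#' @param baseline_sd optional externally estimated baseline SD.
#' @return An event table (data.frame).
#' @export
detect_voltage_events <- function(trace, threshold_sd = 3, min_dur = 0.1,
                                  polarity = -1, baseline_sd = NULL) {
  detect_runs(trace, threshold_sd, min_dur, polarity, "voltage", baseline_sd)
}

#' Detect calcium transients in a dF/F trace
#'
#' As [detect_voltage_events()] with positive-going polarity.
#'
#' @inheritParams detect_voltage_events
#' @return An event table (data.frame).
#' @export
detect_calcium_transients <- function(trace, threshold_sd = 3, min_dur = 0.1,
                                      baseline_sd = NULL) {
  detect_runs(trace, threshold_sd, min_dur, +1, "calcium", baseline_sd)
}

#' Classify voltage events as spiking or subthreshold using the calcium channel
#'
#' A voltage event whose `[onset, peak]` span (padded by `coincidence` on
#' both sides) contains a calcium-transient onset is labelled `"spiking"`;
#' one without is `"subthreshold"`. Calcium transients not matching any
#' voltage event are appended as `"calcium-only"` — under the model every
#' spike rides on a depolarization, so these flag detector misses.
#'
#' @param volt,ca event tables from the same ROI and time base.
#' @param coincidence matching window, s (default 0.2: indicator kinetics
#'   plus one frame).
#' @return A labelled event table sorted by onset.
#' @export
classify_events <- function(volt, ca, coincidence = 0.2) {
  volt <- volt[order(volt$onset), , drop = FALSE]
  ca <- ca[order(ca$onset), , drop = FALSE]
  ca_used <- rep(FALSE, nrow(ca))
  if (nrow(volt)) for (i in seq_len(nrow(volt))) {
    hit <- which(ca$onset >= volt$onset[i] - coincidence &
                   ca$onset <= volt$peak_time[i] + coincidence)
    volt$label[i] <- if (length(hit)) "spiking" else "subthreshold"
    ca_used[hit] <- TRUE
  }
  extra <- ca[!ca_used, , drop = FALSE]
  if (nrow(extra)) extra$label <- "calcium-only"
  out <- rbind(volt, extra)
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peak latency of a stimulus-triggered average
#'
#' Time from the stimulus to the extremum of the STA in the channel's
#' response direction. When the extremum does not rise above the noise
#' floor (3 pre-stimulus SDs, when a pre-stimulus segment exists) the
#' latency is flagged undefined.
#'
#' @param t_rel STA time base relative to the stimulus, s.
#' @param y STA values.
#' @param polarity `-1` (voltage) or `+1` (calcium).
#' @return List: `latency` (s, `NA` when undefined), `peak`, `defined`.
#' @export
peak_latency <- function(t_rel, y, polarity = -1) {
  post <- t_rel >= 0
  if (!any(post)) stopf("STA window must cover the post-stimulus period")
  d <- polarity * y
  pk <- which(post)[which.max(d[post])]
  floor_sd <- if (any(t_rel < 0)) stats::sd(y[t_rel < 0]) else 0
  base <- if (any(t_rel < 0)) mean(d[t_rel < 0]) else 0
  defined <- (d[pk] - base) > 3 * floor_sd && d[pk] > base
  list(latency = if (defined) t_rel[pk] else NA_real_,
       peak = y[pk], defined = defined)
}

#' Signed pre-stimulus dF/F area
#'
#' Integral of dF/F over the `window` seconds preceding the stimulus
#' (a measure of spontaneous input immediately before the response).
#'
#' @param trace dF/F [dv_trace()].
#' @param stim_time s.
#' @param window look-back length, s (default 0.5).
#' @return Signed area, dF/F x s.
#' @export
prestim_area <- function(trace, stim_time, window = 0.5) {
  tr <- trace
  if (stim_time - window < tr$t[1] || stim_time > tr$t[length(tr$t)])
    stopf("pre-stimulus window escapes trace")
  idx <- tr$t >= stim_time - window & tr$t < stim_time
  sum(tr$y[idx]) / tr$rate
}

#' Detect interictal events in an LFP or optical trace
#'
#' Sharp deflections beyond `threshold_sd` robust SDs in the channel's
#' deflection direction, sustained for at least `min_dur` (which rejects
#' single-sample noise excursions), with events closer than `refractory`
#' merged into the larger one; the event rate is the count divided by the
#' trace duration.
#'
#' @param trace band-limited/detrended [dv_trace()].
#' @param threshold_sd threshold in robust-SD units (default 3).
#' @param refractory minimum event spacing, s (default 0.5).
#' @param min_dur minimum supra-threshold duration, s (default 0.05).
#' @param polarity deflection direction (`-1` for LFP and the voltage
#'   channel, `+1` for calcium).
#' @param baseline_sd optional externally estimated baseline SD.
#' @return List: `events` (data.frame time, amplitude), `frequency`
#'   (events/s), `n`.
#' @export
detect_interictal_events <- function(trace, threshold_sd = 3, refractory = 0.5,
                                     min_dur = 0.05, polarity = -1,
                                     baseline_sd = NULL) {
  tr <- trace
  dur <- length(tr$y) / tr$rate
  if (dur <= 0) stopf("zero-duration input")
  d <- polarity * tr$y
  s <- baseline_sd %||% noise_sd_diff(d)
  if (is.na(s) || s == 0) stopf("baseline SD is zero")
  above <- d > threshold_sd * s
  times <- amps <- numeric(0)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_dur_samples(min_dur, tr$rate))
    for (i in keep) {
      idx <- starts[i]:ends[i]
      pk <- idx[which.max(d[idx])]
      if (length(times) && tr$t[pk] - times[length(times)] < refractory) {
        if (d[pk] > polarity * amps[length(amps)]) {
          times[length(times)] <- tr$t[pk]; amps[length(amps)] <- tr$y[pk]
        }
      } else {
        times <- c(times, tr$t[pk]); amps <- c(amps, tr$y[pk])
      }
    }
  }
  list(events = data.frame(time = times, amplitude = amps),
       frequency = length(times) / dur, n = length(times))
}

#' Pre-ictal window statistics of detected events
#'
#' Partitions events by look-back time before seizure onset into the given
#' windows (default the 0-10 s and 10-20 s pre-onset windows) and reports
#' per-window count and mean absolute amplitude.
#'
#' @param events data.frame with columns `time` (or `onset`) and
#'   `amplitude`.
#' @param seizure_onset s.
#' @param windows list of `c(lo, hi)` look-back intervals, s before onset;
#'   must not overlap.
#' @return data.frame: window_lo, window_hi, n, mean_abs_amplitude (`NA`
#'   when a window is empty).
#' @export
preictal_window_stats <- function(events, seizure_onset,
                                  windows = list(c(0, 10), c(10, 20))) {
  w <- do.call(rbind, windows)
  o <- order(w[, 1])
  if (any(w[o, 1][-1] < w[o, 2][-nrow(w)])) stopf("windows overlap")
  tm <- if ("time" %in% names(events)) events$time else events$onset
  look <- seizure_onset - tm
  out <- lapply(windows, function(win) {
    sel <- look > win[1] & look <= win[2]
    data.frame(window_lo = win[1], window_hi = win[2], n = sum(sel),
               mean_abs_amplitude = if (any(sel))
                 mean(abs(events$amplitude[sel])) else NA_real_)
  })
  do.call(rbind, out)
}
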