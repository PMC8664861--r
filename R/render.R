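# Rendering: turn per-cell fluorescence traces (1 kHz) into dual-channel
# movies at the acquisition frame rate, with heartbeat gain, rigid motion
# jitter, mean-preserving shot noise and saturated flash frames. A faster
# trace-level sampler produces ROI traces with equivalent noise statistics
# without rasterizing frames.

FLASH_VALUE <- 3  # a.u.: well above any physiological fluorescence

# integer-shift a matrix, filling exposed borders with the frame median
shift_frame <- function(img, dy, dx) {
  if (dy == 0 && dx == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(stats::median(img), h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- img[ys - dy, xs - dx, drop = FALSE]
  out
}

# per-cell disk masks on the pixel grid; returns H x W weight matrices
soma_masks <- function(scene) {
  w <- round(scene$fov[1] / scene$pixel_size)
  h <- round(scene$fov[2] / scene$pixel_size)
  xs <- (seq_len(w) - 0.5) * scene$pixel_size
  ys <- (seq_len(h) - 0.5) * scene$pixel_size
  lapply(seq_len(scene$n_cells), function(ci) {
    p <- scene$cell_positions[ci, ]
    outer(ys, xs, function(y, x) (x - p[1])^2 + (y - p[2])^2 <=
            scene$soma_radius^2)
  })
}

# box-average 1 kHz traces into frames spanning [k/rate, (k+1)/rate)
integrate_to_frames <- function(traces, sample_rate, frame_rate) {
  traces <- as.matrix(traces)
  nt <- nrow(traces)
  fidx <- floor((seq_len(nt) - 1) / sample_rate * frame_rate) + 1L
  n_frames <- max(fidx)
  out <- matrix(0, n_frames, ncol(traces))
  for (j in seq_len(ncol(traces)))
    out[, j] <- as.numeric(tapply(traces[, j], fidx, mean))
  out
}

#' Render a dual-channel movie from per-cell fluorescence traces
#'
#' Each frame integrates the 1 kHz traces over its exposure (box average).
#' Somata take their cell's trace value, background takes
#' `neuropil_level x` the population mean. The whole frame is then
#' multiplied by the heartbeat gain `1 + amp sin(2 pi f t)`, rigidly
#' shifted by a per-frame integer jitter, degraded by mean-preserving
#' Poisson shot noise (`photon_scale` counts per intensity unit), and the
#' listed `flash_frames` are overwritten with full-scale saturation.
#'
#' @param volt_traces,ca_traces samples x cells matrices, a.u., common
#'   1 kHz time base.
#' @param scene a [scene_plan()].
#' @param noise a [noise_model()].
#' @param frame_rate Hz (default 30, the acquisition rate).
#' @param sample_rate Hz of the input traces.
#' @param seed integer master seed (child streams per noise source).
#' @return List: `volt`, `ca` ([frame_stack()]s) and `motion`
#'   (data.frame frame, dx, dy of the true applied shifts).
#' @export
render_dual_channel_movie <- function(volt_traces, ca_traces, scene,
                                      noise = noise_model(), frame_rate = 30,
                                      sample_rate = 1000, seed = 1) {
  volt_traces <- as.matrix(volt_traces); ca_traces <- as.matrix(ca_traces)
  if (nrow(volt_traces) != nrow(ca_traces))
    stopf("channel traces must share a time base")
  masks <- soma_masks(scene)
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  fv <- integrate_to_frames(volt_traces, sample_rate, frame_rate)
  fc <- integrate_to_frames(ca_traces, sample_rate, frame_rate)
  tn <- nrow(fv)
  if (length(noise$flash_frames) && any(noise$flash_frames >= tn))
    stopf("flash_frames outside stack length")
  motion <- with_seed(child_seed(seed, "motion"), {
    if (noise$motion_sd > 0)
      cbind(dx = round(stats::rnorm(tn, 0, noise$motion_sd)),
            dy = round(stats::rnorm(tn, 0, noise$motion_sd)))
    else cbind(dx = integer(tn), dy = integer(tn))
  })
  tf <- (seq_len(tn) - 0.5) / frame_rate
  hb <- 1 + noise$heartbeat_amp * sin(2 * pi * noise$heartbeat_freq * tf)

  render_channel <- function(frames, tag) {
    arr <- array(0, c(tn, h, w))
    with_seed(child_seed(seed, paste0("shot_", tag)), {
      for (k in seq_len(tn)) {
        img <- matrix(scene$neuropil_level * mean(frames[k, ]), h, w)
        for (ci in seq_len(ncol(frames))) img[masks[[ci]]] <- frames[k, ci]
        img <- img * hb[k]
        img <- shift_frame(img, motion[k, "dy"], motion[k, "dx"])
        if (noise$photon_scale > 0)
          img <- matrix(stats::rpois(h * w, noise$photon_scale * img) /
                          noise$photon_scale, h, w)
        if ((k - 1L) %in% noise$flash_frames) img[] <- FLASH_VALUE
        arr[k, , ] <- img
      }
    })
    arr
  }
  list(volt = frame_stack(render_channel(fv, "volt"), frame_rate, "voltage",
                          "render"),
       ca = frame_stack(render_channel(fc, "ca"), frame_rate, "calcium",
                        "render"),
       motion = data.frame(frame = seq_len(tn) - 1L, dx = motion[, "dx"],
                           dy = motion[, "dy"]))
}

#' Sample fluorescence traces at the frame rate with ROI-level noise
#'
#' Trace-level shortcut around full rasterization: box-integrates the 1 kHz
#' traces to the frame rate, applies the multiplicative heartbeat gain, and
#' adds Gaussian noise of standard deviation `noise_sd` (fraction of the
#' trace level), the ROI-mean equivalent of shot noise. Used by the fast
#' pipeline path and the event-classification benchmarks.
#'
#' @param traces samples x cells matrix, a.u.
#' @param frame_rate Hz.
#' @param sample_rate Hz of `traces`.
#' @param noise_sd fractional noise SD per frame sample.
#' @param heartbeat_amp,heartbeat_freq multiplicative artifact parameters.
#' @param seed integer seed.
#' @return List: `y` (frames x cells matrix), `t` (frame mid-times, s).
#' @export
sample_frame_traces <- function(traces, frame_rate = 30, sample_rate = 1000,
                                noise_sd = 0.0055, heartbeat_amp = 0,
                                heartbeat_freq = 7, seed = 1) {
  f <- integrate_to_frames(as.matrix(traces), sample_rate, frame_rate)
  tn <- nrow(f)
  tf <- (seq_len(tn) - 0.5) / frame_rate
  if (heartbeat_amp > 0)
    f <- f * (1 + heartbeat_amp * sin(2 * pi * heartbeat_freq * tf))
  if (noise_sd > 0)
    f <- f * (1 + with_seed(child_seed(seed, "trace_noise"),
                            matrix(stats::rnorm(length(f), 0, noise_sd),
                                   nrow(f), ncol(f))))
  list(y = f, t = tf)
}
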