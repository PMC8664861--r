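# ROI handling and core trace statistics: grid partition of the field of
# view, ROI-mean extraction, spline detrending, dF/F, SNR, and
# stimulus-triggered averages. dF/F is stored as a fraction internally and
# rendered as percent only in reports.

#' Fluorescence / electrical time series
#'
#' Lightweight trace container: a uniform, strictly increasing time base
#' and one signal.
#'
#' @param y numeric samples (finite).
#' @param rate sampling rate, Hz (alternative to `t`).
#' @param t explicit time stamps, s.
#' @param kind `"raw"`, `"detrended"`, `"dff"` or `"electrical"`.
#' @param label source ROI/channel label.
#' @return An object of class `dv_trace`.
#' @export
dv_trace <- function(y, rate = NULL, t = NULL,
                     kind = c("raw", "detrended", "dff", "electrical"),
                     label = "roi") {
  kind <- match.arg(kind)
  if (any(!is.finite(y))) stopf("trace values must be finite")
  if (is.null(t)) {
    if (is.null(rate)) stopf("supply rate or t")
    t <- (seq_along(y) - 1) / rate
  } else {
    if (length(t) != length(y)) stopf("t and y lengths differ")
    dt <- diff(t)
    if (any(dt <= 0) || (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-9 * dt[1]))
      stopf("t must be strictly increasing and uniform")
    rate <- 1 / dt[1]
  }
  structure(list(t = t, y = as.numeric(y), rate = rate, kind = kind,
                 label = label), class = "dv_trace")
}

trace_rate <- function(tr) tr$rate

#' Partition the field of view into a rectangular ROI grid
#'
#' Produces `n_rows x n_cols` disjoint, exhaustive rectangular masks
#' (tile sizes differ by at most one pixel per dimension) plus one
#' full-field ROI labelled `"full-fov"` whose mean trace is the optical
#' field potential source.
#'
#' @param dims image size `c(H, W)` in pixels (or a [frame_stack()]).
#' @param n_rows,n_cols grid shape (`n_rows * n_cols >= 1`).
#' @param pixel_size um per pixel (for centroids).
#' @return An object of class `roi_set`: list of logical masks, labels,
#'   centroids (um), kinds.
#' @export
partition_fov <- function(dims, n_rows, n_cols, pixel_size = 1) {
  if (inherits(dims, "frame_stack")) dims <- dim(dims$data)[2:3]
  h <- dims[1]; w <- dims[2]
  if (n_rows * n_cols < 1) stopf("grid must have at least one cell")
  if (n_rows > h || n_cols > w) stopf("grid larger than image")
  rb <- round(seq(0, h, length.out = n_rows + 1))
  cb <- round(seq(0, w, length.out = n_cols + 1))
  masks <- list(); labels <- character(0); cents <- NULL; kinds <- character(0)
  for (i in seq_len(n_rows)) for (j in seq_len(n_cols)) {
    m <- matrix(FALSE, h, w)
    m[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]] <- TRUE
    masks[[length(masks) + 1L]] <- m
    labels <- c(labels, sprintf("grid_r%d_c%d", i, j))
    cents <- rbind(cents, c((cb[j] + cb[j + 1]) / 2, (rb[i] + rb[i + 1]) / 2) *
                     pixel_size)
    kinds <- c(kinds, "grid-cell")
  }
  masks[[length(masks) + 1L]] <- matrix(TRUE, h, w)
  labels <- c(labels, "full-fov")
  cents <- rbind(cents, c(w, h) / 2 * pixel_size)
  kinds <- c(kinds, "full-fov")
  roi_set(masks, labels, cents, kinds)
}

#' Construct an ROI set
#'
#' @param masks list of logical `H x W` matrices (non-empty).
#' @param labels character labels.
#' @param centroids n x 2 matrix of (x, y), um.
#' @param kinds per-ROI kind: `"soma"`, `"neuropil"`, `"grid-cell"`,
#'   `"full-fov"`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks, labels = NULL,
                    centroids = NULL, kinds = NULL) {
  if (any(!vapply(masks, any, logical(1)))) stopf("empty ROI mask")
  n <- length(masks)
  labels <- labels %||% sprintf("roi%02d", seq_len(n))
  kinds <- kinds %||% rep("soma", n)
  if (is.null(centroids)) {
    centroids <- t(vapply(masks, function(m) {
      idx <- which(m, arr.ind = TRUE)
      c(mean(idx[, 2]), mean(idx[, 1]))
    }, numeric(2)))
  }
  structure(list(masks = masks, labels = labels,
                 centroids = as.matrix(centroids), kinds = kinds, n = n),
            class = "roi_set")
}

#' ROI set of soma disks from a scene plan
#'
#' The simulator's true ROIs: one disk per cell on the rendered pixel grid.
#'
#' @param scene a [scene_plan()].
#' @return An [roi_set()].
#' @export
scene_rois <- function(scene) {
  roi_set(soma_masks(scene),
          labels = sprintf("cell%02d", seq_len(scene$n_cells)),
          centroids = scene$cell_positions,
          kinds = rep("soma", scene$n_cells))
}

#' Extract ROI-mean traces from a stack
#'
#' Per-frame mean intensity over each mask. The full-field ROI yields the
#' optical-field-potential source trace.
#'
#' @param stack a [frame_stack()].
#' @param rois an [roi_set()].
#' @return A `trace_set`: list with `t`, `y` (frames x ROIs matrix),
#'   `labels`, `rate`.
#' @export
extract_traces <- function(stack, rois) {
  d <- dim(stack$data)
  for (m in rois$masks)
    if (!all(dim(m) == d[2:3])) stopf("ROI mask does not match stack dims")
  tn <- d[1]
  flat <- matrix(stack$data, tn, d[2] * d[3])
  y <- vapply(rois$masks, function(m) {
    idx <- which(as.vector(m))
    rowMeans(flat[, idx, drop = FALSE])
  }, numeric(tn))
  y <- matrix(y, tn, rois$n)
  structure(list(t = (seq_len(tn) - 1) / stack$frame_rate, y = y,
                 labels = rois$labels, rate = stack$frame_rate,
                 channel = stack$channel),
            class = "trace_set")
}

# spline trend fitted to t < cutoff and (linearly, via the natural-spline
# boundary behaviour) extrapolated over the full time base; used to carry
# an interictal F0 baseline across a seizure
extrapolated_trend <- function(t, y, cutoff, knot_spacing) {
  pre <- t < cutoff
  if (sum(pre) < 10) stopf("too little pre-cutoff data for a trend")
  tp <- t[pre]
  dur <- max(tp) - min(tp)
  if (dur <= 2 * knot_spacing) {
    fit <- stats::lm(y[pre] ~ tp)
    return(stats::coef(fit)[1] + stats::coef(fit)[2] * t)
  }
  knots <- seq(min(tp) + knot_spacing, max(tp) - knot_spacing / 2,
               by = knot_spacing)
  fit <- stats::lm(yy ~ splines::ns(tt, knots = knots),
                   data = data.frame(tt = tp, yy = y[pre]))
  as.numeric(stats::predict(fit, newdata = data.frame(tt = t)))
}

# spline trend with interior knots every knot_spacing seconds
spline_trend <- function(t, y, knot_spacing) {
  dur <- t[length(t)] - t[1]
  if (dur <= 2 * knot_spacing)
    stopf("trace shorter than twice the knot spacing")
  knots <- seq(t[1] + knot_spacing, t[length(t)] - knot_spacing / 2,
               by = knot_spacing)
  basis <- splines::ns(t, knots = knots)
  as.numeric(stats::lm.fit(cbind(1, basis), y)$fitted.values)
}

#' Subtract a slow spline trendline
#'
#' Fits a natural-cubic-spline trend with knots every `knot_spacing`
#' seconds and subtracts it, re-adding the trace mean, thereby removing
#' photobleaching and other slow drift while preserving event-scale
#' structure.
#'
#' @param trace a [dv_trace()] (or numeric vector with `rate`).
#' @param knot_spacing s between spline knots (default 10).
#' @param rate sampling rate when `trace` is a bare vector.
#' @return A detrended [dv_trace()].
#' @export
detrend <- function(trace, knot_spacing = 10, rate = NULL) {
  tr <- if (inherits(trace, "dv_trace")) trace else dv_trace(trace, rate = rate)
  trend <- spline_trend(tr$t, tr$y, knot_spacing)
  dv_trace(tr$y - trend + mean(tr$y), t = tr$t, kind = "detrended",
           label = tr$label)
}

#' Fractional fluorescence change dF/F
#'
#' `(F - F0) / F0`. With `f0_window` given (the stimulus-epoch convention),
#' `F0` is the mean over that window — e.g. the 0.5 s preceding a stimulus.
#' Without a window (spontaneous activity), `F0` is the slow spline trend,
#' so the result is the fractional fluctuation about the trend.
#'
#' @param trace a [dv_trace()] or numeric vector (then give `rate`).
#' @param f0_window `c(start, end)` in s, or `NULL` for trend-based F0.
#' @param knot_spacing trend knot spacing for the trend-based mode.
#' @param rate sampling rate for bare vectors.
#' @return A [dv_trace()] of kind `"dff"` (dimensionless fraction).
#' @export
compute_dff <- function(trace, f0_window = NULL, knot_spacing = 10,
                        rate = NULL) {
  tr <- if (inherits(trace, "dv_trace")) trace else dv_trace(trace, rate = rate)
  if (!is.null(f0_window)) {
    idx <- tr$t >= f0_window[1] & tr$t <= f0_window[2]
    if (!any(idx)) stopf("F0 window outside trace")
    f0 <- mean(tr$y[idx])
    if (f0 == 0) stopf("F0 is zero")
    y <- (tr$y - f0) / f0
  } else {
    f0 <- spline_trend(tr$t, tr$y, knot_spacing)
    if (any(f0 == 0)) stopf("F0 trend crosses zero")
    y <- (tr$y - f0) / f0
  }
  dv_trace(y, t = tr$t, kind = "dff", label = tr$label)
}

#' Signal-to-noise ratio of a stimulus response
#'
#' Peak dF/F over the standard deviation of the baseline fluctuation in the
#' 0.5 s before the stimulus. The peak is the extremum in the response
#' window in the channel's response direction (voltage indicator: minimum;
#' calcium: maximum); its magnitude is divided by the baseline SD.
#'
#' @param trace dF/F [dv_trace()].
#' @param stim_time stimulus time, s.
#' @param baseline pre-stimulus baseline length, s (default 0.5).
#' @param response_window post-stimulus search window, s (default 1).
#' @param polarity `-1` (negative-going voltage channel) or `+1`.
#' @return SNR, dimensionless.
#' @export
compute_snr <- function(trace, stim_time, baseline = 0.5,
                        response_window = 1, polarity = -1) {
  tr <- trace
  base_idx <- tr$t >= stim_time - baseline & tr$t < stim_time
  resp_idx <- tr$t >= stim_time & tr$t <= stim_time + response_window
  if (!any(base_idx) || tr$t[1] > stim_time - baseline)
    stopf("baseline window outside trace")
  s <- stats::sd(tr$y[base_idx])
  if (s == 0) stopf("baseline SD is zero")
  pk <- if (polarity < 0) min(tr$y[resp_idx]) else max(tr$y[resp_idx])
  abs(pk) / s
}

#' Stimulus-triggered average
#'
#' Aligns trials at each stimulus time and averages pointwise.
#'
#' @param trace a [dv_trace()].
#' @param stim_times stimulus times, s.
#' @param window `c(pre, post)` in s around each stimulus (pre >= 0).
#' @return List: `t_rel` (s relative to stimulus), `mean`, `trials`
#'   (trials x samples matrix), `n_trials`.
#' @export
stimulus_triggered_average <- function(trace, stim_times, window = c(0.5, 1)) {
  tr <- trace
  dt <- 1 / tr$rate
  pre_n <- round(window[1] * tr$rate)
  post_n <- round(window[2] * tr$rate)
  trials <- matrix(NA_real_, length(stim_times), pre_n + post_n + 1)
  for (i in seq_along(stim_times)) {
    k <- which.min(abs(tr$t - stim_times[i]))
    if (k - pre_n < 1 || k + post_n > length(tr$y))
      stopf("window escapes trace for stimulus at %.3f s", stim_times[i])
    trials[i, ] <- tr$y[(k - pre_n):(k + post_n)]
  }
  list(t_rel = seq(-pre_n, post_n) * dt, mean = colMeans(trials),
       trials = trials, n_trials = length(stim_times))
}
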