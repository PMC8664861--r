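# Field- and population-level analyses: LFP band-pass, correlation
# structure and its distance dependence, windowed LFP-optical
# cross-correlation around seizure onset, onset delays, recruitment order
# and propagation-pattern classification.

#' Zero-phase band-pass filter for the LFP
#'
#' FFT-domain band-pass (exactly zero phase): Fourier components outside
#' `[low, high]` Hz, including DC, are removed.
#'
#' @param y LFP samples (or a [dv_trace()]).
#' @param rate sample rate, Hz (default 1000; ignored for a trace input).
#' @param low,high band edges, Hz (defaults 0.2 and 50).
#' @return Filtered numeric vector (or trace, matching the input).
#' @export
bandpass_lfp <- function(y, rate = 1000, low = 0.2, high = 50) {
  is_tr <- inherits(y, "dv_trace")
  if (is_tr) { rate <- y$rate; yy <- y$y } else yy <- y
  if (low >= high) stopf("band edges must satisfy low < high")
  if (high >= rate / 2) stopf("high edge must be below Nyquist (%g Hz)", rate / 2)
  n0 <- length(yy)
  # mirror-pad to suppress circular-wraparound edge artifacts at the
  # low-frequency end (pad ~ 2 periods of the low edge)
  pad <- min(n0 - 1L, round(2 / low * rate))
  yp <- c(rev(yy[2:(pad + 1L)]), yy, rev(yy[(n0 - pad):(n0 - 1L)]))
  n <- length(yp)
  fr <- (seq_len(n) - 1) / n * rate
  fr <- pmin(fr, rate - fr)   # two-sided frequency axis
  ft <- stats::fft(yp)
  ft[fr < low | fr > high] <- 0
  out <- (Re(stats::fft(ft, inverse = TRUE)) / n)[(pad + 1L):(pad + n0)]
  if (is_tr) dv_trace(out, t = y$t, kind = "electrical", label = y$label)
  else out
}

#' Zero-lag Pearson correlation matrix of a trace set
#'
#' @param y frames x signals matrix (or a `trace_set`).
#' @param labels optional signal labels.
#' @return List of class `corr_matrix`: `r` (symmetric, unit diagonal),
#'   `labels`, `n_samples`. Constant traces yield `NA` entries with a
#'   warning.
#' @export
correlation_matrix <- function(y, labels = NULL) {
  if (inherits(y, "trace_set")) { labels <- labels %||% y$labels; y <- y$y }
  y <- as.matrix(y)
  const <- apply(y, 2, stats::sd) == 0
  if (any(const))
    warning("constant trace(s): ", paste(which(const), collapse = ", "),
            "; correlations flagged NA", call. = FALSE)
  suppressWarnings(r <- stats::cor(y))
  diag(r) <- 1
  r <- (r + t(r)) / 2
  labels <- labels %||% sprintf("s%02d", seq_len(ncol(y)))
  dimnames(r) <- list(labels, labels)
  structure(list(r = r, labels = labels, n_samples = nrow(y)),
            class = "corr_matrix")
}

#' Pairwise correlation versus distance
#'
#' Emits every unordered signal pair with its centroid distance and
#' correlation, plus a fitted linear trend of r on distance.
#'
#' @param m a `corr_matrix` from [correlation_matrix()].
#' @param centroids n x 2 matrix of (x, y) positions, um, one per label.
#' @return List: `pairs` (data.frame i, j, distance, r), `slope` (per um),
#'   `slope_ci` (95%), `mean_r`.
#' @export
correlation_vs_distance <- function(m, centroids) {
  n <- length(m$labels)
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != n) stopf("need one centroid per label")
  pr <- utils::combn(n, 2)
  d <- sqrt(rowSums((centroids[pr[1, ], , drop = FALSE] -
                       centroids[pr[2, ], , drop = FALSE])^2))
  r <- m$r[cbind(pr[1, ], pr[2, ])]
  pairs <- data.frame(i = m$labels[pr[1, ]], j = m$labels[pr[2, ]],
                      distance = d, r = r)
  fit <- stats::lm(r ~ distance, data = pairs)
  ci <- tryCatch(stats::confint(fit)["distance", ],
                 error = function(e) c(NA_real_, NA_real_))
  list(pairs = pairs, slope = unname(stats::coef(fit)["distance"]),
       slope_ci = unname(ci), mean_r = mean(r, na.rm = TRUE))
}

# normalized cross-correlation of two equal-length vectors over +-max_lag
# samples; returns (lag_samples, r)
xcorr_norm <- function(a, b, max_lag_n) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  lags <- -max_lag_n:max_lag_n
  r <- vapply(lags, function(l) {
    ia <- max(1, 1 + l):min(n, n + l)
    ib <- ia - l
    if (length(ia) < 3) return(NA_real_)
    suppressWarnings(stats::cor(a[ia], b[ib]))
  }, numeric(1))
  data.frame(lag = lags, r = r)
}

#' Windowed LFP-optical cross-correlation before seizure onset
#'
#' Downsamples the LFP to the optical frame rate (box average), then for
#' each look-back window before onset computes the normalized
#' cross-correlogram between LFP and optical field potential and reports
#' its peak magnitude and lag.
#'
#' @param lfp [dv_trace()] (band-passed), typically 1 kHz.
#' @param ofp optical field-potential dF/F [dv_trace()] at the frame rate.
#' @param onset LFP seizure-onset time, s.
#' @param windows list of `c(lo, hi)` look-back intervals, s before onset.
#' @param max_lag correlogram extent, s (default 1).
#' @return data.frame: window_lo, window_hi, peak_r (max |r|), lag_s.
#' @export
windowed_lfp_optical_correlation <- function(lfp, ofp, onset,
                                             windows = list(c(0, 10), c(10, 20)),
                                             max_lag = 1) {
  fr <- ofp$rate
  dec <- round(lfp$rate / fr)
  lfp30 <- box_downsample(lfp$y, dec)
  t30 <- (seq_along(lfp30) - 0.5) * dec / lfp$rate
  out <- lapply(windows, function(win) {
    t0 <- onset - win[2]; t1 <- onset - win[1]
    if (t0 < 0) stopf("window (%g, %g) s before onset %g s escapes recording",
                      win[1], win[2], onset)
    ia <- which(t30 >= t0 & t30 < t1)
    ib <- which(ofp$t >= t0 & ofp$t < t1)
    nn <- min(length(ia), length(ib))
    cg <- xcorr_norm(lfp30[ia[seq_len(nn)]], ofp$y[ib[seq_len(nn)]],
                     round(max_lag * fr))
    k <- which.max(abs(cg$r))
    data.frame(window_lo = win[1], window_hi = win[2],
               peak_r = abs(cg$r[k]), lag_s = cg$lag[k] / fr)
  })
  do.call(rbind, out)
}

# first time the boxcar envelope (centered moving average over the sustain
# window) of the rectified signal exceeds thr; brief oscillation dips and
# isolated sharp transients do not trigger
sustained_onset <- function(d, thr, sus_n, t) {
  env <- stats::filter(d, rep(1 / sus_n, sus_n), sides = 2)
  k <- which(!is.na(env) & env > thr)
  if (!length(k)) return(NA_real_)
  t[k[1]]
}

#' Seizure onsets and per-modality delays
#'
#' LFP onset: first time the `sustain`-second envelope of the rectified
#' band-passed LFP exceeds 3 robust (interictal) SDs — a sustained
#' discharge, not an isolated interictal spike. Per-signal onsets are found
#' the same way on each dF/F trace in the channel's response direction;
#' delays are relative to the LFP onset, and per-cell calcium onsets double
#' as recruitment times.
#'
#' @param lfp band-passed LFP [dv_trace()].
#' @param volt,ca frames x cells dF/F matrices (or `NULL`).
#' @param rate optical frame rate, Hz.
#' @param sustain envelope window / required duration, s (default 1).
#' @param threshold_sd threshold in robust-SD units (default 3).
#' @return List of class `seizure_markers`: `lfp_onset`, `volt_onsets`,
#'   `ca_onsets`, `volt_delays`, `ca_delays` (`NA` where no onset found).
#' @export
seizure_onsets <- function(lfp, volt = NULL, ca = NULL, rate = 30,
                           sustain = 2, threshold_sd = 3) {
  d <- abs(lfp$y)
  lfp_on <- sustained_onset(d, threshold_sd * robust_sd(lfp$y),
                            max(1L, round(sustain * lfp$rate)), lfp$t)
  chan_onsets <- function(y, polarity) {
    if (is.null(y)) return(NULL)
    y <- as.matrix(y)
    tt <- (seq_len(nrow(y)) - 0.5) / rate
    vapply(seq_len(ncol(y)), function(j) {
      dj <- polarity * y[, j]
      sustained_onset(dj, threshold_sd * robust_sd(dj),
                      max(1L, round(sustain * rate)), tt)
    }, numeric(1))
  }
  von <- chan_onsets(volt, -1)
  con <- chan_onsets(ca, +1)
  structure(list(lfp_onset = lfp_on, volt_onsets = von, ca_onsets = con,
                 volt_delays = if (!is.null(von)) von - lfp_on,
                 ca_delays = if (!is.null(con)) con - lfp_on),
            class = "seizure_markers")
}

#' Recruitment order and wavefront-speed estimate
#'
#' Regresses per-cell (calcium) onset times on position; the onset-time
#' gradient gives the propagation axis, and the wavefront speed is the
#' reciprocal of the gradient magnitude. Synchronous onsets (gradient
#' indistinguishable from zero) flag the speed as infinite.
#'
#' @param onsets per-cell onset times, s (>= 3 finite).
#' @param positions n x 2 matrix of (x, y), um.
#' @return List: `order` (cell indices by onset), `delays` (s from first),
#'   `speed` (um/s, `Inf` when synchronous), `direction` (unit vector),
#'   `r2`, `synchronous`.
#' @export
recruitment_order <- function(onsets, positions) {
  positions <- as.matrix(positions)
  ok <- is.finite(onsets)
  if (sum(ok) < 3) stopf("need >= 3 recruited cells")
  on <- onsets[ok]; pos <- positions[ok, , drop = FALSE]
  fit <- stats::lm(on ~ pos[, 1] + pos[, 2])
  g <- stats::coef(fit)[2:3]
  g[is.na(g)] <- 0
  gn <- sqrt(sum(g^2))
  spread <- diff(range(on))
  sync <- gn * max(stats::dist(pos)) < 1e-6 || spread < 1e-9
  r2 <- if (stats::var(on) > 0)
    suppressWarnings(summary(fit)$r.squared) else NA_real_
  list(order = order(onsets), delays = onsets - min(on),
       speed = if (sync) Inf else 1 / gn,
       direction = if (sync) c(NA_real_, NA_real_) else unname(g / gn),
       r2 = r2, synchronous = sync)
}

#' Classify the propagation pattern of one population event
#'
#' Given per-area dF/F traces on a grid and an event window: areas with a
#' detected onset inside the window are "active". If the active fraction is
#' below `coverage_frac` the event is `"partial"`; else if the onset spread
#' is within `sync_tol` it is `"synchronous"`; else if onsets vary
#' monotonically with position along the fitted propagation axis
#' (plane-fit R^2 >= 0.5) it is `"propagating"`; otherwise `"synchronous"`
#' with a low-confidence flag.
#'
#' @param y frames x areas dF/F matrix (>= 4 areas).
#' @param t frame times, s.
#' @param window event window `c(t0, t1)`, s.
#' @param centroids area centroids, n x 2, um.
#' @param polarity response direction (default -1, voltage channel).
#' @param threshold_sd onset threshold in robust-SD units.
#' @param sync_tol onset-spread tolerance for synchrony, s (default 0.1).
#' @param coverage_frac minimum active fraction (default 0.75).
#' @return List: `pattern`, `onsets` (`NA` for inactive areas),
#'   `active_frac`, `low_confidence`.
#' @export
classify_propagation_pattern <- function(y, t, window, centroids,
                                         polarity = -1, threshold_sd = 3,
                                         sync_tol = 0.1, coverage_frac = 0.75) {
  y <- as.matrix(y)
  if (ncol(y) < 4) stopf("need a grid of >= 4 areas")
  sel <- t >= window[1] & t <= window[2]
  onsets <- vapply(seq_len(ncol(y)), function(j) {
    d <- polarity * y[, j]
    thr <- threshold_sd * robust_sd(d)
    k <- which(sel & d > thr)
    if (length(k)) t[k[1]] else NA_real_
  }, numeric(1))
  active <- is.finite(onsets)
  if (!any(active)) stopf("no active areas in the event window")
  frac <- mean(active)
  low_conf <- FALSE
  if (frac < coverage_frac) pattern <- "partial"
  else {
    spread <- diff(range(onsets[active]))
    if (spread <= sync_tol) pattern <- "synchronous"
    else {
      fit <- stats::lm(onsets[active] ~ centroids[active, 1] +
                         centroids[active, 2])
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (is.finite(r2) && r2 >= 0.5) pattern <- "propagating"
      else { pattern <- "synchronous"; low_conf <- TRUE }
    }
  }
  list(pattern = pattern, onsets = onsets, active_frac = frac,
       low_confidence = low_conf)
}
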