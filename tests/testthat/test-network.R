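# Field-level analyses: band-pass, correlation structure, seizure markers,
# recruitment and propagation patterns.

test_that("band-pass removes DC, keeps 10 Hz, kills 100 Hz", {
  rate <- 1000
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  y10 <- sin(2 * pi * 10 * t)
  out10 <- bandpass_lfp(5 + y10, rate)
  expect_lt(abs(mean(out10)), 1e-4)
  mid <- t > 1 & t < 9     # judge away from edges
  amp <- (max(out10[mid]) - min(out10[mid])) / 2
  expect_lt(abs(amp - 1), 0.05)
  y100 <- sin(2 * pi * 100 * t)
  out100 <- bandpass_lfp(y100, rate)
  expect_lt(sd(out100[mid]) / sd(y100[mid]), 10^(-20 / 20))  # >= 20 dB down
  expect_error(bandpass_lfp(y10, rate, low = 60, high = 40), "low < high")
  expect_error(bandpass_lfp(y10, rate, high = 600), "Nyquist")
})

test_that("correlation matrix is symmetric, bounded, NA-flagged when degenerate", {
  set.seed(3)
  y <- matrix(rnorm(6000), 2000, 3)
  y <- cbind(y, y[, 1])                     # duplicate trace -> r = 1
  m <- correlation_matrix(y)
  expect_equal(m$r, t(m$r))
  expect_true(all(diag(m$r) == 1))
  expect_true(all(abs(m$r) <= 1))
  expect_equal(m$r[1, 4], 1)
  expect_lt(max(abs(m$r[1, 2:3])), 0.1)     # long independent noise
  expect_warning(mc <- correlation_matrix(cbind(y[, 1], rep(1, 2000))),
                 "constant")
  expect_true(is.na(mc$r[1, 2]))
})

test_that("correlation vs distance emits all pairs and a sensible trend", {
  set.seed(5)
  n <- 8
  pos <- cbind(seq(0, 700, by = 100), 0)
  shared <- rnorm(3000)
  # synchronized population: distance-independent correlation
  y_sync <- sapply(1:n, function(i) shared + rnorm(3000, 0, 0.3))
  cv <- correlation_vs_distance(correlation_matrix(y_sync), pos)
  expect_equal(nrow(cv$pairs), n * (n - 1) / 2)
  expect_lt(abs(cv$slope), 2e-4)
  expect_gt(cv$mean_r, 0.8)
  # constructed spatial decorrelation: two sources mixed by position, so
  # correlation falls monotonically with pairwise distance
  src2 <- rnorm(3000)
  x01 <- pos[, 1] / max(pos[, 1])
  y_dec <- sapply(1:n, function(i)
    (1 - x01[i]) * shared + x01[i] * src2 + rnorm(3000, 0, 0.2))
  cv2 <- correlation_vs_distance(correlation_matrix(y_dec), pos)
  expect_lt(cv2$slope, -1e-4)
  expect_error(correlation_vs_distance(correlation_matrix(y_sync), pos[1:3, ]),
               "centroid")
})

test_that("windowed LFP-optical correlation is exact for identical signals", {
  rate <- 1000
  t <- seq(0, 40 - 1 / rate, by = 1 / rate)
  set.seed(8)
  lfp_y <- bandpass_lfp(rnorm(length(t)), rate)
  lfp <- dv_trace(lfp_y, t = t, kind = "electrical")
  dec <- round(rate / 30)
  ofp <- dv_trace(duovolt:::box_downsample(lfp_y, dec),
                  t = (seq_len(ceiling(length(t) / dec)) - 0.5) * dec / rate,
                  kind = "dff")
  wc <- windowed_lfp_optical_correlation(lfp, ofp, onset = 30)
  expect_equal(wc$peak_r, c(1, 1), tolerance = 1e-9)
  expect_equal(wc$lag_s, c(0, 0))
  expect_error(windowed_lfp_optical_correlation(lfp, ofp, onset = 15,
                                                windows = list(c(10, 20))),
               "escapes")
})

test_that("seizure onsets and delays on constructed signals", {
  rate30 <- 30
  t30 <- seq(1 / 60, 40, by = 1 / 30)
  lfp_t <- seq(0, 40 - 1e-3, by = 1e-3)
  set.seed(2)
  # interictal noise for 30 s, then discharge (robust SD needs the
  # interictal period to dominate the recording, as in the real scenario)
  lfp_y <- rnorm(length(lfp_t), 0, 0.05)
  lfp_y[lfp_t >= 30] <- lfp_y[lfp_t >= 30] -
    2 * (1 + 0.5 * sin(2 * pi * 3 * lfp_t[lfp_t >= 30]))
  lfp <- dv_trace(lfp_y, t = lfp_t, kind = "electrical")
  volt <- matrix(rnorm(length(t30), 0, 0.003), ncol = 1)
  volt[t30 >= 30.1] <- volt[t30 >= 30.1] - 0.05
  ca <- matrix(rnorm(length(t30), 0, 0.01), ncol = 1)
  ca[t30 >= 32.5] <- ca[t30 >= 32.5] + 1
  mk <- seizure_onsets(lfp, volt, ca, rate = 30, sustain = 1)
  expect_equal(mk$lfp_onset, 30, tolerance = 0.6)
  expect_equal(mk$volt_delays, mk$volt_onsets - mk$lfp_onset)
  expect_equal(mk$ca_onsets - mk$volt_onsets, 2.4, tolerance = 0.5)
  # flat traces flagged absent
  mk0 <- seizure_onsets(lfp, matrix(rnorm(length(t30), 0, 0.003), ncol = 1),
                        NULL, rate = 30, sustain = 1)
  expect_true(is.na(mk0$volt_onsets))
})

test_that("recruitment order recovers a constructed wavefront", {
  set.seed(6)
  pos <- cbind(runif(12, 0, 200), runif(12, 0, 200))
  onsets <- 5 + pos[, 1] / 100 + rnorm(12, 0, 0.05)   # 100 um/s along x
  rec <- recruitment_order(onsets, pos)
  expect_lt(abs(rec$speed - 100) / 100, 0.2)
  expect_false(rec$synchronous)
  expect_equal(rec$order, order(onsets))
  # synchronous onsets flagged with infinite speed
  sync <- recruitment_order(rep(5, 12), pos)
  expect_true(sync$synchronous)
  expect_equal(sync$speed, Inf)
  expect_error(recruitment_order(c(1, 2), pos[1:2, ]), ">= 3")
})

test_that("propagation patterns classify synchronous, propagating, partial", {
  rois <- partition_fov(c(40, 40), 2, 2, pixel_size = 5)
  cents <- rois$centroids[rois$kinds == "grid-cell", ]
  t <- seq(1 / 60, 20, by = 1 / 30)
  n <- length(t)
  base <- function() matrix(rnorm(4 * n, 0, 0.002), n, 4)
  ev <- function(y, j, at, amp = -0.03, dur = 1) {
    idx <- t >= at & t <= at + dur
    y[idx, j] <- y[idx, j] + amp; y
  }
  # all areas within 33 ms -> synchronous
  y <- base(); for (j in 1:4) y <- ev(y, j, 10)
  expect_equal(classify_propagation_pattern(y, t, c(9, 13), cents,
                                            threshold_sd = 5)$pattern,
               "synchronous")
  # monotone left-right onset gradient -> propagating
  y2 <- base()
  x01 <- (cents[, 1] - min(cents[, 1])) / diff(range(cents[, 1]))
  for (j in 1:4) y2 <- ev(y2, j, 10 + 2 * x01[j])
  expect_equal(classify_propagation_pattern(y2, t, c(9, 14), cents,
                                            threshold_sd = 5)$pattern,
               "propagating")
  # only one half active -> partial
  y3 <- base()
  for (j in which(cents[, 1] > median(cents[, 1]))) y3 <- ev(y3, j, 10)
  out <- classify_propagation_pattern(y3, t, c(9, 13), cents,
                                      threshold_sd = 5)
  expect_equal(out$pattern, "partial")
  expect_equal(out$active_frac, 0.5)
  expect_error(classify_propagation_pattern(base(), t, c(9, 13), cents,
                                            threshold_sd = 8),
               "no active areas")
})

test_that("resampling order does not change the windowed correlation", {
  rate <- 1000
  t <- seq(0, 35 - 1 / rate, by = 1 / rate)
  set.seed(12)
  sig <- bandpass_lfp(rnorm(length(t)), rate, 0.2, 10)
  lfp <- dv_trace(sig, t = t, kind = "electrical")
  dec <- round(rate / 30)
  y30 <- duovolt:::box_downsample(sig, dec)
  t30 <- (seq_along(y30) - 0.5) * dec / rate
  ofp <- dv_trace(y30 + rnorm(length(y30), 0, 0.01), t = t30, kind = "dff")
  # correlate (downsampled lfp, ofp) vs (pre-downsampled lfp, ofp)
  w1 <- windowed_lfp_optical_correlation(lfp, ofp, onset = 30)
  lfp30 <- dv_trace(y30, t = t30, kind = "electrical")
  w2 <- windowed_lfp_optical_correlation(lfp30, ofp, onset = 30)
  expect_equal(w1$peak_r, w2$peak_r, tolerance = 0.02)
})
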