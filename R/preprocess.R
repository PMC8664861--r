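# Movie preprocessing: stimulus-artifact frame replacement, rigid
# translation registration, and the per-pixel temporal Kalman stack filter
# (acquisition-noise variance 0.05, prediction bias 0.80 by default).

#' Kalman stack-filter parameters
#'
#' @param gain bias placed on the prediction, in `[0, 1)` (default 0.80).
#' @param noise_var acquisition-noise variance estimate, > 0 (default 0.05).
#' @return An object of class `kalman_params`.
#' @export
kalman_params <- function(gain = 0.80, noise_var = 0.05) {
  if (gain < 0 || gain >= 1) stopf("gain must lie in [0, 1)")
  if (noise_var <= 0) stopf("noise_var must be > 0")
  structure(list(gain = gain, noise_var = noise_var), class = "kalman_params")
}

#' Replace stimulus-artifact frames with their predecessor
#'
#' Each flash-contaminated frame becomes an exact copy of the previous
#' (already cleaned) frame, so a run of consecutive flash frames all copy
#' the last clean frame before the run. A flash at frame 0 has no
#' predecessor and copies the next clean frame instead.
#'
#' @param stack a [frame_stack()].
#' @param flash_frames 0-based frame indices.
#' @return A cleaned [frame_stack()].
#' @export
replace_stimulus_frames <- function(stack, flash_frames) {
  tn <- n_frames(stack)
  flash_frames <- as.integer(flash_frames)
  if (length(flash_frames) && (any(flash_frames < 0) || any(flash_frames >= tn)))
    stopf("flash frame index out of range")
  if (!length(flash_frames)) return(stack)
  data <- stack$data
  flagged <- sort(unique(flash_frames)) + 1L
  for (k in flagged) {
    if (k > 1L) data[k, , ] <- data[k - 1L, , ]
    else {
      nxt <- setdiff(seq_len(tn), flagged)
      if (!length(nxt)) stopf("all frames flagged as flash")
      data[1L, , ] <- stack$data[min(nxt), , ]
    }
  }
  frame_stack(data, stack$frame_rate, stack$channel,
              paste0(stack$origin, "|deflash"))
}

# cross-correlation translation estimate of `img` relative to `ref`
# (positive shift: img content displaced by +(dy,dx) w.r.t. ref),
# with parabolic sub-pixel refinement
estimate_shift <- function(ref, img, max_shift) {
  fa <- stats::fft(ref); fb <- stats::fft(img)
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE))
  h <- nrow(cc); w <- ncol(cc)
  # restrict the search to |shift| <= max_shift
  dy_ok <- c(seq_len(max_shift + 1L), (h - max_shift + 1L):h)
  dx_ok <- c(seq_len(max_shift + 1L), (w - max_shift + 1L):w)
  sub <- cc[dy_ok, dx_ok, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  iy <- dy_ok[pk[1]]; ix <- dx_ok[pk[2]]
  wrap <- function(i, n) if (i - 1L > n / 2) i - 1L - n else i - 1L
  dy <- wrap(iy, h); dx <- wrap(ix, w)
  # parabolic refinement along each axis on the circular neighbourhood
  refine <- function(i, n, get) {
    cm <- get(((i - 2L) %% n) + 1L); c0 <- get(i); cp <- get((i %% n) + 1L)
    den <- cm - 2 * c0 + cp
    if (den < 0) max(-0.5, min(0.5, 0.5 * (cm - cp) / den)) else 0
  }
  dy <- dy + refine(iy, h, function(i) cc[i, ix])
  dx <- dx + refine(ix, w, function(i) cc[iy, i])
  c(dy = dy, dx = dx)
}

#' Rigid translation registration of a movie
#'
#' Estimates, per frame, the integer + sub-pixel (parabolic-peak) rigid
#' translation maximizing the cross-correlation with the reference frame,
#' then shifts each frame back by the rounded estimate (borders filled with
#' the frame median). Shift estimates are capped at `max_shift` pixels; a
#' warning is issued when the cap binds (degenerate, e.g. pure-noise,
#' input).
#'
#' @param stack a [frame_stack()] with at least 2 frames.
#' @param reference `"first-frame"` or `"mean-frame"`.
#' @param max_shift cap on the shift search, pixels (default 1/4 of the
#'   smaller image dimension).
#' @return List: `stack` (registered) and `shifts` (data.frame frame, dx,
#'   dy of detected displacements).
#' @export
register_rigid <- function(stack, reference = c("first-frame", "mean-frame"),
                           max_shift = NULL) {
  reference <- match.arg(reference)
  tn <- n_frames(stack)
  if (tn < 2L) stopf("registration needs at least 2 frames")
  d <- dim(stack$data)
  max_shift <- as.integer(max_shift %||% max(1L, floor(min(d[2], d[3]) / 4)))
  ref <- if (reference == "first-frame") stack$data[1, , ] else
    apply(stack$data, c(2, 3), mean)
  if (stats::sd(ref) == 0) stopf("degenerate (constant) reference frame")
  ref <- ref - mean(ref)
  data <- stack$data
  shifts <- matrix(0, tn, 2, dimnames = list(NULL, c("dy", "dx")))
  capped <- FALSE
  for (k in seq_len(tn)) {
    s <- estimate_shift(ref, stack$data[k, , ] - mean(stack$data[k, , ]),
                        max_shift)
    if (any(abs(s) >= max_shift - 0.5)) capped <- TRUE
    shifts[k, ] <- s
    data[k, , ] <- shift_frame(stack$data[k, , ], -round(s["dy"]),
                               -round(s["dx"]))
  }
  if (capped) warning("shift estimate hit the max-shift cap; ",
                      "registration may be unreliable", call. = FALSE)
  list(stack = frame_stack(data, stack$frame_rate, stack$channel,
                           paste0(stack$origin, "|registered")),
       shifts = data.frame(frame = seq_len(tn) - 1L,
                           dx = shifts[, "dx"], dy = shifts[, "dy"]))
}

#' Temporal Kalman stack filter
#'
#' Classic per-pixel recursive stack filter. The state is initialized to
#' frame 0 with predicted variance `noise_var`; at every subsequent frame
#' `K = var / (var + noise_var)`, the estimate is updated as
#' `gain * prediction + (1 - gain) * observation + K * (observation -
#' prediction)` and `var <- var * (1 - K)`. Output frame t is the estimate
#' after observing frame t; frame 0 passes through. The whole-stack
#' vectorized computation is arithmetic-identical to running the scalar
#' recursion on each pixel's time series.
#'
#' @param stack a [frame_stack()] with at least 2 frames.
#' @param p a [kalman_params()].
#' @return Filtered [frame_stack()].
#' @export
kalman_stack_filter <- function(stack, p = kalman_params()) {
  if (!inherits(p, "kalman_params")) stopf("p must be kalman_params")
  tn <- n_frames(stack)
  if (tn < 2L) stopf("need at least 2 frames")
  data <- stack$data
  est <- data[1, , ]
  v <- p$noise_var
  for (k in 2:tn) {
    K <- v / (v + p$noise_var)
    obs <- data[k, , ]
    est <- p$gain * est + (1 - p$gain) * obs + K * (obs - est)
    v <- v * (1 - K)
    data[k, , ] <- est
  }
  frame_stack(data, stack$frame_rate, stack$channel,
              paste0(stack$origin, "|kalman"))
}
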