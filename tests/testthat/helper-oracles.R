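# Shared fixtures and independent oracles.

# scalar Kalman stack recursion, the independent per-pixel oracle
kalman_scalar <- function(x, gain = 0.80, noise_var = 0.05) {
  est <- x[1]
  v <- noise_var
  out <- x
  for (k in 2:length(x)) {
    K <- v / (v + noise_var)
    est <- gain * est + (1 - gain) * x[k] + K * (x[k] - est)
    v <- v * (1 - K)
    out[k] <- est
  }
  out
}

# closed-form peak time of exp(-t/td) - exp(-t/tr)
peak_time_closed_form <- function(tr, td) td * tr / (td - tr) * log(td / tr)

# small random non-negative stack
random_stack <- function(tn, h, w, seed, rate = 30) {
  set.seed(seed)
  frame_stack(array(abs(rnorm(tn * h * w)) + 0.5, c(tn, h, w)), rate,
              "voltage", "fixture")
}

# integrate a 1 kHz trace to 30 Hz frames with exact (non-integer) frame
# boundaries; returns frame mid-times
to30 <- function(f) {
  y <- duovolt:::integrate_to_frames(matrix(f, ncol = 1), 1000, 30)[, 1]
  list(y = y, t = (seq_along(y) - 0.5) / 30)
}

# tiny two-cell scene on a coarse grid
tiny_scene <- function(n_cells = 2, fov = c(60, 60)) {
  scene_plan(cell_positions = cbind(seq(15, fov[1] - 15,
                                        length.out = n_cells),
                                    rep(fov[2] / 2, n_cells)),
             fov = fov, pixel_size = 2, soma_radius = 5)
}
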