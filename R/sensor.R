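# Indicator forward models: Boltzmann fluorescence-voltage transfer with
# two-exponential kinetics and photobleaching for the voltage channel, and a
# spike-number-linear double-exponential transient for the calcium channel.

#' Voltage-indicator model
#'
#' Describes a genetically encoded voltage indicator as a static Boltzmann
#' fluorescence--voltage (F--V) sigmoid followed by linear two-exponential
#' kinetics and monoexponential photobleaching. The defaults describe a
#' soma-targeted, negative-going ArcLight-like sensor: its F--V midpoint is
#' shifted toward subthreshold potentials, the fast kinetic component is
#' 60 ms, and the local F--V slope at a -68.5 mV rest is about
#' -0.19 %dF/F per mV.
#'
#' @param v_half Boltzmann midpoint, mV.
#' @param k_slope Boltzmann steepness, mV (> 0).
#' @param df_max total fractional fluorescence span of the sigmoid.
#' @param polarity `-1` (fluorescence decreases on depolarization, the
#'   ArcLight convention) or `+1`.
#' @param tau_fast,tau_slow kinetic time constants, s (`tau_fast <= tau_slow`).
#' @param frac_fast weight of the fast component, in `[0, 1]`.
#' @param tau_bleach photobleaching time constant, s (`Inf` disables).
#' @param targeting `"somatic"`, `"pan-cellular"` or `"null"`; `"null"` is a
#'   voltage-insensitive control indicator and forces `df_max = 0`.
#' @param baseline fluorescence at full sigmoid saturation offset, a.u.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(v_half = -30, k_slope = 25, df_max = 0.45,
                         polarity = -1, tau_fast = 0.060, tau_slow = 0.300,
                         frac_fast = 0.7, tau_bleach = Inf,
                         targeting = c("somatic", "pan-cellular", "null"),
                         baseline = 1) {
  targeting <- match.arg(targeting)
  if (k_slope <= 0) stopf("k_slope must be > 0")
  if (frac_fast < 0 || frac_fast > 1) stopf("frac_fast must lie in [0, 1]")
  if (tau_fast > tau_slow) stopf("tau_fast must be <= tau_slow")
  if (!polarity %in% c(-1, 1)) stopf("polarity must be -1 or +1")
  if (tau_bleach <= 0) stopf("tau_bleach must be > 0 (use Inf to disable)")
  if (targeting == "null") df_max <- 0
  structure(list(v_half = v_half, k_slope = k_slope, df_max = df_max,
                 polarity = polarity, tau_fast = tau_fast, tau_slow = tau_slow,
                 frac_fast = frac_fast, tau_bleach = tau_bleach,
                 targeting = targeting, baseline = baseline),
            class = "sensor_model")
}

#' Preset voltage-indicator variants
#'
#' `sensor_preset("ST")` is the soma/subthreshold-tuned variant (F--V
#' midpoint shifted negative, higher sensitivity near rest);
#' `sensor_preset("MT")` is the parent variant with a less negative
#' midpoint; `sensor_preset("null")` is the voltage-insensitive control.
#'
#' @param variant one of `"ST"`, `"MT"`, `"null"`.
#' @param ... overrides passed to [sensor_model()].
#' @return A `sensor_model`.
#' @export
sensor_preset <- function(variant = c("ST", "MT", "null"), ...) {
  variant <- match.arg(variant)
  switch(variant,
         ST = sensor_model(v_half = -30, ...),
         MT = sensor_model(v_half = -10, ...),
         null = sensor_model(targeting = "null", ...))
}

#' Steady-state Boltzmann fluorescence of a voltage-indicator model
#'
#' `F(V) = baseline + df_max / (1 + exp(-polarity (V - v_half) / k_slope))`,
#' so that with polarity -1 fluorescence is non-increasing in membrane
#' potential over the whole range.
#'
#' @param v membrane potential, mV (vectorized).
#' @param m a [sensor_model()].
#' @return Fluorescence, a.u.
#' @export
boltzmann_fluorescence <- function(v, m) {
  m$baseline + m$df_max / (1 + exp(-m$polarity * (v - m$v_half) / m$k_slope))
}

# analytic dF/dV of the Boltzmann transfer, a.u. per mV
boltzmann_slope <- function(v, m) {
  s <- 1 / (1 + exp(-m$polarity * (v - m$v_half) / m$k_slope))
  m$df_max * m$polarity / m$k_slope * s * (1 - s)
}

#' Local fluorescence-voltage slope in %dF/F per mV
#'
#' Derivative of the Boltzmann transfer at `v`, normalized by the
#' steady-state fluorescence at `v` and expressed in percent per mV. This is
#' the "slope" entering the voltage detection-limit formula.
#'
#' @inheritParams boltzmann_fluorescence
#' @return Slope in %dF/F per mV (negative for a negative-going sensor).
#' @export
sensor_slope_pct <- function(v, m) {
  100 * boltzmann_slope(v, m) / boltzmann_fluorescence(v, m)
}

# one-pole recursive exponential smoother, y[n] = a y[n-1] + (1-a) x[n],
# initialized at the first sample (assumed pre-existing steady state)
ema_filter <- function(x, tau, dt) {
  if (tau <= 0) return(x)
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                           init = x[1]))
}

#' Fluorescence response of a voltage indicator to a membrane-voltage trace
#'
#' Applies the static Boltzmann transfer sample-wise, then the linear
#' two-exponential kinetic filter (weights `frac_fast`/`1 - frac_fast`,
#' time constants `tau_fast`/`tau_slow`), then multiplies by the
#' photobleaching envelope `exp(-t / tau_bleach)`. The filter is initialized
#' at the steady state of the first sample, so a constant input yields a
#' constant output (modulo bleach). A `targeting = "null"` control returns
#' the bleach-scaled baseline irrespective of the voltage input.
#'
#' @param vm membrane-potential trace, mV.
#' @param m a [sensor_model()].
#' @param sample_rate sampling rate of `vm`, Hz (default 1000).
#' @return Fluorescence trace, a.u., same length as `vm`.
#' @export
sensor_fluorescence <- function(vm, m, sample_rate = 1000) {
  if (!is.numeric(vm) || any(!is.finite(vm))) stopf("vm must be finite numeric")
  if (!inherits(m, "sensor_model")) stopf("m must be a sensor_model")
  dt <- 1 / sample_rate
  f_ss <- boltzmann_fluorescence(vm, m)
  f <- m$frac_fast * ema_filter(f_ss, m$tau_fast, dt) +
    (1 - m$frac_fast) * ema_filter(f_ss, m$tau_slow, dt)
  if (is.finite(m$tau_bleach)) {
    t <- (seq_along(vm) - 1) * dt
    f <- f * exp(-t / m$tau_bleach)
  }
  f
}

#' Calcium-indicator model
#'
#' Spike-number-dependent indicator: each action potential adds a
#' double-exponential transient of unit-normalized shape and amplitude
#' `a_spike` (fractional fluorescence), so a burst of n coincident spikes
#' peaks at `n * a_spike`. With `subthreshold_gain = 0` (the default) the
#' indicator is blind to subthreshold depolarization, mirroring red calcium
#' indicators whose signal is not detectable for subthreshold events.
#'
#' @param a_spike fractional fluorescence amplitude per spike.
#' @param tau_rise,tau_decay transient time constants, s (`tau_rise < tau_decay`).
#' @param subthreshold_gain fractional fluorescence per mV of depolarization
#'   (default 0).
#' @return An object of class `calcium_model`.
#' @export
calcium_model <- function(a_spike = 0.25, tau_rise = 0.05, tau_decay = 0.4,
                          subthreshold_gain = 0) {
  if (a_spike < 0) stopf("a_spike must be >= 0")
  if (tau_rise >= tau_decay) stopf("tau_rise must be < tau_decay")
  structure(list(a_spike = a_spike, tau_rise = tau_rise,
                 tau_decay = tau_decay, subthreshold_gain = subthreshold_gain),
            class = "calcium_model")
}

# time of the maximum of exp(-t/td) - exp(-t/tr)
kernel_peak_time <- function(tau_rise, tau_decay) {
  tau_decay * tau_rise / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

# unit-peak double-exponential kernel sampled at dt over `n` samples
double_exp_kernel <- function(tau_rise, tau_decay, dt, n) {
  t <- (seq_len(n) - 1) * dt
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  tp <- kernel_peak_time(tau_rise, tau_decay)
  k / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Calcium fluorescence from spike times (and optionally voltage)
#'
#' Linear superposition of per-spike transients on a unit baseline:
#' `F(t) = 1 + a_spike * sum_k K(t - t_k) + subthreshold_gain * (Vm - Vm[1])`,
#' where `K` is the unit-peak double-exponential kernel. Spike-free traces
#' are exactly flat when `subthreshold_gain = 0`.
#'
#' @param spikes spike times, s (may be empty).
#' @param vm membrane-potential trace, mV (sets the output length).
#' @param c a [calcium_model()].
#' @param sample_rate Hz (default 1000).
#' @return Fluorescence trace, a.u., same length as `vm`.
#' @export
calcium_fluorescence <- function(spikes, vm, c, sample_rate = 1000) {
  if (!inherits(c, "calcium_model")) stopf("c must be a calcium_model")
  n <- length(vm)
  dt <- 1 / sample_rate
  dur <- n * dt
  if (length(spikes) && (any(spikes < 0) || any(spikes >= dur)))
    stopf("spike times must lie within the trace duration")
  f <- rep(1, n)
  if (length(spikes)) {
    # impulse train convolved with the kernel (truncated at 8 decay constants)
    imp <- numeric(n)
    idx <- pmin(n, floor(spikes * sample_rate) + 1L)
    for (i in idx) imp[i] <- imp[i] + 1
    klen <- min(n, ceiling(8 * c$tau_decay * sample_rate))
    k <- double_exp_kernel(c$tau_rise, c$tau_decay, dt, klen)
    f <- f + c$a_spike * conv_causal(imp, k)
  }
  if (c$subthreshold_gain != 0) f <- f + c$subthreshold_gain * (vm - vm[1])
  f
}

# causal linear convolution truncated to length(x)
conv_causal <- function(x, k) {
  n <- length(x)
  m <- length(k)
  nf <- stats::nextn(n + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - n))) *
                       stats::fft(c(k, numeric(nf - m))), inverse = TRUE)) / nf
  y[seq_len(n)]
}
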