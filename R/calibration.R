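# Indicator calibration: Boltzmann F-V fits, single/double exponential
# kinetics and photobleach fits, the voltage detection limit, and R^2.

#' Fit a Boltzmann fluorescence-voltage curve
#'
#' Least-squares fit of `y = baseline + amplitude / (1 + exp((v_half - v) /
#' k_slope))` with `k_slope > 0`; a negative-going sensor fits a negative
#' `amplitude`. The analytic derivative of the fitted sigmoid is exposed
#' through [fv_slope_at()].
#'
#' @param voltages mV, at least 5 distinct values spanning the sigmoid.
#' @param dff steady-state fluorescence response at each voltage (any
#'   consistent unit: fraction or percent).
#' @return An object of class `fv_fit`: `v_half`, `k_slope`, `amplitude`,
#'   `baseline`, `rss`, `fitted`.
#' @export
fit_fv_curve <- function(voltages, dff) {
  if (length(unique(voltages)) < 5) stopf("need >= 5 distinct voltages")
  if (length(voltages) != length(dff)) stopf("length mismatch")
  if (stats::sd(dff) < 1e-12 * (1 + max(abs(dff))))
    stopf("flat response: data are not sigmoidal")
  rng <- range(dff)
  span <- diff(rng)
  # rough midpoint: voltage where response crosses mid-range
  mid <- (rng[1] + rng[2]) / 2
  ord <- order(voltages)
  vh0 <- stats::approx(dff[ord] + seq_along(dff) * 1e-12 * span,
                       voltages[ord], xout = mid, rule = 2)$y
  amp0 <- if (stats::cor(voltages, dff) > 0) span else -span
  df <- data.frame(v = voltages, y = dff)
  fit <- try(stats::nls(y ~ b + a / (1 + exp((vh - v) / k)), data = df,
                        start = list(b = if (amp0 > 0) rng[1] else rng[2],
                                     a = amp0, vh = vh0,
                                     k = diff(range(voltages)) / 8),
                        lower = c(-Inf, -Inf, -Inf, 1e-6),
                        upper = c(Inf, Inf, Inf, Inf),
                        algorithm = "port",
                        control = stats::nls.control(maxiter = 500,
                                                     warnOnly = FALSE)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stopf("F-V fit failed: %s", attr(fit, "condition")$message)
  cf <- stats::coef(fit)
  structure(list(v_half = unname(cf["vh"]), k_slope = unname(cf["k"]),
                 amplitude = unname(cf["a"]), baseline = unname(cf["b"]),
                 rss = sum(stats::resid(fit)^2),
                 fitted = stats::fitted(fit)),
            class = "fv_fit")
}

#' Analytic slope of a fitted F-V curve
#'
#' Derivative of the fitted Boltzmann sigmoid at voltage `v`, in the fit's
#' response units per mV (negative for a negative-going sensor).
#'
#' @param fit an `fv_fit` from [fit_fv_curve()].
#' @param v mV (vectorized).
#' @return Slope, response units per mV.
#' @export
fv_slope_at <- function(fit, v) {
  s <- 1 / (1 + exp((fit$v_half - v) / fit$k_slope))
  fit$amplitude / fit$k_slope * s * (1 - s)
}

#' Double-exponential fit of a step response
#'
#' Fits `y = y0 + a1 (1 - exp(-t/tau1)) + a2 (1 - exp(-t/tau2))` to a
#' rising or (mirrored) decaying response; components are relabelled so
#' `tau1 <= tau2` and `tau1` is reported as the fast component.
#'
#' @param t time from response onset, s (>= 20 samples).
#' @param y response samples approaching a plateau.
#' @return An object of class `kinetics_fit`: `a1`, `a2`, `tau1`, `tau2`,
#'   `rss`, `fitted`.
#' @export
fit_double_exponential <- function(t, y) {
  if (length(t) < 20) stopf("need >= 20 samples")
  z <- y - y[1]
  span <- utils::tail(z, max(3, length(z) %/% 20))
  plateau <- mean(span)
  if (abs(plateau) < 1e-12 * (1 + max(abs(y))))
    stopf("response does not approach a distinct plateau")
  tr <- max(t) - min(t)
  df <- data.frame(t = t - t[1], z = z)
  fit <- try(suppressWarnings(
    stats::nls(z ~ a1 * (1 - exp(-t / t1)) + a2 * (1 - exp(-t / t2)),
                        data = df,
                        start = list(a1 = plateau * 0.6, a2 = plateau * 0.4,
                                     t1 = tr / 20, t2 = tr / 3),
                        lower = c(-Inf, -Inf, 1e-6, 1e-6),
                        upper = c(Inf, Inf, Inf, Inf),
                        algorithm = "port",
                        # warnOnly: accept port's "false convergence", which
                        # on near-degenerate two-exponential problems still
                        # yields an accurate least-squares solution
                        control = stats::nls.control(maxiter = 1000,
                                                     warnOnly = TRUE))),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stopf("double-exponential fit did not converge: %s",
          attr(fit, "condition")$message)
  cf <- stats::coef(fit)
  a <- unname(cf[c("a1", "a2")]); tau <- unname(cf[c("t1", "t2")])
  o <- order(tau)
  structure(list(a1 = a[o[1]], a2 = a[o[2]], tau1 = tau[o[1]],
                 tau2 = tau[o[2]], rss = sum(stats::resid(fit)^2),
                 fitted = y[1] + stats::fitted(fit)),
            class = "kinetics_fit")
}

#' Single-exponential decay fit
#'
#' Least-squares fit of `y = c exp(-t / tau)`, used for photobleach decay
#' curves (normalize so `y(0) = 1` first) and spike fluorescence decay.
#'
#' @param t time, s (>= 10 samples).
#' @param y decaying positive samples.
#' @return List: `tau` (s), `scale`, `rss`, `fitted`.
#' @export
fit_single_exponential <- function(t, y) {
  if (length(t) < 10) stopf("need >= 10 samples")
  pos <- y > 0
  if (sum(pos) < 5) stopf("data must be positive to fit an exponential decay")
  sl <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
  if (sl[2] >= 0) stopf("data are not decaying")
  df <- data.frame(t = t, y = y)
  fit <- stats::nls(y ~ c0 * exp(-t / tau), data = df,
                    start = list(c0 = exp(unname(sl[1])),
                                 tau = -1 / unname(sl[2])),
                    lower = c(1e-12, 1e-9), algorithm = "port",
                    control = stats::nls.control(maxiter = 500))
  cf <- stats::coef(fit)
  list(tau = unname(cf["tau"]), scale = unname(cf["c0"]),
       rss = sum(stats::resid(fit)^2), fitted = stats::fitted(fit))
}

#' Voltage detection limit from baseline statistics and the F-V slope
#'
#' The smallest membrane-voltage change distinguishable from baseline
#' fluctuation: `(mean - 3 SD) / slope` of the dF/F samples measured around
#' 0 mV change, reported as a positive mV magnitude (for a negative-going
#' sensor the negative slope cancels the sign).
#'
#' @param baseline_dff dF/F samples at `|dVm| < 1 mV`, in %dF/F (>= 2).
#' @param slope local F-V slope in %dF/F per mV (nonzero), e.g.
#'   [fv_slope_at()] at rest or [sensor_slope_pct()].
#' @return List: `limit` (mV, >= 0), `mean`, `sd`, `slope`.
#' @export
detection_limit <- function(baseline_dff, slope) {
  if (length(baseline_dff) < 2) stopf("need >= 2 baseline samples")
  if (slope == 0) stopf("slope must be nonzero")
  m <- mean(baseline_dff); s <- stats::sd(baseline_dff)
  list(limit = abs((m - 3 * s) / slope), mean = m, sd = s, slope = slope)
}

#' Coefficient of determination
#'
#' Conventional `R^2 = 1 - SS_res / SS_tot` between observed and predicted
#' signals.
#'
#' @param observed,predicted equal-length numeric vectors (>= 2 samples;
#'   `observed` not constant).
#' @return R-squared.
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stopf("observed and predicted must be equal length >= 2")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stopf("observed signal is constant")
  1 - sum((observed - predicted)^2) / sst
}
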