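# Membrane-voltage population simulator: spontaneous UP states, small EPSPs,
# visually evoked depolarizations, spikes, and a focal-seizure episode with
# pre-ictal interictal barrages and a slowly propagating ictal wavefront.
# Voltage is simulated at 1 kHz; the renderer integrates to the frame rate.

VM_RATE <- 1000

#' Population membrane-voltage dynamics parameters
#'
#' Rates and amplitudes of the subthreshold events the simulator generates:
#' slow population-synchronous UP states, small per-cell EPSPs, and
#' stimulus-evoked depolarizations. Events whose peak crosses
#' `spike_threshold` may trigger a short spike burst (recorded in the ground
#' truth; spikes add essentially no signal to the slow voltage indicator).
#' Defaults describe lightly anaesthetized layer-2/3 cortex: rest at
#' -68.5 mV, UP states of roughly 15 mV every few seconds.
#'
#' @param v_rest resting potential, mV.
#' @param up_rate UP-state rate, events/s.
#' @param up_amp mean UP-state amplitude, mV (> 0).
#' @param up_dur UP-state duration scale, s.
#' @param epsp_rate per-cell EPSP rate, events/s.
#' @param epsp_amp mean EPSP amplitude, mV.
#' @param evoked_latency stimulus-to-depolarization latency, s.
#' @param evoked_amp mean evoked amplitude, mV.
#' @param spike_threshold spike threshold, mV (> `v_rest`).
#' @param spike_prob_per_up probability that a threshold-crossing event
#'   actually fires a burst.
#' @return An object of class `voltage_dynamics`.
#' @export
voltage_dynamics <- function(v_rest = -68.5, up_rate = 0.25, up_amp = 18,
                             up_dur = 1.2, epsp_rate = 0.5, epsp_amp = 3,
                             evoked_latency = 0.04, evoked_amp = 12,
                             spike_threshold = -52, spike_prob_per_up = 0.9) {
  if (up_amp <= 0) stopf("up_amp must be > 0")
  if (evoked_latency < 0) stopf("evoked_latency must be >= 0")
  if (spike_threshold <= v_rest) stopf("spike_threshold must exceed v_rest")
  vals <- list(v_rest = v_rest, up_rate = up_rate, up_amp = up_amp,
               up_dur = up_dur, epsp_rate = epsp_rate, epsp_amp = epsp_amp,
               evoked_latency = evoked_latency, evoked_amp = evoked_amp,
               spike_threshold = spike_threshold,
               spike_prob_per_up = spike_prob_per_up)
  if (!all(vapply(vals, is.finite, logical(1)))) stopf("non-finite parameter")
  structure(vals, class = "voltage_dynamics")
}

#' Imaged-field geometry
#'
#' Cell somata positions inside a rectangular field of view. If
#' `cell_positions` is omitted, `n_cells` somata are placed uniformly at
#' random with a minimum separation of two radii (seeded).
#'
#' @param n_cells number of cells to place (ignored if positions given).
#' @param fov field-of-view size `c(width, height)`, um.
#' @param pixel_size um per pixel.
#' @param soma_radius um.
#' @param neuropil_level background fluorescence as a fraction of somatic.
#' @param cell_positions optional n x 2 matrix of (x, y), um.
#' @param seed seed for random placement.
#' @return An object of class `scene_plan`.
#' @export
scene_plan <- function(n_cells = 20, fov = c(200, 200), pixel_size = 2,
                       soma_radius = 6, neuropil_level = 0.3,
                       cell_positions = NULL, seed = 1) {
  if (soma_radius <= 0) stopf("soma_radius must be > 0")
  if (is.null(cell_positions)) {
    cell_positions <- with_seed(child_seed(seed, "scene"), {
      pos <- matrix(NA_real_, 0, 2)
      margin <- soma_radius + 1
      tries <- 0
      while (nrow(pos) < n_cells && tries < 20000) {
        p <- c(stats::runif(1, margin, fov[1] - margin),
               stats::runif(1, margin, fov[2] - margin))
        if (!nrow(pos) || min(sqrt(colSums((t(pos) - p)^2))) >= 2 * soma_radius)
          pos <- rbind(pos, p)
        tries <- tries + 1
      }
      pos
    })
    if (nrow(cell_positions) < n_cells)
      stopf("could not place %d cells in the field of view", n_cells)
  }
  cell_positions <- as.matrix(cell_positions)
  if (any(cell_positions[, 1] < 0) || any(cell_positions[, 1] > fov[1]) ||
      any(cell_positions[, 2] < 0) || any(cell_positions[, 2] > fov[2]))
    stopf("all cells must lie inside the field of view")
  structure(list(cell_positions = cell_positions, soma_radius = soma_radius,
                 neuropil_level = neuropil_level, fov = fov,
                 pixel_size = pixel_size, n_cells = nrow(cell_positions)),
            class = "scene_plan")
}

#' Acquisition-noise model
#'
#' @param heartbeat_freq heartbeat-artifact frequency, Hz (default 7, the
#'   ~420 peaks/min cardiac gain artifact of wide-field imaging in mice).
#' @param heartbeat_amp multiplicative artifact amplitude (fraction).
#' @param photon_scale photon counts per unit fluorescence for shot noise;
#'   0 disables.
#' @param motion_sd per-frame rigid jitter SD, pixels.
#' @param flash_frames 0-based indices of frames saturated by stimulus light.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(heartbeat_freq = 7, heartbeat_amp = 0.01,
                        photon_scale = 2000, motion_sd = 0.3,
                        flash_frames = integer(0)) {
  if (heartbeat_amp < 0 || photon_scale < 0 || motion_sd < 0)
    stopf("noise amplitudes must be >= 0")
  structure(list(heartbeat_freq = heartbeat_freq, heartbeat_amp = heartbeat_amp,
                 photon_scale = photon_scale, motion_sd = motion_sd,
                 flash_frames = as.integer(flash_frames)),
            class = "noise_model")
}

#' Focal-seizure scenario parameters
#'
#' A 4-AP-style focus sits `focus_offset` um outside the imaged field (along
#' -x). During the pre-ictal window the focus fires interictal spikes (IIS)
#' whose rate ramps from `iis_rate_early` to `iis_rate_late`; the fraction
#' of each IIS reaching the imaged cells as an EPSP is 0 over the first
#' third of the window and then ramps quadratically to `iis_coupling_ramp`
#' at seizure onset (surround inhibition collapsing). At onset all imaged
#' cells depolarize within `ictal_sync_jitter` (fast subthreshold
#' propagation) while spiking recruitment sweeps in from the focus at
#' `wavefront_speed` (slow ictal wavefront).
#'
#' @param focus_offset um from the field edge to the initiation site.
#' @param wavefront_speed um/s (> 0).
#' @param preictal_window s of interictal activity before LFP onset.
#' @param iis_rate_early,iis_rate_late IIS rate at start/end of the window,
#'   events/s.
#' @param iis_coupling_ramp coupling reached at onset, in `[0, 1]`.
#' @param ictal_sync_jitter SD of subthreshold onset times across cells, s.
#' @return An object of class `seizure_config`.
#' @export
seizure_config <- function(focus_offset = 600, wavefront_speed = 100,
                           preictal_window = 30, iis_rate_early = 0.4,
                           iis_rate_late = 1.2, iis_coupling_ramp = 1,
                           ictal_sync_jitter = 0.05) {
  if (wavefront_speed <= 0) stopf("wavefront_speed must be > 0")
  if (iis_rate_late < iis_rate_early)
    stopf("iis_rate_late must be >= iis_rate_early")
  if (iis_coupling_ramp < 0 || iis_coupling_ramp > 1)
    stopf("iis_coupling_ramp must lie in [0, 1]")
  structure(list(focus_offset = focus_offset, wavefront_speed = wavefront_speed,
                 preictal_window = preictal_window,
                 iis_rate_early = iis_rate_early, iis_rate_late = iis_rate_late,
                 iis_coupling_ramp = iis_coupling_ramp,
                 ictal_sync_jitter = ictal_sync_jitter),
            class = "seizure_config")
}

# unit-peak difference-of-exponentials kernel values on a sample grid
event_kernel <- function(t, tau_rise, tau_decay) {
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  tp <- kernel_peak_time(tau_rise, tau_decay)
  k / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

# add amp * kernel starting at `onset` (s) into trace `y` in place-ish
add_event <- function(y, onset, amp, tau_rise, tau_decay, rate = VM_RATE) {
  i0 <- floor(onset * rate) + 1L
  n <- length(y)
  if (i0 > n) return(y)
  len <- min(n - i0 + 1L, ceiling((8 * tau_decay + 5 * tau_rise) * rate))
  t <- (seq_len(len) - 1) / rate
  idx <- i0:(i0 + len - 1L)
  y[idx] <- y[idx] + amp * event_kernel(t, tau_rise, tau_decay)
  y
}

UP_TAU_RISE <- 0.10
EVOKED_TAU_RISE <- 0.01
EVOKED_TAU_DECAY <- 0.10
EPSP_TAU_RISE <- 0.005
EPSP_TAU_DECAY <- 0.05

#' Simulate spontaneous and evoked population membrane voltage
#'
#' Generates per-cell membrane voltage at 1 kHz: population-synchronous UP
#' states (Poisson, shared onset, per-cell amplitude jitter), independent
#' per-cell EPSPs, and stimulus-evoked depolarizations beginning
#' `evoked_latency` after each stimulus. Events whose per-cell peak crosses
#' `spike_threshold` fire a 1-3 spike burst (with probability
#' `spike_prob_per_up`) near the event peak; spike times go to the ground
#' truth but add no voltage deflection by default (the slow indicator is
#' spike-insensitive).
#'
#' @param dyn a [voltage_dynamics()].
#' @param scene a [scene_plan()].
#' @param stim_times stimulus times, s, within `[0, duration)`.
#' @param duration s (> 0).
#' @param seed integer master seed.
#' @return A list with `vm` (samples x cells matrix, mV), `spikes` (list of
#'   per-cell spike times), `events` (data.frame: cell, onset, peak_time,
#'   amp_mv, kind), `sample_rate`, and `t`.
#' @export
simulate_population_voltage <- function(dyn, scene, stim_times = numeric(0),
                                        duration = 60, seed = 1) {
  if (duration <= 0) stopf("duration must be > 0")
  if (length(stim_times) && (any(stim_times < 0) || any(stim_times >= duration)))
    stopf("stim_times must lie in [0, duration)")
  n_cells <- scene$n_cells
  nt <- round(duration * VM_RATE)
  with_seed(child_seed(seed, "voltage"), {
    vm <- matrix(dyn$v_rest, nt, n_cells)
    spikes <- vector("list", n_cells)
    ev <- list()
    up_decay <- max(dyn$up_dur / 3, UP_TAU_RISE * 1.5)
    up_peak_off <- kernel_peak_time(UP_TAU_RISE, up_decay)
    ev_peak_off <- kernel_peak_time(EVOKED_TAU_RISE, EVOKED_TAU_DECAY)

    # population events: renewal process with a slow-oscillation dead time
    # (UP states do not overlap), mean rate = up_rate
    up_onsets <- numeric(0)
    if (dyn$up_rate > 0) {
      dead <- min(2.5, 0.5 / dyn$up_rate)
      mean_gap <- max(1 / dyn$up_rate - dead, 0.01)
      tcur <- stats::rexp(1, 1 / mean_gap)
      while (tcur < duration - 2) {
        up_onsets <- c(up_onsets, tcur)
        tcur <- tcur + dead + stats::rexp(1, 1 / mean_gap)
      }
    }
    pop <- data.frame(onset = up_onsets,
                      amp = dyn$up_amp * stats::runif(length(up_onsets), 0.85, 1.15),
                      tr = rep(UP_TAU_RISE, length(up_onsets)),
                      td = rep(up_decay, length(up_onsets)),
                      poff = rep(up_peak_off, length(up_onsets)))
    if (length(stim_times))
      pop <- rbind(pop, data.frame(onset = stim_times + dyn$evoked_latency,
                                   amp = dyn$evoked_amp, tr = EVOKED_TAU_RISE,
                                   td = EVOKED_TAU_DECAY, poff = ev_peak_off))
    if (nrow(pop)) pop <- pop[order(pop$onset), , drop = FALSE]

    for (ci in seq_len(n_cells)) {
      y <- vm[, ci]
      sp <- numeric(0)
      if (nrow(pop)) for (ei in seq_len(nrow(pop))) {
        amp <- pop$amp[ei] * stats::runif(1, 0.9, 1.1)
        jit <- stats::rnorm(1, 0, 0.01)
        onset <- max(0, pop$onset[ei] + jit)
        y <- add_event(y, onset, amp, pop$tr[ei], pop$td[ei])
        peak_t <- onset + pop$poff[ei]
        crossed <- dyn$v_rest + amp >= dyn$spike_threshold
        kind <- "subthreshold"
        if (crossed && stats::runif(1) < dyn$spike_prob_per_up) {
          ns <- 1L + stats::rpois(1, 1)
          st <- peak_t + (seq_len(ns) - 1L) * 0.012
          st <- st[st < duration]
          sp <- c(sp, st)
          kind <- "spiking"
        }
        ev[[length(ev) + 1L]] <- data.frame(cell = ci, onset = onset,
                                            peak_time = peak_t, amp_mv = amp,
                                            kind = kind)
      }
      n_ep <- stats::rpois(1, dyn$epsp_rate * duration)
      if (n_ep) for (o in stats::runif(n_ep, 0, duration))
        y <- add_event(y, o, dyn$epsp_amp * stats::runif(1, 0.5, 1.5),
                       EPSP_TAU_RISE, EPSP_TAU_DECAY)
      vm[, ci] <- y
      spikes[[ci]] <- sort(sp)
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(cell = integer(0), onset = numeric(0), peak_time = numeric(0),
                 amp_mv = numeric(0), kind = character(0))
    events <- events[order(events$cell, events$onset), , drop = FALSE]
    rownames(events) <- NULL
    list(vm = vm, spikes = spikes, events = events, sample_rate = VM_RATE,
         t = (seq_len(nt) - 1) / VM_RATE)
  })
}

IIS_AMP_FOCUS <- 20    # mV deflection of an interictal spike at the focus
IIS_AMP_FIELD <- 20    # mV population EPSP at full coupling in the field
ICTAL_PLATEAU <- 25    # mV sustained ictal depolarization
ICTAL_TAU_RISE <- 0.15

#' Simulate a focal-seizure episode
#'
#' Interictal barrages plus an ictal invasion (see [seizure_config()]).
#' Returns imaged-cell voltage, the focus voltage trace that drives the LFP,
#' and a ground-truth record. LFP onset is at `preictal_window`; per-cell
#' subthreshold onsets cluster within `ictal_sync_jitter` of it, while
#' spiking recruitment times follow focus distance / `wavefront_speed`.
#'
#' @param dyn a [voltage_dynamics()] (supplies rest and threshold).
#' @param scene a [scene_plan()].
#' @param sz a [seizure_config()].
#' @param duration s; must exceed `preictal_window` plus the wavefront
#'   travel time to the far edge of the field.
#' @param seed integer master seed.
#' @return A list with `vm`, `spikes`, `focus_vm`, `iis` (data.frame of
#'   focus IIS: time, coupling), `ground_truth` (list: lfp_onset,
#'   sub_onsets, recruit_times, events, spikes), `sample_rate`, `t`.
#' @export
simulate_seizure_episode <- function(dyn, scene, sz = seizure_config(),
                                     duration = 45, seed = 1) {
  t_on <- sz$preictal_window
  xs <- scene$cell_positions[, 1]
  travel <- (sz$focus_offset + max(xs)) / sz$wavefront_speed
  if (duration <= t_on + travel + 1)
    stopf("duration must cover the pre-ictal window plus wavefront travel")
  n_cells <- scene$n_cells
  nt <- round(duration * VM_RATE)
  with_seed(child_seed(seed, "seizure"), {
    # focus IIS train: rate ramps linearly early -> late over the window
    rmax <- sz$iis_rate_late
    cand <- sort(stats::runif(stats::rpois(1, rmax * t_on), 0, t_on))
    rate_t <- sz$iis_rate_early + (sz$iis_rate_late - sz$iis_rate_early) *
      cand / t_on
    iis_t <- cand[stats::runif(length(cand)) < rate_t / rmax]
    # coupling: zero over the first third (intact surround inhibition),
    # then an accelerating (power-1.5) ramp to the at-onset maximum --
    # EPSPs become detectable well before onset yet keep growing steeply
    cpl <- ifelse(iis_t < t_on / 3, 0,
                  sz$iis_coupling_ramp *
                    ((iis_t - t_on / 3) / (2 * t_on / 3))^1.5)

    focus_vm <- rep(dyn$v_rest, nt)
    for (i in seq_along(iis_t))
      focus_vm <- add_event(focus_vm, iis_t[i], IIS_AMP_FOCUS, 0.008, 0.05)
    # ictal discharge at the focus: tonic depolarization carrying a large
    # rhythmic (spike-wave-like, ~3 Hz) oscillation that dominates the
    # 0.2-50 Hz band of the LFP
    it <- which((seq_len(nt) - 1) / VM_RATE >= t_on)
    tt <- ((it - 1) / VM_RATE) - t_on
    env <- 1 - exp(-tt / ICTAL_TAU_RISE)
    focus_vm[it] <- focus_vm[it] + ICTAL_PLATEAU * env *
      (1 + 0.8 * sin(2 * pi * 3 * tt))

    vm <- matrix(dyn$v_rest, nt, n_cells)
    spikes <- vector("list", n_cells)
    sub_onsets <- recruit <- numeric(n_cells)
    ev <- list()
    dist <- sz$focus_offset + xs   # propagation along +x from the focus edge
    for (ci in seq_len(n_cells)) {
      y <- vm[, ci]
      for (i in seq_along(iis_t)) if (cpl[i] > 0) {
        amp <- cpl[i] * IIS_AMP_FIELD * stats::runif(1, 0.85, 1.15)
        o <- iis_t[i] + 0.02 + stats::rnorm(1, 0, 0.004)  # fast propagation
        y <- add_event(y, o, amp, 0.02, 0.15)
        ev[[length(ev) + 1L]] <- data.frame(cell = ci, onset = o,
                                            peak_time = o + kernel_peak_time(0.02, 0.15),
                                            amp_mv = amp, kind = "iis_epsp")
      }
      so <- t_on + stats::rnorm(1, 0, sz$ictal_sync_jitter)
      sub_onsets[ci] <- so
      i0 <- max(1L, floor(so * VM_RATE) + 1L)
      tt <- (seq(i0, nt) - i0) / VM_RATE
      y[i0:nt] <- y[i0:nt] + ICTAL_PLATEAU * (1 - exp(-tt / ICTAL_TAU_RISE))
      recruit[ci] <- t_on + dist[ci] / sz$wavefront_speed
      sp <- recruit[ci] + cumsum(c(0, rep(0.06, 7)))
      spikes[[ci]] <- sp[sp < duration]
      vm[, ci] <- y
    }
    gt <- list(lfp_onset = t_on, sub_onsets = sub_onsets,
               recruit_times = recruit,
               events = if (length(ev)) do.call(rbind, ev) else NULL,
               spikes = spikes)
    list(vm = vm, spikes = spikes, focus_vm = focus_vm,
         iis = data.frame(time = iis_t, coupling = cpl),
         ground_truth = gt, sample_rate = VM_RATE,
         t = (seq_len(nt) - 1) / VM_RATE)
  })
}

#' Synthesize a local field potential from population voltage
#'
#' The LFP is modeled as the negated, scaled population-mean deviation of
#' membrane voltage from rest (synchronous depolarization appears as a
#' negative field deflection), at the electrophysiology sample rate.
#'
#' @param vm samples x cells matrix (or vector), mV.
#' @param v_rest resting potential subtracted before averaging; default the
#'   first sample of each trace.
#' @param gain mV of LFP per mV of mean depolarization.
#' @return Numeric LFP trace, same length as `nrow(vm)`.
#' @export
synthesize_lfp <- function(vm, v_rest = NULL, gain = 0.1) {
  vm <- as.matrix(vm)
  if (ncol(vm) == 0 || nrow(vm) == 0) stopf("empty population")
  if (is.null(v_rest)) v_rest <- vm[1, ]
  -gain * (rowMeans(sweep(vm, 2, v_rest)))
}
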