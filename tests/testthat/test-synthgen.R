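# Synthetic-data generator: indicator forward models, population voltage,
# seizure episode, LFP synthesis and movie rendering.

test_that("sensor model validates its invariants", {
  expect_error(sensor_model(k_slope = 0), "k_slope")
  expect_error(sensor_model(frac_fast = 1.2), "frac_fast")
  expect_error(sensor_model(tau_fast = 0.5, tau_slow = 0.1), "tau_fast")
  expect_equal(sensor_model(targeting = "null", df_max = 0.4)$df_max, 0)
})

test_that("steady-state response matches the configured Boltzmann (oracle)", {
  m <- sensor_model()
  # constant input -> constant output at the Boltzmann value
  f <- sensor_fluorescence(rep(-68.5, 500), m)
  expect_equal(f, rep(boltzmann_fluorescence(-68.5, m), 500), tolerance = 1e-12)
  # -70 -> -50 mV step: steady-state dF/F equals the Boltzmann ratio, and
  # sits near the linearized -0.19 %/mV x 20 mV = -3.8% prediction
  vm <- c(rep(-70, 300), rep(-50, 6000))
  f <- sensor_fluorescence(vm, m)
  dff <- f[length(f)] / f[300] - 1
  oracle <- boltzmann_fluorescence(-50, m) / boltzmann_fluorescence(-70, m) - 1
  expect_equal(dff, oracle, tolerance = 1e-6)
  expect_lt(abs(dff - (-0.038)), 0.012)
  expect_lt(dff, 0)
})

test_that("ST variant responds more than MT to the same 20 mV step", {
  st <- sensor_preset("ST"); mt <- sensor_preset("MT")
  expect_lt(st$v_half, mt$v_half)
  dff <- function(m) boltzmann_fluorescence(-48.5, m) /
    boltzmann_fluorescence(-68.5, m) - 1
  expect_gt(abs(dff(st)), abs(dff(mt)))
})

test_that("sensor is monotone non-increasing in Vm for polarity -1", {
  m <- sensor_model()
  v <- seq(-120, 60, by = 1)
  expect_true(all(diff(boltzmann_fluorescence(v, m)) <= 0))
  m2 <- sensor_model(polarity = 1)
  expect_true(all(diff(boltzmann_fluorescence(v, m2)) >= 0))
})

test_that("null-targeted control sensor ignores voltage", {
  m <- sensor_model(targeting = "null")
  vm <- -68.5 + 30 * sin(seq(0, 20, length.out = 3000))
  f <- sensor_fluorescence(vm, m)
  expect_equal(f, rep(m$baseline, 3000), tolerance = 1e-12)
})

test_that("simulated step response returns configured kinetics when refit", {
  m <- sensor_model(tau_fast = 0.06, tau_slow = 0.3, frac_fast = 0.7)
  vm <- c(rep(-68.5, 100), rep(-48.5, 1900))
  f <- sensor_fluorescence(vm, m)
  fit <- fit_double_exponential((0:1900) / 1000, f[100:2000])
  expect_lt(abs(fit$tau1 - 0.06) / 0.06, 0.05)
  expect_lt(abs(fit$tau2 - 0.30) / 0.30, 0.05)
})

test_that("photobleach multiplies an exponential envelope", {
  m <- sensor_model(tau_bleach = 50)
  f <- sensor_fluorescence(rep(-68.5, 20000), m)
  fit <- fit_single_exponential((0:19999) / 1000, f / f[1])
  expect_lt(abs(fit$tau - 50) / 50, 0.02)
  expect_lt(abs(fit$scale - 1), 0.02)
})

test_that("calcium transients are linear in spike count with closed-form peak", {
  cm <- calcium_model(a_spike = 0.2, tau_rise = 0.05, tau_decay = 0.4)
  vm <- rep(-68.5, 4000)
  f0 <- calcium_fluorescence(numeric(0), vm, cm)
  expect_equal(f0, rep(1, 4000))          # spike-free trace is flat
  f1 <- calcium_fluorescence(1.0, vm, cm)
  f3 <- calcium_fluorescence(rep(1.0, 3), vm, cm)
  expect_lt(abs(max(f3 - 1) / max(f1 - 1) - 3), 0.01 * 3)
  # peak at t0 + closed-form kernel maximum
  tp_oracle <- peak_time_closed_form(0.05, 0.4)
  t_peak <- (which.max(f1) - 1) / 1000
  expect_lt(abs(t_peak - (1.0 + tp_oracle)), 0.005)
  expect_equal(max(f1) - 1, 0.2, tolerance = 1e-3)
  expect_error(calcium_fluorescence(10, vm, cm), "within the trace")
})

test_that("population voltage: no drive means flat traces at rest", {
  dyn <- voltage_dynamics(up_rate = 0, epsp_rate = 0)
  sim <- simulate_population_voltage(dyn, tiny_scene(), duration = 5, seed = 1)
  expect_equal(sim$vm, matrix(-68.5, 5000, 2))
  expect_equal(nrow(sim$events), 0L)
})

test_that("evoked depolarization peaks shortly after latency (forward oracle)", {
  dyn <- voltage_dynamics(up_rate = 0, epsp_rate = 0, evoked_latency = 0.04)
  sim <- simulate_population_voltage(dyn, tiny_scene(4), stim_times = 1.0,
                                     duration = 3, seed = 7)
  for (ci in 1:4) {
    pk <- sim$t[which.max(sim$vm[, ci])]
    expect_gte(pk, 1.03); expect_lte(pk, 1.10)
  }
})

test_that("simulation is bit-identical under the same seed", {
  dyn <- voltage_dynamics()
  a <- simulate_population_voltage(dyn, tiny_scene(3), duration = 10, seed = 42)
  b <- simulate_population_voltage(dyn, tiny_scene(3), duration = 10, seed = 42)
  expect_identical(a$vm, b$vm)
  expect_identical(a$events, b$events)
  c <- simulate_population_voltage(dyn, tiny_scene(3), duration = 10, seed = 43)
  expect_false(identical(a$vm, c$vm))
})

test_that("population voltage rejects bad inputs", {
  dyn <- voltage_dynamics()
  expect_error(simulate_population_voltage(dyn, tiny_scene(), duration = -1),
               "duration")
  expect_error(simulate_population_voltage(dyn, tiny_scene(),
                                           stim_times = 99, duration = 5),
               "stim_times")
  expect_error(voltage_dynamics(spike_threshold = -80), "spike_threshold")
})

test_that("spikes arise only from threshold-crossing events", {
  dyn <- voltage_dynamics(up_amp = 30, spike_threshold = -50,
                          spike_prob_per_up = 1, epsp_rate = 0)
  sim <- simulate_population_voltage(dyn, tiny_scene(), duration = 30, seed = 3)
  expect_true(all(sim$events$kind == "spiking"))
  expect_true(all(lengths(sim$spikes) > 0))
  dyn2 <- voltage_dynamics(up_amp = 5, spike_threshold = -50, epsp_rate = 0)
  sim2 <- simulate_population_voltage(dyn2, tiny_scene(), duration = 30, seed = 3)
  expect_true(all(sim2$events$kind == "subthreshold"))
  expect_true(all(lengths(sim2$spikes) == 0))
  # spike times strictly increasing per cell
  for (sp in sim$spikes) expect_true(all(diff(sp) > 0))
})

test_that("seizure episode honors geometry and coupling contract", {
  scene <- tiny_scene(2, fov = c(130, 60))  # cells 100 um apart on x
  sz <- seizure_config(focus_offset = 1000, wavefront_speed = 100,
                       preictal_window = 12)
  sim <- simulate_seizure_episode(voltage_dynamics(), scene, sz,
                                  duration = 26, seed = 1)
  gt <- sim$ground_truth
  # recruitment delay difference = distance / speed
  expect_equal(abs(diff(gt$recruit_times)), 1.0, tolerance = 1e-9)
  expect_true(all(gt$recruit_times >= gt$lfp_onset))
  # early-window IIS (zero coupling) leave imaged cells unperturbed
  early <- sim$t < sz$preictal_window / 3 - 0.5
  expect_equal(sim$vm[early, ], matrix(-68.5, sum(early), 2))
  expect_true(any(sim$iis$time < sz$preictal_window / 3))
  # subthreshold onsets tighter than recruitment spread
  sz2 <- seizure_config(preictal_window = 12, ictal_sync_jitter = 0.05)
  big <- scene_plan(n_cells = 12, fov = c(150, 150), seed = 2)
  sim2 <- simulate_seizure_episode(voltage_dynamics(), big, sz2,
                                   duration = 26, seed = 5)
  expect_lt(sd(sim2$ground_truth$sub_onsets), sd(sim2$ground_truth$recruit_times))
  expect_error(seizure_config(wavefront_speed = 0), "wavefront_speed")
})

test_that("LFP is the negated scaled population-mean depolarization", {
  vm <- matrix(-68.5, 10000, 3)
  expect_equal(synthesize_lfp(vm), rep(0, 10000))     # silent -> flat
  vm[4000:4500, ] <- -48.5                            # synchronous 20 mV
  lfp <- synthesize_lfp(vm, v_rest = -68.5, gain = 0.1)
  expect_equal(length(lfp), 10000)                    # 10 s -> 10,000 samples
  expect_equal(min(lfp), -2)
  expect_equal(which.min(lfp), 4000)
  expect_true(all(lfp <= 0))
  expect_error(synthesize_lfp(matrix(numeric(0), 0, 0)), "empty")
})

test_that("rendered movie preserves traces, heartbeat and determinism", {
  scene <- tiny_scene()
  tr <- matrix(1 + 0.2 * sin(seq(0, 6 * pi, length.out = 3000)), 3000, 2)
  # noise-free render: FOV-mean trace proportional to the input trace
  nz0 <- noise_model(heartbeat_amp = 0, photon_scale = 0, motion_sd = 0)
  mv <- render_dual_channel_movie(tr, tr, scene, nz0, seed = 1)
  fov <- extract_traces(mv$volt, partition_fov(mv$volt, 1, 1))
  frame_tr <- duovolt:::integrate_to_frames(tr[, 1, drop = FALSE], 1000, 30)
  r <- cor(fov$y[, 2], frame_tr[, 1])
  expect_gt(r, 0.999999)
  # heartbeat shows up as a 7 Hz spectral peak of the FOV-mean trace
  trb <- matrix(1, 3000, 2)
  nzh <- noise_model(heartbeat_amp = 0.02, photon_scale = 0, motion_sd = 0)
  mvh <- render_dual_channel_movie(trb, trb, scene, nzh, seed = 1)
  y <- extract_traces(mvh$volt, partition_fov(mvh$volt, 1, 1))$y[, 2]
  sp <- Mod(fft(y - mean(y)))[2:45]
  fr <- (2:45 - 1) / length(y) * 30
  expect_lt(abs(fr[which.max(sp)] - 7), 0.2)
  # same seed -> identical stacks; flash frames saturated
  nz <- noise_model(flash_frames = c(5, 6))
  a <- render_dual_channel_movie(tr, tr, scene, nz, seed = 9)
  b <- render_dual_channel_movie(tr, tr, scene, nz, seed = 9)
  expect_identical(a$volt$data, b$volt$data)
  expect_true(all(a$volt$data[6, , ] == a$volt$data[6, 1, 1]))
  expect_error(render_dual_channel_movie(tr, tr, scene,
                                         noise_model(flash_frames = 1e5)),
               "flash_frames")
})

test_that("calcium/voltage dissociation: subthreshold scenes are calcium-silent", {
  dyn <- voltage_dynamics(up_amp = 10, spike_threshold = -50, epsp_rate = 0)
  scene <- tiny_scene(3)
  sim <- simulate_population_voltage(dyn, scene, duration = 30, seed = 11)
  cm <- calcium_model()
  for (ci in 1:3) {
    fca <- calcium_fluorescence(sim$spikes[[ci]], sim$vm[, ci], cm)
    expect_equal(fca, rep(1, length(fca)))
  }
  fv <- sensor_fluorescence(sim$vm[, 1], sensor_model())
  expect_gt(diff(range(fv)), 0)
})
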