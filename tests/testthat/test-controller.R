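test_that("commands map to currents as h W Imax with unit clipping", {
  W <- synergy_matrix(diag(2))
  chans <- list(stim_channel_config(0, I_max = 100),
                stim_channel_config(1, I_max = 150))
  cur <- command_to_currents(c(0.5, 0.5), W, c(0, 1), chans)
  expect_equal(unname(cur), c(50, 75))
  expect_equal(unname(command_to_currents(c(0, 0), W, c(0, 1), chans)), c(0, 0))
  # selective synergy: a unit row routes Imax to one channel only
  W1 <- synergy_matrix(matrix(c(0, 1, 0), 1, 3))
  chans3 <- lapply(0:2, stim_channel_config, I_max = 50)
  expect_equal(unname(command_to_currents(1, W1, 0:2, chans3)), c(0, 50, 0))
  # unnormalized activations are clipped at 1 before scaling
  Wbig <- synergy_matrix(matrix(3, 1, 1))
  expect_equal(unname(command_to_currents(2, Wbig, 0,
                                          list(stim_channel_config(0, I_max = 50)))),
               50)
  expect_error(command_to_currents(c(1, 1), W, c(0, 9), chans),
               "unconfigured")
})

test_that("a zero-jitter session ticks exactly at 1/F_s", {
  cfg <- fast_session(seed = 1, duration = 50)
  log <- run_session(cfg)
  expect_length(log$times, 1000)
  expect_equal(diff(log$times), rep(0.05, 999), tolerance = 1e-12)
  expect_false(log$stopped)
  # first frame is at the session start phase
  expect_equal(log$cycle_percent[1], 75)
  expect_equal(unname(log$commands[1, ]),
               unname(lookup_command(cfg$command_table, 75)))
  # cycle percentage advances by 100 f / F_s per tick, modulo 100
  steps <- diff(log$cycle_percent) %% 100
  expect_equal(steps, rep(100 * 0.1 / 20, 999), tolerance = 1e-9)
})

test_that("sessions are deterministic given config and seed", {
  cfg <- default_session_fixture(seed = 5, duration = 8)
  l1 <- run_session(cfg)
  l2 <- run_session(cfg)
  expect_identical(l1$times, l2$times)
  expect_identical(l1$currents, l2$currents)
  expect_identical(l1$pulse_train$pulses, l2$pulse_train$pulses)
  l3 <- run_session(default_session_fixture(seed = 6, duration = 8))
  expect_false(identical(l1$times, l3$times))
})

test_that("stimulation is open-loop: measured CoP never alters the frames", {
  cfg <- default_session_fixture(seed = 3, duration = 8)
  l1 <- run_session(cfg)
  fake <- data.frame(timestamp = seq(0, 8, by = 0.01),
                     cop_x = rnorm(801, 0, 5))
  l2 <- run_session(cfg, measured_cop = fake)
  expect_identical(l1$times, l2$times)
  expect_identical(l1$commands, l2$commands)
  expect_identical(l1$currents, l2$currents)
  expect_identical(l1$pulse_train$pulses, l2$pulse_train$pulses)
  expect_false(identical(l1$measured_cop, l2$measured_cop))
})

test_that("dispatched pulse amplitudes respect quantization and Imax", {
  log <- run_session(default_session_fixture(seed = 9, duration = 8))
  amp <- log$pulse_train$pulses$amplitude_mA
  expect_true(all(amp <= 50 + 1e-12))
  k <- amp / STIM_QUANT_STEP_MA
  expect_equal(k, round(k), tolerance = 1e-9)
})

test_that("single_burst mode runs one sway cycle", {
  cfg <- fast_session(seed = 2, duration = 50)
  cfg$stim_mode <- "single_burst"
  log <- run_session(cfg)
  expect_equal(log$duration, 10) # one 0.1 Hz cycle
  expect_length(log$times, 200)
})

test_that("a timing violation stops stimulation and marks the log", {
  cfg <- fast_session(seed = 4, duration = 20,
                      jitter = jitter_model("truncnorm", sigma_ms = 30,
                                            trunc_sd = 3))
  log <- run_session(cfg)
  expect_true(log$stopped)
  expect_true(all(log$frames$frame_times <= log$stop_time))
  expect_lte(max(log$pulse_train$pulses$time), log$stop_time + 1e-9)
})

test_that("session config invariants are enforced with named rules", {
  cfg <- fast_session(seed = 1)
  expect_error(session_config(cfg$sway, cfg$command_table, cfg$W,
                              cfg$channel_map, cfg$channels,
                              F_t = 40, F_s = 50, duration = 10, seed = 1),
               "lower than F_t")
  expect_error(session_config(cfg$sway, cfg$command_table, cfg$W,
                              cfg$channel_map, cfg$channels,
                              F_t = 40, F_s = 20, duration = 10),
               "seed")
})

test_that("CoP comparison recovers delay, phase and noise level", {
  ref <- sway_reference(10, 0.1)
  t <- seq(0, 50, by = 0.01)
  ident <- data.frame(timestamp = t, cop = reference_at(ref, t))
  m0 <- compare_cop(ident, ref)
  expect_lt(m0$rms_cm, 1e-9)
  expect_equal(m0$lag_s, 0)
  # one-second delay at 0.1 Hz is a 36 degree phase offset
  delayed <- data.frame(timestamp = t, cop = reference_at(ref, pmax(t - 1, 0)))
  m1 <- compare_cop(delayed, ref)
  expect_equal(m1$lag_s, 1, tolerance = 0.02)
  expect_equal(m1$phase_deg, 36, tolerance = 1)
  set.seed(8)
  noisy <- data.frame(timestamp = t,
                      cop = reference_at(ref, t) + rnorm(length(t), 0, 0.5))
  m2 <- compare_cop(noisy, ref)
  expect_equal(m2$rms_cm, 0.5, tolerance = 0.1)
})
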