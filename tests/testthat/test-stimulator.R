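chans8 <- lapply(0:7, stim_channel_config, I_max = 50, pulse_width_ms = 1)

test_that("current quantization matches the brute-force lattice oracle", {
  expect_equal(quantize_current(0, 150), 0)
  expect_equal(quantize_current(10, 150), 13 * 0.7827)
  expect_equal(quantize_current(150, 150), 191 * 0.7827)
  set.seed(4)
  for (x in c(runif(50, 0, 160), 0.39, 0.392, 149.9)) {
    expect_equal(quantize_current(x, 150), quantize_oracle(x, 150),
                 tolerance = 1e-12)
    expect_equal(quantize_current(x, 40), quantize_oracle(x, 40),
                 tolerance = 1e-12)
  }
  expect_error(quantize_current(-1, 150), "nonnegative")
})

test_that("quantization is idempotent and never exceeds I_max", {
  x <- seq(0, 160, by = 0.11)
  q <- quantize_current(x, 50)
  expect_equal(quantize_current(q, 50), q, tolerance = 1e-12)
  expect_true(all(q <= 50 + 1e-12))
  # step = 0 disables the lattice but keeps the clamp
  expect_equal(quantize_current(c(3.3, 70), 50, step = 0), c(3.3, 50))
})

test_that("channel configuration enforces the device constraints", {
  ch <- stim_channel_config(17, I_max = 120, pulse_width_ms = 2)
  expect_identical(ch$group, 1L)
  expect_identical(stim_channel_config(3)$group, 0L)
  expect_error(stim_channel_config(32), "channel_id")
  expect_error(stim_channel_config(1, I_max = 151))
  expect_error(stim_channel_config(1, pulse_width_ms = 6))
  expect_error(stimulator_state(chans8, F_t = 120), "100 Hz")
})

test_that("pulse count per channel is floor(duration * F_t), frames or not", {
  st <- stimulator_state(chans8, F_t = 40)
  st <- apply_frame(st, 0, rep(10, 8))
  tr <- generate_pulse_train(st, 50)
  counts <- table(tr$pulses$channel)
  expect_true(all(counts == 2000))
  # irregular frame arrivals do not change the count
  st2 <- stimulator_state(chans8, F_t = 40)
  for (t in c(0, 0.013, 0.4, 0.40001, 7.77)) {
    st2 <- apply_frame(st2, t, runif(8, 0, 50))
  }
  counts2 <- table(generate_pulse_train(st2, 50)$pulses$channel)
  expect_true(all(counts2 == 2000))
})

test_that("a single constant frame yields a constant quantized train", {
  st <- stimulator_state(chans8, F_t = 40)
  st <- apply_frame(st, 0, rep(10, 8))
  tr <- generate_pulse_train(st, 5)
  expect_true(all(tr$pulses$amplitude_mA == 13 * 0.7827))
  expect_true(all(tr$pulses$amplitude_mA <= 50))
  # successive onsets on one channel differ by exactly T_t
  for (ch in c(0, 5)) {
    on <- tr$pulses$time[tr$pulses$channel == ch]
    expect_equal(diff(on), rep(1 / 40, length(on) - 1), tolerance = 1e-12)
  }
})

test_that("mid-period updates only affect channels not yet fired", {
  # two channels fire sequentially within a 25 ms period: channel 0 at the
  # period start, channel 4 at 4/16 * T_t = 6.25 ms after it
  chans <- list(stim_channel_config(0, I_max = 150),
                stim_channel_config(4, I_max = 150))
  T_t <- 1 / 40
  mk <- function(frame_time) {
    st <- stimulator_state(chans, F_t = 40, quantization_step = 0)
    st <- apply_frame(st, 0, c(10, 10))
    st <- apply_frame(st, frame_time, c(20, 20))
    generate_pulse_train(st, 3 * T_t)
  }
  amp <- function(tr, ch) tr$pulses$amplitude_mA[tr$pulses$channel == ch]
  # frame exactly at the period-2 boundary: both channels adopt it there
  tr <- mk(T_t)
  expect_equal(amp(tr, 0), c(10, 20, 20))
  expect_equal(amp(tr, 4), c(10, 20, 20))
  # frame between the two firings of period 2: channel 0 already fired and
  # keeps the old amplitude for that period; channel 4 fires with the new one
  tr <- mk(T_t + 0.003)
  expect_equal(amp(tr, 0), c(10, 10, 20))
  expect_equal(amp(tr, 4), c(10, 20, 20))
  # frame after all of period 2 fired: nothing changes until period 3
  tr <- mk(T_t + 0.010)
  expect_equal(amp(tr, 0), c(10, 10, 20))
  expect_equal(amp(tr, 4), c(10, 10, 20))
})

test_that("the two 16-channel groups fire concurrently, slots sequentially", {
  chans <- lapply(c(0, 3, 16, 19), stim_channel_config)
  st <- apply_frame(stimulator_state(chans, F_t = 40), 0, rep(5, 4))
  tr <- generate_pulse_train(st, 1 / 40)
  t_of <- function(ch) tr$pulses$time[tr$pulses$channel == ch]
  expect_equal(t_of(0), t_of(16)) # same slot, different groups
  expect_equal(t_of(3), t_of(19))
  expect_gt(t_of(3), t_of(0)) # later slot in the same group
})

test_that("apply_frame rejects unknown channels and out-of-order frames", {
  st <- stimulator_state(chans8, F_t = 40)
  expect_error(apply_frame(st, 0, c(1), channel_ids = 20), "unknown channel")
  st <- apply_frame(st, 1, rep(0, 8))
  expect_error(apply_frame(st, 0.5, rep(0, 8)), "time order")
})

test_that("the timing monitor flags out-of-tolerance intervals", {
  # perfectly periodic updates: nothing to report
  ok <- timing_monitor(seq(0, 1, by = 0.05), T_sE = 50, tolerance = 25)
  expect_identical(nrow(ok$violations), 0L)
  # documented example: one 76 ms interval out of [25, 75]
  mon <- timing_monitor(c(0, 0.050, 0.100, 0.176), T_sE = 50, tolerance = 25)
  expect_identical(nrow(mon$violations), 1L)
  expect_equal(mon$violations$interval_ms, 76)
  expect_equal(mon$stop_events, 0.176)
  # a single gap of T_sE + 2 * tolerance
  mon2 <- timing_monitor(c(0, 0.1, 0.2), T_sE = 100, tolerance = 10)
  expect_identical(nrow(mon2$violations), 0L)
  mon3 <- timing_monitor(c(0, 0.1, 0.22), T_sE = 100, tolerance = 10)
  expect_identical(nrow(mon3$violations), 1L)
  # fewer than two updates: empty report
  expect_identical(timing_monitor(0.5, 50, 25)$n_intervals, 0L)
})
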