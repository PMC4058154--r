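# Open-loop synergistic controller.
#
# At each tick of the synergy clock (nominal rate F_s, jittered like a
# non-real-time host), the controller reads the cycle percentage of the sway
# reference from elapsed simulated time, looks up the neural command in the
# 100-entry table, maps it to per-channel currents via M = H x W x Imax and
# dispatches a parameter frame to the stimulator. Measured CoP from the force
# plate is logged for feedback display only: it never alters stimulation.

#' Session configuration
#'
#' @param sway a [sway_reference()]
#' @param command_table a [build_command_table()] result
#' @param W a [synergy_matrix()] (K must match the table)
#' @param channel_map integer vector of length N: channel id (0-31) driven by
#'   each muscle (column of W)
#' @param channels list of [stim_channel_config()] covering the mapped ids
#' @param F_t stimulation frequency (Hz), <= 100
#' @param F_s synergy update frequency (Hz); must be below `F_t` and within
#'   the supported 1-20 Hz range
#' @param duration session duration (s)
#' @param jitter a [jitter_model()] for the controller tick (default
#'   truncated normal, sigma 8 ms)
#' @param seed integer seed (mandatory: sessions are reproducible by contract)
#' @param stim_mode `"continuous"` (run for `duration`) or `"single_burst"`
#'   (one sway cycle, capped at `duration`)
#' @param quantization_step stimulator DAC step (mA); 0 disables quantization
#' @return a `session_config` object
#' @export
session_config <- function(sway, command_table, W, channel_map, channels,
                           F_t = 40, F_s = 20, duration = 50,
                           jitter = jitter_model("truncnorm", sigma_ms = 8),
                           seed, stim_mode = c("continuous", "single_burst"),
                           quantization_step = STIM_QUANT_STEP_MA) {
  stim_mode <- match.arg(stim_mode)
  if (missing(seed) || is.null(seed)) {
    stop("seed is required: sessions must be reproducible")
  }
  if (F_s >= F_t) {
    stop("F_s must be lower than F_t (synergy updates slower than stimulation)")
  }
  if (F_s < 1 || F_s > 20) stop("F_s outside the supported 1-20 Hz range")
  if (F_t > 100) stop("F_t exceeds the 100 Hz device limit")
  stopifnot(duration > 0, inherits(sway, "sway_reference"),
            inherits(command_table, "neural_command_table"),
            inherits(W, "synergy_matrix"))
  if (command_table$K != W$K) stop("command table and W disagree on K")
  if (length(channel_map) != W$N) {
    stop("channel_map must give one channel per muscle (column of W)")
  }
  ids <- vapply(channels, function(ch) ch$channel_id, integer(1))
  if (!all(channel_map %in% ids)) {
    stop("channel_map refers to unconfigured channel id(s)")
  }
  structure(list(sway = sway, command_table = command_table, W = W,
                 channel_map = as.integer(channel_map), channels = channels,
                 F_t = F_t, F_s = F_s, duration = duration, jitter = jitter,
                 seed = as.integer(seed), stim_mode = stim_mode,
                 quantization_step = quantization_step),
            class = "session_config")
}

#' Map a neural command to per-channel currents
#'
#' Computes muscle activations a = h %*% W, clips them to \[0, 1\] (so no
#' channel can be driven past its limit by unnormalized inputs) and scales
#' each muscle's activation by the Imax of its mapped channel:
#' current_i = a_i * Imax(channel_map\[i\]).
#'
#' @param h K-vector neural command, >= 0
#' @param W a [synergy_matrix()] (or K x N matrix)
#' @param channel_map integer vector: channel id per muscle
#' @param channels list of [stim_channel_config()]
#' @return named numeric vector of currents (mA), one per mapped channel id
#' @export
#' @examples
#' W <- synergy_matrix(diag(2))
#' chans <- list(stim_channel_config(0, I_max = 100),
#'               stim_channel_config(1, I_max = 150))
#' command_to_currents(c(0.5, 0.5), W, c(0, 1), chans) # 50, 75
command_to_currents <- function(h, W, channel_map, channels) {
  wm <- if (inherits(W, "synergy_matrix")) W$weights else as.matrix(W)
  assert_nonneg(h, "neural command")
  if (length(h) != nrow(wm)) stop("command length must equal K")
  ids <- vapply(channels, function(ch) ch$channel_id, integer(1))
  if (!all(channel_map %in% ids)) {
    stop("muscle mapped to an unconfigured channel")
  }
  a <- pmin(pmax(as.numeric(h %*% wm), 0), 1)
  imax <- vapply(channel_map, function(id) {
    channels[[which(ids == id)]]$I_max
  }, numeric(1))
  stats::setNames(a * imax, as.character(channel_map))
}

#' Run an open-loop stimulation session
#'
#' Simulates the controller clock at nominal period 1/F_s with jitter drawn
#' from the config's jitter model (deterministic under the config seed). At
#' each tick the cycle percentage is computed from elapsed simulated time, the
#' command looked up, currents computed and a frame dispatched to the
#' simulated stimulator. The timing monitor checks every inter-tick period
#' against a tolerance of one stimulation period; a violation stops
#' stimulation at that point and marks the log.
#'
#' @param config a [session_config()]
#' @param measured_cop optional data.frame (timestamp, cop_x) standing in for
#'   the force-plate stream; if `NULL` one is simulated from the reference.
#'   Measured CoP is logged only — stimulation is open-loop and bit-identical
#'   whatever is supplied here.
#' @return a `session_log`: tick times, cycle percentages, commands, currents,
#'   measured periods T_s (ms), the dispatched frames as a
#'   [stimulator_state()], the [generate_pulse_train()] result, reference and
#'   measured CoP streams, metronome events, and stop information
#' @export
run_session <- function(config, measured_cop = NULL) {
  stopifnot(inherits(config, "session_config"))
  duration <- config$duration
  if (config$stim_mode == "single_burst") {
    duration <- min(duration, 1 / config$sway$frequency)
  }
  nominal <- 1 / config$F_s
  ticks <- with_seed(config$seed, {
    n_guess <- ceiling(duration * config$F_s * 1.25) + 50L
    repeat {
      per <- nominal + draw_period_jitter(config$jitter, n_guess) / 1000
      per <- pmax(per, 1e-4) # a tick can never precede its predecessor
      tt <- cumsum(c(0, per))
      if (tt[length(tt)] >= duration) break
      n_guess <- n_guess * 2L
    }
    tt[tt < duration]
  })
  p <- cycle_percent_at(config$sway, ticks)
  commands <- t(vapply(p, function(pi) lookup_command(config$command_table, pi),
                       numeric(config$command_table$K)))
  commands <- matrix(commands, ncol = config$command_table$K)
  currents <- t(apply(commands, 1L, command_to_currents, W = config$W,
                      channel_map = config$channel_map,
                      channels = config$channels))
  currents <- matrix(currents, ncol = length(config$channel_map),
                     dimnames = list(NULL, as.character(config$channel_map)))

  # timing monitor: tolerance of one stimulation period
  mon <- timing_monitor(ticks, T_sE = 1000 / config$F_s,
                        tolerance = 1000 / config$F_t)
  stopped <- length(mon$stop_events) > 0
  stop_time <- if (stopped) mon$stop_events[1] else NA_real_
  keep <- if (stopped) ticks <= stop_time else rep(TRUE, length(ticks))

  stim <- stimulator_state(config$channels, F_t = config$F_t,
                           quantization_step = config$quantization_step)
  # collapse duplicate channel targets: frames address unique channel ids
  uniq_ids <- unique(config$channel_map)
  for (i in which(keep)) {
    stim <- apply_frame(stim, ticks[i],
                        amplitudes = currents[i, as.character(uniq_ids)],
                        channel_ids = uniq_ids)
  }
  train_end <- if (stopped) stop_time else duration
  train <- generate_pulse_train(stim, max(train_end, 1 / config$F_t))

  if (is.null(measured_cop)) {
    measured_cop <- simulate_stream(
      function(t) reference_at(config$sway, t),
      duration = duration, seed = config$seed + 1L
    )[, c("timestamp", "cop_x")]
  }
  structure(list(
    times = ticks, cycle_percent = p, commands = commands,
    currents = currents, T_s_ms = diff(ticks) * 1000,
    frames = stim, pulse_train = train,
    reference_cop = data.frame(timestamp = ticks,
                               cop = reference_at(config$sway, ticks)),
    measured_cop = measured_cop,
    metronome = metronome_schedule(config$sway, duration),
    monitor = mon, stopped = stopped, stop_time = stop_time,
    duration = duration, config = config
  ), class = "session_log")
}

#' Compare a measured CoP stream with the reference trajectory
#'
#' Resamples the measured stream onto a uniform grid over the overlapping
#' time support and reports the RMS tracking error, the lag maximizing the
#' cross-correlation with the reference (scanned over +/- half a sway period)
#' and the equivalent phase offset in degrees of the sway cycle.
#'
#' @param measured data.frame with `timestamp` (s) and a CoP column (`cop` or
#'   `cop_x`, cm)
#' @param ref a [sway_reference()]
#' @param grid_dt resampling step (s), default 0.01
#' @return list with `rms_cm`, `lag_s`, `phase_deg`
#' @export
compare_cop <- function(measured, ref, grid_dt = 0.01) {
  cop_col <- intersect(c("cop", "cop_x"), names(measured))[1]
  if (is.na(cop_col)) stop("measured stream needs a 'cop' or 'cop_x' column")
  t0 <- max(0, min(measured$timestamp))
  t1 <- min(max(measured$timestamp), Inf)
  if (t1 <= t0) stop("measured stream and reference do not overlap in time")
  grid <- seq(t0, t1, by = grid_dt)
  meas <- stats::approx(measured$timestamp, measured[[cop_col]],
                        xout = grid, rule = 2)$y
  rms <- sqrt(mean((meas - reference_at(ref, grid))^2))
  half <- 1 / (2 * ref$frequency)
  lags <- seq(-half, half, by = grid_dt)
  cc <- vapply(lags, function(l) {
    shifted <- grid - l
    ok <- shifted >= 0
    if (sum(ok) < 3) return(-Inf)
    suppressWarnings(stats::cor(meas[ok], reference_at(ref, shifted[ok])))
  }, numeric(1))
  lag <- lags[which.max(cc)]
  phase <- ((360 * ref$frequency * lag + 180) %% 360) - 180
  list(rms_cm = rms, lag_s = lag, phase_deg = phase)
}
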