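# Simulated multi-channel current-controlled electrostimulator.
#
# Device constraints modeled: 32 channels in two independent groups of 16
# (groups fire concurrently, channels within a group sequentially in id order,
# spread uniformly over one stimulation period); current 0-150 mA with a DAC
# resolution of 0.7827 mA; pulse width 0-5 ms; stimulation frequency up to
# 100 Hz. Parameter updates arriving mid-period only affect channels that
# have not yet fired in that period.

#' DAC current resolution of the simulated stimulator (mA)
#' @export
STIM_QUANT_STEP_MA <- 0.7827

#' Configuration of one stimulation channel
#'
#' @param channel_id integer in 0..31; the group (0 or 1) is `channel_id %/% 16`
#' @param I_max maximum current (mA), in (0, 150]
#' @param pulse_width_ms pulse width (ms), in (0, 5]
#' @param waveform `"biphasic"` or `"monophasic"` (envelope analysis uses the
#'   absolute amplitude either way; the micro-shape is not modeled)
#' @return a `stim_channel_config` object
#' @export
stim_channel_config <- function(channel_id, I_max = 50, pulse_width_ms = 1,
                                waveform = c("biphasic", "monophasic")) {
  waveform <- match.arg(waveform)
  channel_id <- as.integer(channel_id)
  stopifnot(channel_id >= 0L, channel_id <= 31L,
            I_max > 0, I_max <= 150,
            pulse_width_ms > 0, pulse_width_ms <= 5)
  structure(list(channel_id = channel_id, group = channel_id %/% 16L,
                 I_max = I_max, pulse_width_ms = pulse_width_ms,
                 waveform = waveform),
            class = "stim_channel_config")
}

#' Quantize a current amplitude to the stimulator's DAC lattice
#'
#' Rounds to the nearest integer multiple of the quantization step; if the
#' nearest multiple exceeds `I_max`, the largest multiple not exceeding
#' `I_max` is used instead. `step = 0` disables quantization (amplitude is
#' only clamped), which is useful to isolate the quantization effect in
#' envelope comparisons.
#'
#' @param amplitude requested current (mA), >= 0, vectorized
#' @param I_max channel current limit (mA)
#' @param step quantization step (mA), default [STIM_QUANT_STEP_MA]
#' @return quantized, clamped current (mA)
#' @export
#' @examples
#' quantize_current(10, 150)  # 13 * 0.7827 = 10.1751 mA
quantize_current <- function(amplitude, I_max = 150, step = STIM_QUANT_STEP_MA) {
  if (any(amplitude < 0)) stop("amplitude must be nonnegative")
  stopifnot(I_max > 0, step >= 0)
  if (step == 0) return(pmin(amplitude, I_max))
  q <- round(amplitude / step) * step
  kmax <- floor(I_max / step + 1e-9)
  pmin(q, kmax * step)
}

#' Create a stimulator state
#'
#' Holds the channel configuration, the stimulation frequency and the log of
#' parameter frames received so far. Frames are turned into pulses by
#' [generate_pulse_train()].
#'
#' @param channels list of [stim_channel_config()]
#' @param F_t stimulation frequency (Hz), <= 100 (device limit)
#' @param quantization_step DAC step (mA); 0 disables quantization
#' @return a `stimulator_state` object
#' @export
stimulator_state <- function(channels, F_t = 40,
                             quantization_step = STIM_QUANT_STEP_MA) {
  stopifnot(F_t > 0)
  if (F_t > 100) stop("F_t exceeds the 100 Hz device limit")
  ids <- vapply(channels, function(ch) ch$channel_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate channel ids")
  names(channels) <- as.character(ids)
  structure(list(channels = channels, channel_ids = ids, F_t = F_t,
                 quantization_step = quantization_step,
                 frame_times = numeric(0),
                 frame_amplitudes = matrix(numeric(0), 0L, length(ids)),
                 frame_widths = matrix(numeric(0), 0L, length(ids))),
            class = "stimulator_state")
}

#' Apply a stimulation-parameter frame to the stimulator
#'
#' Registers new per-channel amplitudes (and optionally pulse widths) at
#' `arrival_time`. The update semantics follow the hardware rule: a channel
#' whose pulse in the ongoing stimulation period has already fired keeps its
#' old parameters until the next period, while channels not yet fired adopt
#' the new values immediately; from the next period every channel uses the new
#' values. The rule is realized when pulses are generated: each pulse takes
#' the most recent frame that arrived at or before its onset.
#'
#' @param state a [stimulator_state()]
#' @param arrival_time frame arrival time (s); must not precede earlier frames
#' @param amplitudes numeric vector of requested currents (mA) named by (or
#'   ordered as) the configured channel ids
#' @param widths optional pulse widths (ms); defaults to each channel's
#'   configured width
#' @param channel_ids ids the amplitudes refer to (default: all configured)
#' @return the updated `stimulator_state`
#' @export
apply_frame <- function(state, arrival_time, amplitudes, widths = NULL,
                        channel_ids = state$channel_ids) {
  stopifnot(inherits(state, "stimulator_state"))
  unknown <- setdiff(channel_ids, state$channel_ids)
  if (length(unknown) > 0) {
    stop("unknown channel id(s): ", paste(unknown, collapse = ", "))
  }
  if (length(amplitudes) != length(channel_ids)) {
    stop("amplitudes and channel_ids lengths differ")
  }
  if (length(state$frame_times) > 0 && arrival_time < max(state$frame_times)) {
    stop("frames must arrive in time order")
  }
  amp_row <- rep(0, length(state$channel_ids))
  names(amp_row) <- as.character(state$channel_ids)
  # channels not in this frame keep their previous requested value
  if (nrow(state$frame_amplitudes) > 0) {
    amp_row[] <- state$frame_amplitudes[nrow(state$frame_amplitudes), ]
  }
  amp_row[as.character(channel_ids)] <- amplitudes
  wid_row <- vapply(state$channels, function(ch) ch$pulse_width_ms, numeric(1))
  if (nrow(state$frame_widths) > 0) {
    wid_row[] <- state$frame_widths[nrow(state$frame_widths), ]
  }
  if (!is.null(widths)) wid_row[as.character(channel_ids)] <- widths
  state$frame_times <- c(state$frame_times, arrival_time)
  state$frame_amplitudes <- rbind(state$frame_amplitudes, amp_row,
                                  deparse.level = 0)
  state$frame_widths <- rbind(state$frame_widths, wid_row, deparse.level = 0)
  state
}

# Onset offset of a channel within one stimulation period: the 16 slots of a
# group are spread uniformly over T_t; the two groups run concurrently.
channel_offset <- function(channel_id, T_t) {
  (channel_id %% 16L) / 16 * T_t
}

#' Generate the per-channel pulse train of a session
#'
#' Every channel fires once per stimulation period T_t = 1/F_t at its fixed
#' intra-period offset; the pulse amplitude is the quantized value of the most
#' recent frame that arrived at or before the pulse onset (zero before the
#' first frame). Exactly `floor(duration * F_t)` periods are generated.
#'
#' @param state a [stimulator_state()] with frames applied
#' @param duration session duration (s)
#' @return a `pulse_train`: data.frame `pulses` (time, channel, amplitude_mA,
#'   width_ms) plus `F_t`, `quantization_step` and `duration`
#' @export
generate_pulse_train <- function(state, duration) {
  stopifnot(inherits(state, "stimulator_state"), duration > 0)
  T_t <- 1 / state$F_t
  nper <- floor(duration * state$F_t)
  out <- vector("list", length(state$channel_ids))
  for (i in seq_along(state$channel_ids)) {
    id <- state$channel_ids[i]
    cfg <- state$channels[[as.character(id)]]
    onsets <- (seq_len(nper) - 1L) * T_t + channel_offset(id, T_t)
    k <- findInterval(onsets + 1e-12, state$frame_times)
    amp <- ifelse(k > 0, state$frame_amplitudes[pmax(k, 1L), i], 0)
    wid <- ifelse(k > 0, state$frame_widths[pmax(k, 1L), i], cfg$pulse_width_ms)
    amp <- quantize_current(amp, cfg$I_max, state$quantization_step)
    out[[i]] <- data.frame(time = onsets, channel = id,
                           amplitude_mA = amp, width_ms = wid)
  }
  pulses <- do.call(rbind, out)
  pulses <- pulses[order(pulses$time, pulses$channel), ]
  rownames(pulses) <- NULL
  structure(list(pulses = pulses, F_t = state$F_t,
                 quantization_step = state$quantization_step,
                 duration = duration,
                 channel_ids = state$channel_ids),
            class = "pulse_train")
}

#' Check synergy-update periods against a tolerance window
#'
#' Flags every inter-update interval outside `[T_sE - tolerance,
#' T_sE + tolerance]`. The stimulator's timing monitor emits a stop signal at
#' the first violation so stimulation can be halted when the soft-real-time
#' host fails its timing contract.
#'
#' @param update_times sorted update arrival times (s)
#' @param T_sE expected update period (ms)
#' @param tolerance tolerance (ms), typically one stimulation period T_t
#' @return list with `violations` (data.frame: index, interval_ms, time_s),
#'   `stop_events` (times of all violations, s) and `n_intervals`
#' @export
timing_monitor <- function(update_times, T_sE, tolerance) {
  stopifnot(tolerance >= 0)
  if (length(update_times) < 2L) {
    return(list(violations = data.frame(index = integer(0),
                                        interval_ms = numeric(0),
                                        time_s = numeric(0)),
                stop_events = numeric(0), n_intervals = 0L))
  }
  if (is.unsorted(update_times)) stop("update_times must be sorted")
  iv <- diff(update_times) * 1000
  bad <- which(iv < T_sE - tolerance | iv > T_sE + tolerance)
  list(violations = data.frame(index = bad, interval_ms = iv[bad],
                               time_s = update_times[bad + 1L]),
       stop_events = update_times[bad + 1L],
       n_intervals = length(iv))
}
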