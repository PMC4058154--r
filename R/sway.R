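# Sinusoidal CoP sway reference and the cycle-locked neural-command table.
#
# Phase convention: the cycle origin (0%) is the positive extreme of the
# reference, r(p) = A * cos(2*pi*p/100). The ascending zero crossing then
# falls at exactly 75% of the cycle, which is where a training session starts
# (the subject stands with the CoP at zero, about to sway toward the positive
# extreme).

#' Sinusoidal sway reference
#'
#' @param amplitude peak CoP excursion (cm), > 0
#' @param frequency sway frequency (Hz); voluntary postural sway lies below
#'   0.5 Hz, so larger values trigger a warning
#' @param axis sway axis, mediolateral (`"ML"`) or anteroposterior (`"AP"`)
#' @param start_cycle_percent cycle percentage at session start, in \[0, 100);
#'   default 75 (ascending zero crossing)
#' @return a `sway_reference` object
#' @export
#' @examples
#' ref <- sway_reference(amplitude = 10, frequency = 0.1)
#' reference_at(ref, c(0, 2.5)) # 0 cm, then the +10 cm extreme
sway_reference <- function(amplitude, frequency, axis = c("ML", "AP"),
                           start_cycle_percent = 75) {
  axis <- match.arg(axis)
  stopifnot(amplitude > 0, frequency > 0,
            start_cycle_percent >= 0, start_cycle_percent < 100)
  if (frequency > 0.5) {
    warning("sway frequency above 0.5 Hz exceeds the voluntary postural sway range")
  }
  structure(list(amplitude = amplitude, frequency = frequency, axis = axis,
                 start_cycle_percent = start_cycle_percent),
            class = "sway_reference")
}

#' Cycle percentage of the reference at elapsed time t
#'
#' @param ref a [sway_reference()]
#' @param t elapsed session time (s), vectorized
#' @return percentage of the sway cycle in \[0, 100)
#' @export
cycle_percent_at <- function(ref, t) {
  stopifnot(all(t >= 0))
  (ref$start_cycle_percent + 100 * ref$frequency * t) %% 100
}

#' Reference CoP value at elapsed time t
#'
#' r(t) = A cos(2 pi p(t) / 100) with p(t) the cycle percentage.
#'
#' @inheritParams cycle_percent_at
#' @return CoP reference (cm), vectorized over `t`
#' @export
reference_at <- function(ref, t) {
  p <- cycle_percent_at(ref, t)
  ref$amplitude * cospi(2 * p / 100)
}

#' Invert a CoP value to a cycle percentage
#'
#' The cosine reference is two-valued in amplitude; the movement direction
#' (sign of the reference slope) picks the branch. Values beyond the
#' amplitude are clamped (measurement overshoot) with a warning.
#'
#' @param ref a [sway_reference()]
#' @param cop measured or reference CoP (cm), vectorized
#' @param direction `"rising"` (CoP increasing) or `"falling"`
#' @return cycle percentage in \[0, 100)
#' @export
#' @examples
#' ref <- sway_reference(10, 0.1)
#' cycle_percentage_from_cop(ref, 0, "rising") # 75
cycle_percentage_from_cop <- function(ref, cop, direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  A <- ref$amplitude
  if (any(abs(cop) > A)) {
    warning("CoP beyond the reference amplitude; clamped to +/-A")
    cop <- pmin(pmax(cop, -A), A)
  }
  base <- (100 / (2 * pi)) * acos(cop / A) # falling branch, in [0, 50]
  if (direction == "falling") base %% 100 else (100 - base) %% 100
}

#' Build the 100-entry neural-command lookup table
#'
#' Resamples each neural-command column over one sway period at 1% cycle
#' resolution (linear interpolation with periodic wrap-around), giving the
#' 100-samples-per-cycle table the controller indexes in real time.
#'
#' @param H_cycle an [activation_trace()] spanning exactly one sway period
#' @param period the sway period (s); defaults to the trace's time span
#'   extended by one sample step
#' @return a `neural_command_table` with a 100 x K `entries` matrix
#' @export
build_command_table <- function(H_cycle, period = NULL) {
  stopifnot(inherits(H_cycle, "activation_trace"))
  t <- H_cycle$sample_times
  n <- length(t)
  if (n < 2L) stop("H_cycle must contain at least two samples")
  if (is.null(period)) period <- (t[n] - t[1]) * n / (n - 1)
  pct <- 100 * (t - t[1]) / period
  if (any(pct >= 100 + 1e-9)) {
    stop("H_cycle extends beyond one sway period")
  }
  if (max(pct) < 100 - 2 * (100 / n)) {
    stop("H_cycle does not cover a full sway period")
  }
  pct <- pmin(pct, 100 - 1e-12)
  # periodic wrap: duplicate the first sample at 100%
  xs <- c(pct, pct[1] + 100)
  grid <- 0:99
  entries <- apply(H_cycle$commands, 2L, function(col) {
    stats::approx(xs, c(col, col[1]), xout = grid, rule = 2)$y
  })
  entries <- matrix(entries, nrow = 100L, ncol = H_cycle$K)
  colnames(entries) <- colnames(H_cycle$commands)
  structure(list(entries = entries, resolution_percent = 1L, K = H_cycle$K),
            class = "neural_command_table")
}

#' Look up the neural command for a cycle percentage
#'
#' Nearest-entry convention: the table is fixed at 100 discrete samples, so
#' `p` is rounded to the nearest integer percent and wrapped modulo 100.
#'
#' @param table a [build_command_table()] result
#' @param p cycle percentage (any real; wrapped)
#' @return the K-vector of neural commands
#' @export
lookup_command <- function(table, p) {
  idx <- floor(p + 0.5) %% 100
  table$entries[idx + 1L, , drop = TRUE]
}

#' Metronome beat schedule for a sway session
#'
#' The auditory metronome cues the direction reversals of the sway, i.e. the
#' extremes of the reference, so beats fall every half period starting from
#' the first extreme at or after t = 0.
#'
#' @param ref a [sway_reference()]
#' @param duration session duration (s)
#' @return list with `beat_times` (s) and `frequency` (beats/s = 2 * sway f)
#' @export
#' @examples
#' metronome_schedule(sway_reference(10, 0.1), 50)$beat_times # 2.5, 7.5, ...
metronome_schedule <- function(ref, duration) {
  stopifnot(duration > 0)
  half <- 1 / (2 * ref$frequency)
  # percent distance from the start phase to the next extreme (p = 0 or 50)
  d <- (50 - ref$start_cycle_percent %% 50) %% 50
  t1 <- d / (100 * ref$frequency)
  beats <- if (t1 > duration) numeric(0) else seq(t1, duration, by = half)
  list(beat_times = beats, frequency = 2 * ref$frequency)
}
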