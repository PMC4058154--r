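# EMG-envelope reconstruction from the simulated pulse train.
#
# The stimulator output for one channel is a train of narrow current pulses
# whose amplitude follows the synergy model M = H x W x Imax. Low-pass
# filtering the train (a rough model of the skin-muscle system) recovers the
# modulating envelope; comparing it with the theoretical H x W envelope
# validates the whole stimulation chain.

#' Render a channel's pulse train as a densely sampled waveform
#'
#' Rectangular pulses on a uniform grid: sample k (time k/rate) is nonzero iff
#' it falls inside a pulse's \[onset, onset + width) interval. Biphasic pulses
#' are rendered by their absolute amplitude (envelope convention).
#'
#' @param train a [generate_pulse_train()] result
#' @param channel channel id to render
#' @param rate rendering rate (Hz); must be at least 2 * F_t, and 1 kHz
#'   (default) resolves millisecond pulse widths
#' @param duration length of the rendered series (s); default the train's
#' @return list with `t` (s) and `x` (mA), both of length `duration * rate`
#' @export
render_waveform <- function(train, channel, rate = 1000,
                            duration = train$duration) {
  stopifnot(inherits(train, "pulse_train"))
  if (rate < 2 * train$F_t) {
    stop("rendering rate below 2 * F_t would alias the pulse train")
  }
  n <- floor(duration * rate)
  x <- numeric(n)
  pl <- train$pulses[train$pulses$channel == channel, , drop = FALSE]
  if (nrow(pl) > 0) {
    onset <- pl$time
    width <- pl$width_ms / 1000
    j0 <- pmax(ceiling(onset * rate - 1e-9), 0)
    j1 <- pmin(ceiling((onset + width) * rate - 1e-9) - 1, n - 1L)
    for (k in seq_along(onset)) {
      if (j1[k] >= j0[k] && j0[k] < n) {
        x[(j0[k]:min(j1[k], n - 1L)) + 1L] <- abs(pl$amplitude_mA[k])
      }
    }
  }
  list(t = (seq_len(n) - 1L) / rate, x = x)
}

#' Zero-phase Butterworth low-pass envelope filter
#'
#' Forward-backward (zero-phase) Butterworth low-pass. The input is padded on
#' both sides by odd reflection before filtering so that edge transients decay
#' inside the pad rather than contaminating the series; the DC gain is exactly
#' 1 by construction. Defaults (order 4, cutoff 2 Hz) pass the sub-0.5 Hz
#' sway band essentially unattenuated while rejecting a 40 Hz stimulation
#' carrier by more than four orders of magnitude per pass.
#'
#' @param x input series
#' @param rate sample rate (Hz)
#' @param cutoff low-pass cutoff (Hz), must be below the Nyquist rate
#' @param order filter order (per pass)
#' @return filtered series, same length as `x`
#' @export
lowpass_envelope <- function(x, rate, cutoff = 2, order = 4) {
  stopifnot(cutoff > 0, rate > 0, order >= 1)
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  n <- length(x)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # renormalize the numerator so the DC gain is exactly 1 (the designed
  # coefficients carry ~1e-9 rounding)
  bf$b <- bf$b * sum(bf$a) / sum(bf$b)
  pad <- min(n - 1L, ceiling(10 * rate / cutoff))
  # odd reflection about the end points
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  yp <- signal::filtfilt(bf, xp)
  yp[pad + seq_len(n)]
}

#' Compare a reconstructed envelope with the theoretical one
#'
#' Both series are min-max normalized to \[0, 1\]; Pearson correlation and
#' normalized RMSE are computed over the common grid with the first and last
#' `trim_s` seconds excluded (filter settling windows).
#'
#' @param theoretical theoretical envelope series (H x W on the grid)
#' @param filtered filtered pulse-train series on the same grid
#' @param rate common sample rate (Hz)
#' @param trim_s edge exclusion (s) at each end, default 1
#' @return an `envelope_comparison`: normalized series plus `pearson_r` and
#'   `nrmse`; a constant series yields `pearson_r = NA` with a warning
#' @export
compare_envelopes <- function(theoretical, filtered, rate = 1000, trim_s = 1) {
  n <- length(theoretical)
  if (length(filtered) != n) stop("series must share one time grid")
  trim <- floor(trim_s * rate)
  if (2 * trim >= n) stop("trim window longer than the series")
  idx <- seq(trim + 1L, n - trim)
  mm_norm <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(rep(0, length(v)))
    (v - r[1]) / diff(r)
  }
  th <- mm_norm(theoretical[idx])
  fl <- mm_norm(filtered[idx])
  constant <- stats::sd(th) == 0 || stats::sd(fl) == 0
  r <- if (constant) {
    warning("constant series: correlation undefined")
    NA_real_
  } else stats::cor(th, fl)
  structure(list(theoretical = th, filtered = fl,
                 pearson_r = r,
                 nrmse = sqrt(mean((th - fl)^2)),
                 n_used = length(idx), constant_flag = constant),
            class = "envelope_comparison")
}

#' End-to-end envelope reconstruction report for a session
#'
#' For each stimulated channel: renders the session's pulse train, low-pass
#' filters it, evaluates the theoretical envelope m_i(t) = sum_j h_j(p(t))
#' w_ji x Imax on the same grid (commands from the session's lookup table,
#' interpolated linearly and periodically in cycle percentage) and compares
#' the two.
#'
#' @param log a [run_session()] result
#' @param rate rendering rate (Hz), default 1000
#' @param cutoff,order Butterworth parameters, see [lowpass_envelope()]
#' @param trim_s edge exclusion for the comparison (s)
#' @return list with `per_channel` (data.frame: channel, muscle, pearson_r,
#'   nrmse) and `comparisons` (list of [compare_envelopes()] results, named by
#'   channel id)
#' @export
envelope_report <- function(log, rate = 1000, cutoff = 2, order = 4,
                            trim_s = 1) {
  stopifnot(inherits(log, "session_log"))
  config <- log$config
  grid_n <- floor(log$duration * rate)
  tgrid <- (seq_len(grid_n) - 1L) / rate
  pgrid <- cycle_percent_at(config$sway, tgrid)
  # continuous theoretical command: periodic linear interpolation of the table
  tab <- config$command_table$entries
  xs <- c(0:99, 100)
  hx <- rbind(tab, tab[1, , drop = FALSE])
  Hdense <- vapply(seq_len(ncol(tab)), function(j) {
    stats::approx(xs, hx[, j], xout = pgrid)$y
  }, numeric(grid_n))
  wm <- config$W$weights
  act <- pmin(pmax(Hdense %*% wm, 0), 1) # T x N muscle activations
  ids <- vapply(config$channels, function(ch) ch$channel_id, integer(1))
  rows <- list(); comps <- list()
  for (i in seq_along(config$channel_map)) {
    id <- config$channel_map[i]
    imax <- config$channels[[which(ids == id)]]$I_max
    theo <- act[, i] * imax
    wf <- render_waveform(log$pulse_train, id, rate = rate,
                          duration = log$duration)
    filt <- lowpass_envelope(wf$x, rate = rate, cutoff = cutoff, order = order)
    cmp <- compare_envelopes(theo, filt, rate = rate, trim_s = trim_s)
    rows[[i]] <- data.frame(channel = id, muscle = i,
                            pearson_r = cmp$pearson_r, nrmse = cmp$nrmse)
    comps[[as.character(id)]] <- cmp
  }
  list(per_channel = do.call(rbind, rows), comparisons = comps)
}
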