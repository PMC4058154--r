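# Probabilistic timing analysis of synergy-update periods.
#
# A soft-real-time host refreshes the stimulator's synergy parameters at a
# nominal period T_sE but the realized periods T_s are random. The stimulator
# tolerates updates within one stimulation period T_t of the expected time,
# so the quantities of interest are P(T_s <= T_sE + T_t) (update arrives
# before a further stimulation period elapses), P(T_s <= T_sE - T_t) (update
# arrives a full stimulation period early) and their difference, the mass
# inside the tolerance window.

#' A record of synergy-update periods
#'
#' @param periods_ms measured or simulated update periods (ms), > 0
#' @param T_sE expected period (ms)
#' @param T_t stimulation period (ms), default 25 (40 Hz stimulation)
#' @param source `"simulated"` or `"imported"`
#' @return a `timing_record` object
#' @export
timing_record <- function(periods_ms, T_sE, T_t = 25,
                          source = c("simulated", "imported")) {
  source <- match.arg(source)
  stopifnot(all(periods_ms > 0), T_sE > 0, T_t > 0)
  structure(list(periods_ms = as.numeric(periods_ms), T_sE = T_sE, T_t = T_t,
                 source = source),
            class = "timing_record")
}

#' Simulate synergy-update periods under a jitter model
#'
#' Draws n periods as T_sE plus additive jitter. The default model is a
#' zero-mean truncated normal with sigma = 8 ms, truncated at +/- 3 sigma — a
#' parametric stand-in for the scheduling noise of a non-real-time operating
#' system.
#'
#' @param T_sE expected period (ms)
#' @param jitter a [jitter_model()]
#' @param n number of periods
#' @param seed integer seed
#' @param T_t stimulation period (ms) stored on the record
#' @return a [timing_record()]
#' @export
simulate_periods <- function(T_sE, jitter = jitter_model("truncnorm", sigma_ms = 8),
                             n = 2000L, seed = 1L, T_t = 25) {
  stopifnot(n >= 1L)
  periods <- T_sE + with_seed(seed, draw_period_jitter(jitter, n))
  timing_record(periods, T_sE = T_sE, T_t = T_t, source = "simulated")
}

#' Empirical CDF of the update periods
#'
#' Right-continuous ECDF, F(x) = P(T_s <= x), matching the "less than or
#' equal" convention of the tolerance probabilities.
#'
#' @param record a [timing_record()]
#' @return a step function of class `ecdf`
#' @export
empirical_cdf <- function(record) {
  if (length(record$periods_ms) == 0) stop("empty timing record")
  stats::ecdf(record$periods_ms)
}

#' Tolerance-window probabilities of the update periods
#'
#' @param record a [timing_record()]
#' @param T_t tolerance half-width (ms); defaults to the record's T_t
#' @return list with `p_upper` = P(T_s <= T_sE + T_t), `p_lower` =
#'   P(T_s <= T_sE - T_t) and `p_window = p_upper - p_lower`
#' @export
#' @examples
#' rec <- timing_record(c(40, 50, 60, 80), T_sE = 50, T_t = 25)
#' tolerance_probabilities(rec) # p_upper 0.75, p_lower 0, window 0.75
tolerance_probabilities <- function(record, T_t = record$T_t) {
  x <- record$periods_ms
  p_upper <- mean(x <= record$T_sE + T_t)
  p_lower <- mean(x <= record$T_sE - T_t)
  list(p_upper = p_upper, p_lower = p_lower, p_window = p_upper - p_lower)
}

#' Summary table of tolerance probabilities across update frequencies
#'
#' @param records list of [timing_record()] (typically one per update
#'   frequency, e.g. T_sE = 1000, 200, 100, 50 ms)
#' @return data.frame: T_sE_ms, F_sE_Hz, n, p_upper, p_lower, p_window
#' @export
timing_report <- function(records) {
  if (length(records) == 0) {
    warning("no timing records supplied; empty report")
    return(data.frame(T_sE_ms = numeric(0), F_sE_Hz = numeric(0),
                      n = integer(0), p_upper = numeric(0),
                      p_lower = numeric(0), p_window = numeric(0)))
  }
  rows <- lapply(records, function(rec) {
    p <- tolerance_probabilities(rec)
    data.frame(T_sE_ms = rec$T_sE, F_sE_Hz = 1000 / rec$T_sE,
               n = length(rec$periods_ms),
               p_upper = p$p_upper, p_lower = p$p_lower,
               p_window = p$p_window)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read externally measured update periods from a one-column CSV (ms)
#'
#' @param path CSV path; a single numeric column of periods in ms (header
#'   optional)
#' @param T_sE expected period (ms)
#' @param T_t stimulation period (ms)
#' @return a [timing_record()] with source `"imported"`
#' @export
read_timing_csv <- function(path, T_sE, T_t = 25) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1)
  header <- is.na(suppressWarnings(as.numeric(first[[1]])))
  x <- utils::read.csv(path, header = header)[[1]]
  timing_record(as.numeric(x), T_sE = T_sE, T_t = T_t, source = "imported")
}
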