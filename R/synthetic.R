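# Synthetic-data generators: sway-locked neural commands, block-structured
# synergy matrices, noisy EMG envelopes and the default validation session.
#
# Study conditions emulated: three neural modules driving eight stimulated
# muscles, a 10 cm / 0.1 Hz sinusoidal sway reference, 40 Hz stimulation,
# 20 Hz synergy updates, 50 s sessions.

#' Specification for the synthetic generators
#'
#' Commands are raised-cosine bumps locked to the sway cycle: module j peaks
#' at `centers[j]` percent with full width `widths[j]` percent and is zero
#' outside its bump. Defaults place the K bumps evenly over the cycle with
#' disjoint supports (width 100/K), which keeps the factorization
#' identifiable.
#'
#' @param K number of modules (default 3)
#' @param N number of muscles (default 8), N >= K
#' @param period sway period (s), default 10 (0.1 Hz)
#' @param centers bump centers (% of cycle), length K
#' @param widths bump full widths (% of cycle), length K, > 0
#' @param noise_sigma EMG noise sigma as a fraction of the signal maximum
#' @param seed integer seed
#' @param samples_per_period samples over one period (>= 400 by default)
#' @return a `generator_spec` object
#' @export
generator_spec <- function(K = 3L, N = 8L, period = 10,
                           centers = (seq_len(K) - 0.5) * 100 / K,
                           widths = rep(100 / K, K),
                           noise_sigma = 0.05, seed = 42L,
                           samples_per_period = 400L) {
  stopifnot(K >= 1L, N >= K, period > 0, length(centers) == K,
            length(widths) == K, noise_sigma >= 0, samples_per_period >= 2L)
  if (any(widths <= 0)) stop("degenerate zero-width command bump")
  structure(list(K = as.integer(K), N = as.integer(N), period = period,
                 centers = centers, widths = widths,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 samples_per_period = as.integer(samples_per_period)),
            class = "generator_spec")
}

#' Raised-cosine command bump as a function of cycle percentage
#'
#' 0.5 * (1 + cos(2 pi d / width)) for circular distance |d| <= width/2 from
#' the center, zero elsewhere; peak value 1 at the center.
#'
#' @param p cycle percentage, vectorized (any real; treated modulo 100)
#' @param center bump center (%)
#' @param width bump full width (%)
#' @return command values in \[0, 1\]
#' @export
raised_cosine_bump <- function(p, center, width) {
  stopifnot(width > 0)
  d <- ((p - center + 50) %% 100) - 50
  ifelse(abs(d) <= width / 2, 0.5 * (1 + cos(2 * pi * d / width)), 0)
}

#' Simulate sway-locked neural commands over one period
#'
#' @param spec a [generator_spec()]
#' @return an [activation_trace()] of dimension `samples_per_period` x K
#' @export
simulate_neural_commands <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$samples_per_period
  p <- (seq_len(n) - 1L) / n * 100
  H <- vapply(seq_len(spec$K), function(j) {
    raised_cosine_bump(p, spec$centers[j], spec$widths[j])
  }, numeric(n))
  H <- matrix(H, ncol = spec$K,
              dimnames = list(NULL, paste0("module_", seq_len(spec$K))))
  activation_trace(H, sample_times = p / 100 * spec$period)
}

#' Simulate a block-structured synergy matrix
#'
#' Muscles are partitioned into K contiguous blocks; each module dominates its
#' own block (weights drawn in \[0.7, 1\]) with small cross-talk elsewhere
#' (\[0, 0.15\]). Rows are normalized to unit maximum. The disjoint dominant
#' blocks make the factorization identifiable, so NNMF recovers the matrix
#' from noiseless data up to permutation.
#'
#' @param spec a [generator_spec()]
#' @return a [synergy_matrix()] of dimension K x N
#' @export
simulate_synergy_matrix <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  K <- spec$K; N <- spec$N
  owner <- ceiling(seq_len(N) * K / N) # module owning each muscle
  W <- with_seed(spec$seed, {
    w <- matrix(stats::runif(K * N, 0, 0.15), K, N)
    for (i in seq_len(N)) w[owner[i], i] <- stats::runif(1, 0.7, 1)
    w
  })
  W <- W / apply(W, 1L, max)
  synergy_matrix(W)
}

#' Simulate a noisy EMG envelope matrix from commands and synergies
#'
#' M = H W plus additive Gaussian noise with sigma = `noise_sigma` times the
#' maximum of the clean signal, clipped at zero to preserve nonnegativity.
#'
#' @param H an [activation_trace()]
#' @param W a [synergy_matrix()]
#' @param noise_sigma noise fraction (of max(H W))
#' @param seed integer seed
#' @return a [muscle_activations()]
#' @export
simulate_emg <- function(H, W, noise_sigma = 0.05, seed = 42L) {
  M0 <- reconstruct_activations(H, W)
  vals <- M0$values
  if (noise_sigma > 0) {
    noise <- with_seed(seed, {
      matrix(stats::rnorm(length(vals), 0, noise_sigma * max(vals)),
             nrow(vals), ncol(vals))
    })
    vals <- pmax(vals + noise, 0)
  }
  muscle_activations(vals, M0$sample_times)
}

#' Default validation session configuration
#'
#' The standard end-to-end fixture: 3 modules, 8 muscles, a 10 cm / 0.1 Hz
#' mediolateral sway reference starting at 75% of the cycle, stimulation at
#' 40 Hz, synergy updates at 20 Hz, 50 s duration, identity channel map
#' (muscle i drives channel i - 1) and Imax = 50 mA on every channel.
#'
#' @param seed integer seed (default 42)
#' @param duration session length (s), default 50
#' @param jitter controller-tick [jitter_model()]; default truncated normal,
#'   sigma 8 ms
#' @param quantization_step DAC step (mA); 0 disables quantization
#' @return a [session_config()]
#' @export
#' @examples
#' cfg <- default_session_fixture(seed = 1)
#' cfg$F_t; cfg$duration
default_session_fixture <- function(seed = 42L, duration = 50,
                                    jitter = jitter_model("truncnorm", sigma_ms = 8),
                                    quantization_step = STIM_QUANT_STEP_MA) {
  spec <- generator_spec(K = 3L, N = 8L, period = 10, seed = seed)
  Hc <- simulate_neural_commands(spec)
  W <- simulate_synergy_matrix(spec)
  sway <- sway_reference(amplitude = 10, frequency = 0.1, axis = "ML",
                         start_cycle_percent = 75)
  channels <- lapply(0:7, stim_channel_config, I_max = 50, pulse_width_ms = 1)
  session_config(
    sway = sway,
    command_table = build_command_table(Hc, period = spec$period),
    W = W, channel_map = 0:7, channels = channels,
    F_t = 40, F_s = 20, duration = duration,
    jitter = jitter, seed = seed, stim_mode = "continuous",
    quantization_step = quantization_step
  )
}
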