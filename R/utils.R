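# Internal helpers shared across modules.

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Truncated normal deviates by inverse-CDF sampling
#'
#' @param n number of draws
#' @param mean,sd normal parameters
#' @param lower,upper truncation bounds (absolute, same units as `mean`)
#' @keywords internal
#' @noRd
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Construct a jitter model description
#'
#' Jitter models parameterize the random deviation of soft-real-time periods
#' (controller ticks, synergy updates) or of force-plate inter-sample
#' intervals. `"none"` is deterministic; `"truncnorm"` is additive
#' zero-mean truncated-normal noise in milliseconds (the default stand-in for
#' a non-real-time operating system scheduler); `"gamma"` draws whole
#' inter-sample intervals from a Gamma distribution with the given shape and a
#' mean fixed by the consumer (used by the force-plate stream).
#'
#' @param name one of `"none"`, `"truncnorm"`, `"gamma"`
#' @param sigma_ms standard deviation in ms (truncnorm)
#' @param trunc_sd truncation in units of `sigma_ms` (truncnorm)
#' @param shape Gamma shape parameter (gamma)
#' @return a `jitter_model` list
#' @export
#' @examples
#' jitter_model("truncnorm", sigma_ms = 8)
jitter_model <- function(name = c("none", "truncnorm", "gamma"),
                         sigma_ms = 8, trunc_sd = 3, shape = 25) {
  name <- match.arg(name)
  stopifnot(sigma_ms >= 0, trunc_sd > 0, shape > 0)
  structure(list(name = name, sigma_ms = sigma_ms, trunc_sd = trunc_sd,
                 shape = shape),
            class = "jitter_model")
}

# Additive period jitter in milliseconds. RNG must already be seeded by the
# caller; returns zeros for the "none" model.
draw_period_jitter <- function(model, n) {
  switch(model$name,
    none = rep(0, n),
    truncnorm = rtruncnorm(n, 0, model$sigma_ms,
                           lower = -model$trunc_sd * model$sigma_ms,
                           upper = model$trunc_sd * model$sigma_ms),
    gamma = stats::rgamma(n, shape = model$shape,
                          scale = model$sigma_ms / model$shape) - model$sigma_ms,
    stop("unknown jitter model: ", model$name)
  )
}

# Inter-sample intervals (seconds) with target mean `mean_s`.
draw_intervals <- function(model, n, mean_s) {
  switch(model$name,
    none = rep(mean_s, n),
    gamma = stats::rgamma(n, shape = model$shape, scale = mean_s / model$shape),
    truncnorm = mean_s + rtruncnorm(n, 0, model$sigma_ms / 1000,
                                    lower = -model$trunc_sd * model$sigma_ms / 1000,
                                    upper = model$trunc_sd * model$sigma_ms / 1000),
    stop("unknown jitter model: ", model$name)
  )
}

# Stop unless all entries of x are finite and nonnegative.
assert_nonneg <- function(x, what) {
  if (!all(is.finite(x)) || any(x < 0)) {
    stop(what, " must be finite and nonnegative", call. = FALSE)
  }
  invisible(x)
}
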