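# Muscle-synergy model: m_i(t) = sum_j h_j(t) w_ji, i.e. M = H %*% W with
# M (T x N) muscle activations, H (T x K) neural commands and W (K x N)
# nonnegative synergy weights.

#' Synergy weight matrix
#'
#' A `synergy_matrix` holds the K x N nonnegative matrix W whose row j gives
#' the relative contribution of synergy module j to each of N muscles.
#'
#' @param weights numeric K x N matrix, entries >= 0
#' @param muscle_labels optional character vector of N muscle names
#' @return a `synergy_matrix` object
#' @export
#' @examples
#' synergy_matrix(rbind(c(1, 0.2, 0), c(0, 0.5, 1)))
synergy_matrix <- function(weights, muscle_labels = NULL) {
  weights <- as.matrix(weights)
  assert_nonneg(weights, "synergy weights")
  if (nrow(weights) < 1L || ncol(weights) < 1L) stop("W must be at least 1 x 1")
  if (is.null(muscle_labels)) {
    muscle_labels <- colnames(weights)
    if (is.null(muscle_labels)) {
      muscle_labels <- paste0("muscle_", seq_len(ncol(weights)))
    }
  }
  stopifnot(length(muscle_labels) == ncol(weights))
  colnames(weights) <- muscle_labels
  rownames(weights) <- paste0("module_", seq_len(nrow(weights)))
  structure(list(weights = weights, K = nrow(weights), N = ncol(weights),
                 muscle_labels = muscle_labels),
            class = "synergy_matrix")
}

#' Neural-command trace
#'
#' An `activation_trace` holds the T x K matrix H of time-varying neural
#' commands h_j(t), one column per synergy module, sampled at strictly
#' increasing times.
#'
#' @param commands numeric T x K matrix, entries >= 0
#' @param sample_times numeric vector of T strictly increasing times (s)
#' @return an `activation_trace` object
#' @export
activation_trace <- function(commands, sample_times = NULL) {
  commands <- as.matrix(commands)
  assert_nonneg(commands, "neural commands")
  if (is.null(sample_times)) sample_times <- seq_len(nrow(commands)) - 1
  stopifnot(length(sample_times) == nrow(commands))
  if (nrow(commands) > 1L && any(diff(sample_times) <= 0)) {
    stop("sample_times must be strictly increasing")
  }
  structure(list(commands = commands, sample_times = as.numeric(sample_times),
                 K = ncol(commands)),
            class = "activation_trace")
}

#' Muscle-activation matrix
#'
#' Container for the T x N matrix M of (envelope) muscle activations.
#'
#' @param values numeric T x N matrix
#' @param sample_times numeric vector of T strictly increasing times (s)
#' @return a `muscle_activations` object
#' @export
muscle_activations <- function(values, sample_times = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("activations must be finite")
  if (is.null(sample_times)) sample_times <- seq_len(nrow(values)) - 1
  stopifnot(length(sample_times) == nrow(values))
  if (nrow(values) > 1L && any(diff(sample_times) <= 0)) {
    stop("sample_times must be strictly increasing")
  }
  structure(list(values = values, sample_times = as.numeric(sample_times),
                 N = ncol(values)),
            class = "muscle_activations")
}

as_matrix_input <- function(x) {
  if (inherits(x, "muscle_activations")) x$values
  else if (inherits(x, "activation_trace")) x$commands
  else as.matrix(x)
}

#' Reconstruct muscle activations from commands and synergies
#'
#' Forward synergy model: M\[t, i\] = sum_j H\[t, j\] * W\[j, i\].
#'
#' @param H an [activation_trace()] (or T x K matrix)
#' @param W a [synergy_matrix()] (or K x N matrix)
#' @return a [muscle_activations()] of dimension T x N
#' @export
#' @examples
#' H <- activation_trace(cbind(c(1, 0), c(2, 1)))
#' W <- synergy_matrix(rbind(c(1, 0, 2), c(3, 1, 0)))
#' reconstruct_activations(H, W)$values
reconstruct_activations <- function(H, W) {
  hm <- as_matrix_input(H)
  wm <- if (inherits(W, "synergy_matrix")) W$weights else as.matrix(W)
  if (ncol(hm) != nrow(wm)) {
    stop(sprintf("shape mismatch: H has %d modules but W has %d rows",
                 ncol(hm), nrow(wm)))
  }
  times <- if (inherits(H, "activation_trace")) H$sample_times else NULL
  muscle_activations(hm %*% wm, times)
}

#' Variance accounted for by a synergy factorization
#'
#' Global VAF = 1 - ||M - H W||_F^2 / ||M||_F^2, plus the per-muscle
#' (per-column) analogue. The reported `vaf` and `per_muscle_vaf` are clipped
#' to \[0, 1\]; `vaf_raw` keeps the unclipped value (which can be negative for
#' a factorization worse than the zero model).
#'
#' @param M observed [muscle_activations()] (or matrix)
#' @param H [activation_trace()] (or matrix) of commands
#' @param W [synergy_matrix()] (or matrix) of weights
#' @return list with `vaf`, `vaf_raw`, `per_muscle_vaf`, `K_used`
#' @export
compute_vaf <- function(M, H, W) {
  mm <- as_matrix_input(M)
  hm <- as_matrix_input(H)
  wm <- if (inherits(W, "synergy_matrix")) W$weights else as.matrix(W)
  if (ncol(hm) != nrow(wm) || nrow(hm) != nrow(mm) || ncol(wm) != ncol(mm)) {
    stop("inconsistent dimensions among M, H and W")
  }
  tot <- sum(mm^2)
  if (tot == 0) stop("M has zero norm: VAF is undefined for an all-zero signal")
  resid <- mm - hm %*% wm
  vaf_raw <- 1 - sum(resid^2) / tot
  col_tot <- colSums(mm^2)
  per_raw <- ifelse(col_tot > 0, 1 - colSums(resid^2) / col_tot, NA_real_)
  list(vaf = min(max(vaf_raw, 0), 1),
       vaf_raw = vaf_raw,
       per_muscle_vaf = pmin(pmax(per_raw, 0), 1),
       K_used = ncol(hm))
}

#' Choose the number of synergy modules by a VAF threshold
#'
#' Extracts factorizations at K = 1, 2, ... and returns the smallest K whose
#' best-of-restarts global VAF reaches `vaf_threshold`. In rhythmic-sway EMG,
#' two modules typically explain more than 90% of the variance, so the usual
#' threshold is 0.90.
#'
#' @param M nonnegative [muscle_activations()] (or matrix)
#' @param vaf_threshold required VAF fraction in \[0, 1)
#' @param seed integer seed controlling all NNMF restarts
#' @param restarts random restarts per K (best objective kept)
#' @param max_K largest K to try (default `min(T, N)`)
#' @param ... further arguments for [extract_synergies()]
#' @return list with `K` (selected count), `reached` (logical; `FALSE` means
#'   even `max_K` missed the threshold and `K = max_K` is returned flagged),
#'   and `vaf_curve`, a data.frame of K vs best VAF
#' @export
select_module_count <- function(M, vaf_threshold = 0.90, seed = 1L,
                                restarts = 20L, max_K = NULL, ...) {
  mm <- as_matrix_input(M)
  if (vaf_threshold < 0 || vaf_threshold >= 1) {
    stop("vaf_threshold must lie in [0, 1)")
  }
  if (is.null(max_K)) max_K <- min(dim(mm))
  ks <- integer(0); vafs <- numeric(0)
  for (K in seq_len(max_K)) {
    fit <- extract_synergies(M, K = K, seed = seed, restarts = restarts, ...)
    ks <- c(ks, K); vafs <- c(vafs, fit$vaf$vaf)
    if (fit$vaf$vaf >= vaf_threshold) {
      return(list(K = K, reached = TRUE,
                  vaf_curve = data.frame(K = ks, vaf = vafs)))
    }
  }
  list(K = max_K, reached = FALSE, vaf_curve = data.frame(K = ks, vaf = vafs))
}
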