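# Shared fixtures and independent oracles used across test files.

# Element-wise triple-loop matrix product: the brute-force oracle for the
# synergy forward model.
matmul_oracle <- function(H, W) {
  Tn <- nrow(H); K <- ncol(H); N <- ncol(W)
  M <- matrix(0, Tn, N)
  for (t in seq_len(Tn)) {
    for (i in seq_len(N)) {
      s <- 0
      for (j in seq_len(K)) s <- s + H[t, j] * W[j, i]
      M[t, i] <- s
    }
  }
  M
}

# VAF by direct element-wise summation.
vaf_oracle <- function(M, H, W) {
  R <- M - matmul_oracle(H, W)
  ss_res <- 0; ss_tot <- 0
  for (t in seq_len(nrow(M))) {
    for (i in seq_len(ncol(M))) {
      ss_res <- ss_res + R[t, i]^2
      ss_tot <- ss_tot + M[t, i]^2
    }
  }
  1 - ss_res / ss_tot
}

# Nearest lattice multiple by brute-force enumeration over k = 0..191,
# restricted to multiples not exceeding I_max.
quantize_oracle <- function(x, I_max, step = 0.7827) {
  ks <- 0:191
  ks <- ks[ks * step <= I_max + 1e-12]
  cand <- ks * step
  cand[which.min(abs(cand - x))]
}

# Best cosine similarity matching of recovered synergy rows to ground truth
# (greedy over the K! permutations for small K).
row_cosine_match <- function(W_hat, W0) {
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  K <- nrow(W0)
  perms <- if (K == 1) list(1) else
    unlist(lapply(combinat_perms(K), list), recursive = FALSE)
  best <- -Inf
  for (p in perms) {
    sims <- vapply(seq_len(K), function(j) cs(W_hat[p[j], ], W0[j, ]), 1)
    if (min(sims) > best) best <- min(sims)
  }
  best
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in combinat_perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, ifelse(rest >= i, rest + 1L, rest))
    }
  }
  out
}

make_recovery_problem <- function(K = 2L, N = 8L, samples = 200L,
                                  noise = 0, seed = 7L) {
  spec <- generator_spec(K = K, N = N, samples_per_period = samples,
                         noise_sigma = noise, seed = seed)
  H0 <- simulate_neural_commands(spec)
  W0 <- simulate_synergy_matrix(spec)
  list(spec = spec, H0 = H0, W0 = W0,
       M = simulate_emg(H0, W0, noise_sigma = noise, seed = seed))
}

fast_session <- function(seed = 1L, duration = 10,
                         jitter = jitter_model("none"), ...) {
  default_session_fixture(seed = seed, duration = duration, jitter = jitter,
                          ...)
}
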