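# Nonnegative matrix factorization by multiplicative updates (Lee-Seung,
# Frobenius objective). Small dense problems only: sway-EMG envelopes are a
# few hundred samples by a handful of muscles.

nmf_multiplicative <- function(M, K, max_iter = 2000L, tol = 1e-6) {
  Tn <- nrow(M); N <- ncol(M)
  eps <- .Machine$double.eps
  scale <- sqrt(mean(M) / K + eps)
  H <- matrix(stats::runif(Tn * K, eps, 1), Tn, K) * scale
  W <- matrix(stats::runif(K * N, eps, 1), K, N) * scale
  obj_old <- sum((M - H %*% W)^2)
  for (it in seq_len(max_iter)) {
    W <- W * crossprod(H, M) / (crossprod(H) %*% W + eps)
    H <- H * (M %*% t(W)) / (H %*% tcrossprod(W) + eps)
    if (it %% 10L == 0L || it == max_iter) {
      obj <- sum((M - H %*% W)^2)
      if (abs(obj_old - obj) <= tol * max(obj_old, eps)) {
        obj_old <- obj
        break
      }
      obj_old <- obj
    }
  }
  list(H = H, W = W, objective = obj_old)
}

# Resolve the scale indeterminacy of H %*% W: scale each synergy row of W to
# unit maximum and rescale the paired column of H to compensate. All-zero
# rows are left untouched.
normalize_row_max <- function(H, W) {
  rmax <- apply(W, 1L, max)
  sc <- ifelse(rmax > 0, rmax, 1)
  W <- W / sc
  H <- sweep(H, 2L, sc, `*`)
  list(H = H, W = W)
}

#' Extract muscle synergies from an activation matrix by NNMF
#'
#' Factorizes a nonnegative T x N activation matrix as M ~ H W with H (T x K)
#' and W (K x N) nonnegative, minimizing the Frobenius reconstruction error by
#' multiplicative updates. The factorization is run from `restarts` random
#' initializations and the best objective is kept, then normalized so every
#' synergy row of W has unit maximum (H rescaled to compensate). Deterministic
#' for a given `seed`.
#'
#' @param M nonnegative [muscle_activations()] (or T x N matrix)
#' @param K number of synergy modules, 1 <= K <= min(T, N)
#' @param seed integer seed for the random initializations
#' @param restarts number of random restarts (default 20)
#' @param max_iter maximum multiplicative-update iterations per restart
#' @param tol relative objective-change convergence tolerance
#' @return list with `H` ([activation_trace()]), `W` ([synergy_matrix()]),
#'   `vaf` (the [compute_vaf()] result for the returned pair) and `objective`
#' @export
#' @examples
#' W0 <- rbind(c(1, 0.1, 0, 0), c(0, 0, 1, 0.4))
#' H0 <- cbind(abs(sin(seq(0, pi, length.out = 50))),
#'             abs(cos(seq(0, pi, length.out = 50))))
#' fit <- extract_synergies(H0 %*% W0, K = 2, seed = 1, restarts = 5)
#' fit$vaf$vaf
extract_synergies <- function(M, K, seed = 1L, restarts = 20L,
                              max_iter = 2000L, tol = 1e-6) {
  mm <- as_matrix_input(M)
  if (any(mm < 0)) stop("M must be nonnegative for NNMF")
  if (K < 1L || K > min(dim(mm))) stop("K must satisfy 1 <= K <= min(T, N)")
  stopifnot(restarts >= 1L)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- nmf_multiplicative(mm, K, max_iter = max_iter, tol = tol)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  norm <- normalize_row_max(best$H, best$W)
  times <- if (inherits(M, "muscle_activations")) M$sample_times else NULL
  labels <- if (inherits(M, "muscle_activations")) colnames(mm) else colnames(mm)
  H <- activation_trace(norm$H, times)
  W <- synergy_matrix(norm$W, muscle_labels = labels)
  list(H = H, W = W, vaf = compute_vaf(mm, norm$H, norm$W),
       objective = best$objective)
}
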