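test_that("reconstruction matches the element-wise triple-loop oracle", {
  H <- rbind(c(1, 2), c(0, 1))
  W <- rbind(c(1, 0, 2), c(3, 1, 0))
  M <- reconstruct_activations(activation_trace(H), synergy_matrix(W))
  expect_equal(M$values, matmul_oracle(H, W), ignore_attr = TRUE)
  expect_equal(unname(M$values), rbind(c(7, 2, 2), c(3, 1, 0)))

  set.seed(11)
  for (rep in 1:5) {
    H <- matrix(runif(30), 6, 5)
    W <- matrix(runif(20), 5, 4)
    M <- reconstruct_activations(H, W)
    expect_equal(unname(M$values), matmul_oracle(H, W), tolerance = 1e-12)
  }
})

test_that("reconstruction handles degenerate inputs and shape errors", {
  W <- synergy_matrix(matrix(runif(8), 2, 4))
  Hz <- activation_trace(matrix(0, 10, 2))
  expect_true(all(reconstruct_activations(Hz, W)$values == 0))
  # K = 1, constant unit command: every row of M equals W's single row
  H1 <- activation_trace(matrix(1, 5, 1))
  W1 <- synergy_matrix(matrix(c(0.2, 0.5, 1), 1, 3))
  M1 <- reconstruct_activations(H1, W1)
  for (t in 1:5) expect_equal(unname(M1$values[t, ]), c(0.2, 0.5, 1))
  expect_error(reconstruct_activations(matrix(1, 3, 2), matrix(1, 3, 4)),
               "shape mismatch")
})

test_that("VAF agrees with the direct summation oracle", {
  # hand example: M all ones, reconstruction hits half the entries
  M <- rbind(c(1, 1), c(1, 1))
  H <- rbind(c(1), c(1))
  W <- matrix(c(1, 0), 1, 2)
  v <- compute_vaf(M, H, W)
  expect_equal(v$vaf, 0.5)
  set.seed(22)
  for (rep in 1:5) {
    H <- matrix(runif(24), 8, 3)
    W <- matrix(runif(12), 3, 4)
    M <- matmul_oracle(H, W) + matrix(rnorm(32, 0, 0.1), 8, 4)
    v <- compute_vaf(M, H, W)
    expect_equal(v$vaf_raw, vaf_oracle(M, H, W), tolerance = 1e-10)
  }
})

test_that("VAF is 1 for exact reconstruction, 0 for the null model, errors on zero M", {
  H <- matrix(runif(20), 10, 2)
  W <- matrix(runif(6), 2, 3)
  M <- H %*% W
  expect_equal(compute_vaf(M, H, W)$vaf, 1)
  expect_equal(compute_vaf(M, matrix(0, 10, 2), W)$vaf, 0)
  expect_error(compute_vaf(matrix(0, 4, 2), matrix(0, 4, 1), matrix(0, 1, 2)),
               "zero norm")
})

test_that("NNMF recovers a noiseless planted factorization", {
  prob <- make_recovery_problem(K = 2, noise = 0, seed = 7)
  fit <- extract_synergies(prob$M, K = 2, seed = 7, restarts = 10)
  expect_gte(fit$vaf$vaf, 0.999)
  expect_true(all(fit$H$commands >= 0))
  expect_true(all(fit$W$weights >= 0))
  # row-max normalization convention
  expect_equal(unname(apply(fit$W$weights, 1, max)), c(1, 1))
  expect_gte(row_cosine_match(fit$W$weights, prob$W0$weights), 0.95)
  # K0 = 3 as well
  prob3 <- make_recovery_problem(K = 3, noise = 0, seed = 9)
  fit3 <- extract_synergies(prob3$M, K = 3, seed = 9, restarts = 10)
  expect_gte(row_cosine_match(fit3$W$weights, prob3$W0$weights), 0.95)
})

test_that("NNMF is deterministic under a seed and rejects invalid input", {
  prob <- make_recovery_problem(K = 2, noise = 0.05, seed = 5)
  f1 <- extract_synergies(prob$M, K = 2, seed = 31, restarts = 3)
  f2 <- extract_synergies(prob$M, K = 2, seed = 31, restarts = 3)
  expect_identical(f1$W$weights, f2$W$weights)
  expect_identical(f1$H$commands, f2$H$commands)
  Mneg <- prob$M$values; Mneg[1, 1] <- -1
  expect_error(extract_synergies(Mneg, K = 2, seed = 1), "nonnegative")
  expect_error(extract_synergies(prob$M, K = 0, seed = 1), "K must")
})

test_that("best-of-restarts VAF is non-decreasing in K", {
  prob <- make_recovery_problem(K = 2, noise = 0.1, seed = 13)
  vafs <- vapply(1:4, function(K) {
    extract_synergies(prob$M, K = K, seed = 13, restarts = 5)$vaf$vaf
  }, numeric(1))
  expect_true(all(diff(vafs) >= -1e-6))
})

test_that("a silent muscle gets a near-zero synergy column", {
  prob <- make_recovery_problem(K = 2, N = 6, noise = 0, seed = 3)
  M <- prob$M$values
  M[, 4] <- 0
  fit <- extract_synergies(M, K = 2, seed = 3, restarts = 5)
  # a zero column contributes nothing to the objective, so the optimum puts
  # (numerically) no weight there
  expect_lt(max(fit$W$weights[, 4]), 1e-3)
  recon <- fit$H$commands %*% fit$W$weights
  expect_lt(max(abs(recon[, 4])), 1e-3)
})

test_that("module-count selection finds the planted K and honors edge cases", {
  prob <- make_recovery_problem(K = 2, noise = 0.05, seed = 7)
  sel <- select_module_count(prob$M, 0.90, seed = 7, restarts = 10)
  expect_identical(sel$K, 2L)
  expect_true(sel$reached)
  expect_equal(nrow(sel$vaf_curve), 2)
  # vacuous threshold: one module always suffices
  expect_identical(select_module_count(prob$M, 0, seed = 1, restarts = 2)$K, 1L)
  # rank-1 generator recovered at K = 1
  h <- abs(sin(seq(0, pi, length.out = 60)))
  w <- c(1, 0.4, 0.7, 0.1)
  M1 <- outer(h, w)
  sel1 <- select_module_count(M1, 0.99, seed = 2, restarts = 5)
  expect_identical(sel1$K, 1L)
  expect_error(select_module_count(prob$M, 1.0, seed = 1), "vaf_threshold")
})
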