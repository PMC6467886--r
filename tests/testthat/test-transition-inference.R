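test_that("principal root recovers the daily chain from powered matrices", {
  # identity is its own root
  I4 <- diag(4); dimnames(I4) <- list(paste0("P", 1:4), paste0("P", 1:4))
  r <- estimate_root(I4, I4, n = 7)
  expect_equal(unname(r$values), diag(4), tolerance = 1e-12)

  # 2-state worked example: root of the squared chain
  P <- two_state_chain()
  W2 <- naive_power(P, 2)
  expect_equal(unname(W2), matrix(c(0.83, 0.17, 0.34, 0.66), 2, byrow = TRUE))
  est <- regularize(estimate_root(diag(2), W2, 2))
  expect_lt(max(abs(est - P)), 1e-10)
})

test_that("root estimation oracle: random chains recovered across depths", {
  # oracle: the candidate root powered back must reproduce Wn
  for (seed in 1:8) {
    K <- sample(2:6, 1)
    P <- random_reversible_chain(K, seed)
    for (n in c(2, 5, 13, 30)) {
      Wn <- naive_power(P, n)
      est <- regularize(estimate_root(diag(K), Wn, n))
      expect_lt(max(abs(est - P)), 1e-8)
      expect_lt(max(abs(naive_power(est, n) - Wn)), 1e-8)
    }
  }
})

test_that("root estimation is invariant to state-order permutation", {
  P <- random_reversible_chain(5, seed = 3)
  n <- 6
  Wn <- naive_power(P, n)
  est <- regularize(estimate_root(diag(5), Wn, n))
  set.seed(1)
  perm <- sample(5)
  p_mat <- diag(5)[perm, ]
  Wp <- p_mat %*% Wn %*% t(p_mat)
  estp <- regularize(estimate_root(diag(5), Wp, n))
  expect_equal(unname(p_mat %*% est %*% t(p_mat)), unname(estp),
               tolerance = 1e-9)
})

test_that("estimate_root rejects singular day-0 matrices and warns off-design", {
  W0 <- matrix(0.5, 2, 2)
  expect_error(estimate_root(W0, diag(2), 2), "singular")
  W0b <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  expect_warning(estimate_root(W0b, diag(2), 2), "not the identity")
})

test_that("regularization clips, renormalizes and is idempotent", {
  # already stochastic: fixed point, exactly
  P <- two_state_chain()
  expect_identical(regularize(P), P)

  raw <- matrix(c(0.5, -0.1, 0.7,
                  0.2, 0.5, 0.3,
                  -0.2, -0.3, 0), 3, byrow = TRUE)
  reg <- regularize(raw)
  expect_equal(unname(reg[1, ]), c(5 / 12, 0, 7 / 12))
  expect_equal(unname(reg[2, ]), c(0.2, 0.5, 0.3))
  # fully clipped row falls back to the unit self-transition
  expect_equal(unname(reg[3, ]), c(0, 0, 1))
  expect_equal(regularize(reg), reg)
  expect_error(regularize(matrix(c(1, NA, 0, 1), 2)), "non-finite")
})

test_that("averaging is the unweighted entrywise mean and stays stochastic", {
  A <- diag(2)
  B <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, byrow = TRUE)
  M <- average_estimates(list(A, B))
  expect_equal(unname(M), matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
  expect_identical(average_estimates(list(B)), B)
  expect_error(average_estimates(list()), "at least one")
  expect_error(average_estimates(list(A, diag(3))), "shape")
  set.seed(7)
  mats <- replicate(3, {
    m <- matrix(rgamma(16, 1), 4); m / rowSums(m)
  }, simplify = FALSE)
  expect_equal(rowSums(average_estimates(mats)), rep(1, 4), tolerance = 1e-12)
})

test_that("multi-day estimator averages per-day regularized roots", {
  P <- random_reversible_chain(4, seed = 5)
  days <- c(20L, 30L, 70L)
  W_list <- lapply(days, function(n) naive_power(P, n))
  P_hat <- estimate_transition_matrix(W_list, days = days)
  expect_lt(max(abs(P_hat - P)), 1e-8)
  diag_df <- attr(P_hat, "diagnostics")
  expect_equal(diag_df$t, days)
  expect_true(all(diag_df$method == "eigen"))
})

test_that("optimization fallback recovers roots and is deterministic", {
  P <- random_reversible_chain(3, seed = 9)
  n <- 4
  Wn <- naive_power(P, n)
  fit <- fit_root_by_optimization(Wn, n, seed = 123)
  expect_lt(fit$residual, 1e-6)
  expect_lt(max(abs(fit$P - P)), 1e-4)
  expect_lt(max(abs(naive_power(fit$P, n) - Wn)), 1e-6)

  # identity fixed point
  fit_id <- fit_root_by_optimization(diag(3), 5, seed = 1)
  expect_equal(unname(fit_id$P), diag(3), tolerance = 1e-10)

  # bit-identical across runs at a fixed seed
  fit2 <- fit_root_by_optimization(Wn, n, seed = 123)
  expect_identical(fit$P, fit2$P)
})

test_that("transition graph lists off-diagonal entries above threshold", {
  sp_n <- paste0("P", 1:16)
  P <- matrix(1 / 16, 16, 16, dimnames = list(sp_n, sp_n))
  g <- extract_graph(P, tau = 0)
  expect_equal(g$n_possible, 240L)
  expect_equal(g$n_edges, 240L)

  g_id <- extract_graph(diag(3), tau = 0)
  expect_equal(g_id$n_edges, 0L)

  P3 <- matrix(c(0.9, 0.1, 0,
                 0, 0.95, 0.05,
                 0.2, 0, 0.8), 3, byrow = TRUE,
               dimnames = list(letters[1:3], letters[1:3]))
  g3 <- extract_graph(P3, tau = 0.01)
  expect_equal(g3$n_edges, 3L)
  expect_setequal(paste(g3$edges$from, g3$edges$to),
                  c("a b", "b c", "c a"))
  expect_equal(sort(g3$edges$weight), c(0.05, 0.1, 0.2))
  expect_error(extract_graph(P3, tau = -1), "tau")
})
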