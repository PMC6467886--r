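test_that("ground-truth structures satisfy their constraints and are seeded", {
  # kronecker: matrix equals the product of its stored factors
  mk <- generate_ground_truth(16, "kronecker-independent", seed = 5)
  expect_equal(unname(mk$P_true), Reduce(kronecker, mk$factors),
               tolerance = 1e-14)
  expect_gte(min(diag(mk$P_true)), 0.95 - 1e-12)

  # with-transient: zero incoming off-diagonal mass, positive outgoing
  mt <- generate_ground_truth(8, "with-transient", seed = 2)
  j <- mt$transient_state
  expect_equal(unname(mt$P_true[-j, j]), rep(0, 7))
  expect_gt(sum(mt$P_true[j, -j]), 0)

  # irreducible: strongly connected with lazy diagonal
  mi <- generate_ground_truth(6, "irreducible", seed = 3)
  expect_true(classify_states(mi$P_true)$irreducible)
  expect_gte(min(diag(mi$P_true)), 0.95)

  # tree: each non-root state fed only by its parent
  tr <- generate_ground_truth(8, "tree-hierarchy", seed = 11)
  for (i in 2:8) {
    feeders <- unname(which(tr$P_true[, i] > 0 & seq_len(8) != i))
    expect_equal(feeders, tr$tree_parent[i])
  }

  # determinism contract
  expect_identical(generate_ground_truth(8, "irreducible", seed = 7),
                   generate_ground_truth(8, "irreducible", seed = 7))
  expect_error(generate_ground_truth(1, "irreducible"), "at least 2")
  expect_error(generate_ground_truth(6, "kronecker-independent"), "2\\^m")
  expect_error(generate_ground_truth(4, "irreducible", self_mass = 1), "self_mass")
})

test_that("expected-mode simulation equals the matrix-power oracle", {
  model <- generate_ground_truth(8, "irreducible", seed = 13)
  days <- c(5L, 20L, 31L)
  sim <- simulate_experiment(model, days = days, mode = "expected", seed = 1)
  expect_equal(sim$value_kind, "fractions")
  for (t in days) {
    W <- build_proportion_matrix(sim$table, model$states, t)
    expect_equal(bare(W), bare(naive_power(model$P_true, t)),
                 tolerance = 1e-12)
    expect_equal(rowSums(W), setNames(rep(1, 8), model$states),
                 tolerance = 1e-12)
  }
  # identity chain never moves
  frozen <- generate_ground_truth(4, "irreducible", seed = 1)
  frozen$P_true[] <- diag(4)
  simf <- simulate_experiment(frozen, days = c(3L, 9L), mode = "expected", seed = 1)
  Wf <- build_proportion_matrix(simf$table, frozen$states, 9)
  expect_equal(bare(Wf), diag(4))
})

test_that("per-cell simulation matches expectations within sampling error", {
  model <- generate_ground_truth(4, "irreducible", seed = 21, self_mass = 0.8)
  n <- 1e5
  days <- c(5L, 15L)
  sim <- simulate_experiment(model, days = days, n_cells = n,
                             mode = "per-cell", seed = 99)
  expect_equal(sim$value_kind, "counts")
  tab <- as.data.frame(sim$table)
  # counts conserve the phenotyped census
  totals <- tapply(tab$value, interaction(tab$initial_state, tab$time_days), sum)
  expect_true(all(totals == n))
  for (t in days) {
    W_obs <- build_proportion_matrix(sim$table, model$states, t)
    W_exp <- naive_power(model$P_true, t)
    # every entry within 4 binomial standard deviations
    sd_bound <- sqrt(W_exp * (1 - W_exp) / n)
    expect_true(all(abs(W_obs - W_exp) <= 4 * sd_bound + 1e-12))
  }
  # per-culture seed split: rerun is identical
  sim2 <- simulate_experiment(model, days = days, n_cells = n,
                              mode = "per-cell", seed = 99)
  expect_identical(as.data.frame(sim$table), as.data.frame(sim2$table))
})

test_that("day 0 in per-cell mode returns the exact initial composition", {
  model <- generate_ground_truth(4, "irreducible", seed = 2)
  sim <- simulate_experiment(model, days = c(0L, 3L), n_cells = 1000,
                             mode = "per-cell", seed = 1)
  tab <- as.data.frame(sim$table)
  d0 <- tab[tab$time_days == 0 & tab$initial_state == "P2", ]
  expect_equal(d0$value[d0$observed_state == "P2"], 1000)
  expect_equal(sum(d0$value), 1000)
})

test_that("proliferation shifts compositions toward fast-dividing states", {
  P <- diag(2) # no transitions: growth differences alone drive the shift
  model <- generate_ground_truth(2, "irreducible", seed = 1)
  model$P_true[] <- P
  model$doubling_times <- c(1, 10)
  x <- phenflux:::expected_trajectory(model, c(0.5, 0.5), days = 10L)[["10"]]
  # analytic: x1/x2 = 2^(10/1) / 2^(10/10)
  expect_equal(x[1] / x[2], 2^10 / 2^1, tolerance = 1e-9)
  expect_equal(sum(x), 1, tolerance = 1e-12)
})

test_that("recovery error is near zero on noiseless data and shrinks with cells", {
  model <- generate_ground_truth(8, "irreducible", seed = 31)
  noiseless <- recovery_benchmark(model, days = c(20L, 30L, 70L),
                                  mode = "expected", seeds = 1)
  expect_lt(noiseless$max_abs_error, 1e-6)
  expect_lt(noiseless$tv_stationary, 1e-6)

  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    rb <- recovery_benchmark(model, days = c(20L, 30L, 70L), n_cells = n,
                             seeds = 1:2, mode = "per-cell")
    mean(rb$mean_abs_error)
  }, numeric(1))
  expect_equal(errs, sort(errs, decreasing = TRUE))
})

test_that("tree ground truths keep a perfect hierarchy through the pipeline", {
  for (seed in c(4, 11)) {
    model <- generate_ground_truth(8, "tree-hierarchy", seed = seed)
    sim <- simulate_experiment(model, days = c(20L, 30L, 70L),
                               mode = "expected", seed = 1)
    W_list <- lapply(c(20, 30, 70), function(t) {
      build_proportion_matrix(sim$table, model$states, t)
    })
    P_hat <- estimate_transition_matrix(W_list, days = c(20, 30, 70))
    h <- krackhardt_hierarchy(extract_graph(P_hat, tau = 0))
    expect_equal(h$score, 1)
  }
})
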