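test_that("stationary distribution matches closed forms and the power oracle", {
  # 2-state closed form: pi = (b, a) / (a + b) for off-diagonals a, b
  P <- two_state_chain()
  eq <- stationary_distribution(P)
  expect_true(eq$unique)
  expect_equal(unname(eq$pi), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(unname(as.vector(eq$pi %*% P)), unname(eq$pi), tolerance = 1e-9)

  # doubly stochastic chains are uniform
  D <- matrix(c(0.5, 0.3, 0.2,
                0.2, 0.5, 0.3,
                0.3, 0.2, 0.5), 3, byrow = TRUE)
  expect_equal(unname(stationary_distribution(D)$pi), rep(1 / 3, 3),
               tolerance = 1e-12)

  # agreement with power iteration on random irreducible chains
  for (seed in 1:5) {
    Q <- random_reversible_chain(sample(3:8, 1), seed)
    eqq <- stationary_distribution(Q)
    expect_equal(unname(eqq$pi), power_iteration_stationary(Q),
                 tolerance = 1e-10)
    expect_equal(sum(eqq$pi), 1, tolerance = 1e-12)
  }
})

test_that("reducible chains report all extremal stationary solutions", {
  eq <- stationary_distribution(diag(4))
  expect_false(eq$unique)
  expect_equal(eq$n_recurrent_classes, 4L)
  basis <- do.call(rbind, eq$extremals)
  expect_equal(unname(basis), diag(4))
})

test_that("composition prediction is the matrix-power action on the simplex", {
  P <- two_state_chain()
  expect_equal(unname(predict_composition(P, c(0.4, 0.6), 0)), c(0.4, 0.6))
  expect_equal(unname(predict_composition(P, c(1, 0), 1)), unname(P[1, ]))
  expect_equal(unname(predict_composition(P, c(1, 0), 2)), c(0.83, 0.17))
  expect_error(predict_composition(P, c(1, 0), -1), "non-negative")
  expect_error(predict_composition(P, c(0.7, 0.7), 3), "sum to 1")

  # rows of pure-start predictions at day t equal P^t (oracle: matrix power)
  Q <- random_reversible_chain(5, seed = 2)
  for (t in c(3, 11)) {
    Wt <- t(vapply(1:5, function(i) {
      predict_composition(Q, replace(rep(0, 5), i, 1), t)
    }, numeric(5)))
    expect_equal(unname(Wt), unname(naive_power(Q, t)), tolerance = 1e-12)
  }
  # simplex membership exact under long propagation
  x <- predict_composition(Q, rep(0.2, 5), 500)
  expect_equal(sum(x), 1, tolerance = 1e-12)
  expect_true(all(x >= 0))
})

test_that("relaxation time finds the first day within tolerance of equilibrium", {
  P <- two_state_chain()
  # analytic: TV(t) = (1/3) * 0.7^t; first t with TV < 0.01 is 10
  r <- time_to_equilibrium(P, c(1, 0), eps = 0.01, metric = "tv")
  expect_equal(r$days, 10L)
  expect_true(r$reached)

  # starting at equilibrium takes 0 days
  eq <- stationary_distribution(P)
  expect_equal(time_to_equilibrium(P, eq$pi)$days, 0L)

  # non-increasing in eps
  prev <- Inf
  for (eps in c(0.001, 0.01, 0.05, 0.2)) {
    d <- time_to_equilibrium(P, c(1, 0), eps = eps)$days
    expect_lte(d, prev)
    prev <- d
  }

  # t_max cutoff reports the last distance instead of a time
  slow <- matrix(c(0.999, 0.001, 0.001, 0.999), 2, byrow = TRUE)
  r2 <- time_to_equilibrium(slow, c(1, 0), eps = 1e-4, t_max = 50)
  expect_false(r2$reached)
  expect_true(is.na(r2$days))
  expect_gt(r2$distance, 1e-4)

  expect_error(time_to_equilibrium(diag(3), c(1, 0, 0)), "not unique")
  flip <- matrix(c(0, 1, 1, 0), 2)
  expect_error(time_to_equilibrium(flip, c(1, 0)), "periodic")
})

test_that("distance to equilibrium vanishes for aperiodic irreducible chains", {
  for (seed in 1:4) {
    P <- random_reversible_chain(sample(3:6, 1), seed)
    pi <- stationary_distribution(P)$pi
    set.seed(seed)
    x <- rgamma(nrow(P), 1); x <- x / sum(x)
    d_prev <- Inf
    for (t in c(10, 100, 1000)) {
      d <- phenflux:::tv_distance(predict_composition(P, x, t), pi)
      expect_lte(d, d_prev + 1e-15)
      d_prev <- d
    }
    expect_lt(d_prev, 1e-10)
  }
})

test_that("state classification identifies transient, recurrent and absorbing", {
  # irreducible 3-cycle with self-loops
  C <- matrix(c(0.5, 0.5, 0,
                0, 0.5, 0.5,
                0.5, 0, 0.5), 3, byrow = TRUE)
  cl <- classify_states(C)
  expect_true(cl$irreducible)
  expect_true(all(cl$status == "recurrent"))
  expect_length(cl$recurrent_classes, 1L)

  # unit self-transition row is absorbing
  A <- matrix(c(1, 0, 0.3, 0.7), 2, byrow = TRUE)
  cla <- classify_states(A)
  expect_true(cla$absorbing[1])
  expect_false(cla$absorbing[2])

  # zero incoming off-diagonal mass but positive outgoing: transient,
  # reducible, no absorbing state
  P <- matrix(c(0.8, 0.2, 0,
                0.3, 0.7, 0,
                0.1, 0.2, 0.7), 3, byrow = TRUE,
              dimnames = list(paste0("P", 1:3), paste0("P", 1:3)))
  clt <- classify_states(P)
  expect_false(clt$irreducible)
  expect_equal(clt$transient_states, "P3")
  expect_false(any(clt$absorbing))
})

test_that("admixture design hits attainable relaxation targets deterministically", {
  P <- two_state_chain()
  d0 <- design_admixture(P, target_days = 0, seed = 4)
  expect_equal(d0$achieved_days, 0)
  expect_equal(unname(d0$composition), c(2 / 3, 1 / 3), tolerance = 1e-9)

  d10 <- design_admixture(P, target_days = 10, seed = 4)
  expect_equal(d10$achieved_days, 10)

  d10b <- design_admixture(P, target_days = 10, seed = 4)
  expect_identical(d10$composition, d10b$composition)
  expect_error(design_admixture(diag(2), 5), "not unique")
})
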