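#' Generate a ground-truth plasticity model
#'
#' Builds a seeded, reproducible K-state daily transition chain of a chosen
#' structural class, for use as simulation ground truth in recovery tests:
#' \describe{
#'   \item{irreducible}{strictly positive off-diagonals; every state reaches
#'     every other (the normoxia-like, fully plastic regime).}
#'   \item{tree-hierarchy}{a rooted out-tree: each non-root state is fed only
#'     by its parent, leaves are absorbing — a perfect phenotypic hierarchy.}
#'   \item{with-transient}{one designated state receives no incoming
#'     off-diagonal mass but can still exit (the hypoxia-like regime: a
#'     reducible chain with a transient state and no absorbing state).}
#'   \item{kronecker-independent}{the Kronecker product of log2(K) independent
#'     2-state marker chains; marker transitions do not depend on the other
#'     markers.}
#' }
#'
#' @param K number of states (>= 2; a power of 2 for
#'   `kronecker-independent`).
#' @param structure structural class (see above).
#' @param self_mass guaranteed lower bound on every diagonal entry, in
#'   `[0, 1)`. The default 0.95 caps the daily switching probability at 5%,
#'   which places bulk relaxation around 50 days and pure-start relaxation
#'   around 100 days — the weeks-to-months scale over which marker-sorted
#'   glioma cultures are observed to re-equilibrate, and the regime in which
#'   a day-20/30/70 measurement design is actually informative (a chain that
#'   equilibrates within a week leaves no signal in such data).
#' @param seed integer seed.
#' @param doubling_times optional per-state doubling times in days (length K)
#'   enabling proliferation in the simulator.
#' @return object of class `ground_truth_model`: `P_true`, `structure`,
#'   `states`, `doubling_times`, `seed`, plus structure-specific fields
#'   (`factors` for kronecker, `transient_state`, `tree_parent`).
#' @export
generate_ground_truth <- function(K, structure = c("irreducible", "tree-hierarchy",
                                                   "with-transient",
                                                   "kronecker-independent"),
                                  self_mass = 0.95, seed = 1L,
                                  doubling_times = NULL) {
  structure_name <- match.arg(structure)
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  if (self_mass < 0 || self_mass >= 1) stop("self_mass must be in [0, 1)", call. = FALSE)
  if (!is.null(doubling_times) && length(doubling_times) != K) {
    stop("doubling_times must have length K", call. = FALSE)
  }
  if (!is.null(doubling_times) && any(doubling_times <= 0)) {
    stop("doubling times must be positive", call. = FALSE)
  }
  set.seed(seed)
  states <- paste0("P", seq_len(K))
  extra <- list()
  P <- switch(structure_name,
    "irreducible" = {
      Q <- matrix(stats::rgamma(K * K, shape = 1), K, K)
      Q <- Q / rowSums(Q)
      self_mass * diag(K) + (1 - self_mass) * Q
    },
    "tree-hierarchy" = {
      if (K < 2) stop("tree structure needs K >= 2", call. = FALSE)
      parent <- c(NA_integer_,
                  vapply(2:K, function(i) sample.int(i - 1L, 1L), integer(1)))
      P <- matrix(0, K, K)
      for (i in seq_len(K)) {
        children <- which(parent == i)
        if (length(children) == 0L) {
          P[i, i] <- 1 # leaf: absorbing
        } else {
          # distinct internal self-retentions keep the chain diagonalizable
          d <- stats::runif(1, self_mass, 0.999)
          w <- stats::rgamma(length(children), shape = 1)
          P[i, i] <- d
          P[i, children] <- (1 - d) * w / sum(w)
        }
      }
      extra$tree_parent <- parent
      P
    },
    "with-transient" = {
      trans <- K # designated transient state: the last
      Q <- matrix(stats::rgamma(K * K, shape = 1), K, K)
      Q[, trans] <- 0 # no incoming mass (also zero self via Q; restored below)
      Q <- Q / rowSums(Q)
      P <- self_mass * diag(K) + (1 - self_mass) * Q
      extra$transient_state <- trans
      P
    },
    "kronecker-independent" = {
      m <- log2(K)
      if (m != round(m)) stop("kronecker-independent needs K = 2^m", call. = FALSE)
      m <- as.integer(m)
      d_min <- self_mass^(1 / m) # per-factor floor so the product diagonal >= self_mass
      factors <- lapply(seq_len(m), function(j) {
        a <- stats::runif(1, 0, 1 - d_min) # P(+ -> -)
        b <- stats::runif(1, 0, 1 - d_min) # P(- -> +)
        matrix(c(1 - a, a, b, 1 - b), 2, 2, byrow = TRUE)
      })
      extra$factors <- factors
      Reduce(kronecker, factors)
    }
  )
  dimnames(P) <- list(states, states)
  assert_row_stochastic(P, what = "ground-truth matrix")
  # verify structure constraints before returning
  if (structure_name == "irreducible" && !classify_states(P)$irreducible) {
    stop("generated matrix is not irreducible", call. = FALSE)
  }
  if (structure_name == "with-transient") {
    stopifnot(all(P[-extra$transient_state, extra$transient_state] == 0))
  }
  if (structure_name != "kronecker-independent" && any(diag(P) < self_mass)) {
    stop("diagonal fell below self_mass", call. = FALSE)
  }
  structure(
    c(list(P_true = P, structure = structure_name, states = states,
           doubling_times = doubling_times, seed = seed, K = K), extra),
    class = "ground_truth_model"
  )
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat("Ground-truth model:", x$K, "states, structure =", x$structure,
      ", seed =", x$seed, "\n")
  invisible(x)
}

# Multivariate hypergeometric draw: sample `size` cells without replacement
# from a census of counts (sequential conditional rhyper draws).
sample_census <- function(counts, size) {
  K <- length(counts)
  total <- sum(counts)
  if (size >= total) return(counts)
  out <- integer(K)
  remaining <- total
  take <- size
  for (i in seq_len(K)) {
    if (take == 0L) break
    if (i == K) {
      out[i] <- take
      break
    }
    x <- stats::rhyper(1, counts[i], remaining - counts[i], take)
    out[i] <- x
    take <- take - x
    remaining <- remaining - counts[i]
  }
  out
}

# One culture's per-cell trajectory: daily division (per-day division
# probability 2^(1/d_i) - 1) followed by per-cell state transitions, with
# phenotyping snapshots at the requested days.
simulate_culture_cells <- function(model, counts0, days, n_cells, replace) {
  P <- model$P_true
  K <- model$K
  g <- model$doubling_times
  horizon <- max(days)
  counts <- counts0
  snapshots <- list()
  if (0L %in% days) snapshots[["0"]] <- counts # exact initial composition
  for (day in seq_len(horizon)) {
    if (!is.null(g)) {
      births <- stats::rbinom(K, counts, 2^(1 / g) - 1)
      counts <- counts + births
    }
    new_counts <- integer(K)
    for (i in seq_len(K)) {
      if (counts[i] > 0L) {
        new_counts <- new_counts + as.integer(stats::rmultinom(1, counts[i], P[i, ]))
      }
    }
    counts <- new_counts
    if (day %in% days) snapshots[[as.character(day)]] <- counts
  }
  lapply(snapshots, function(cn) {
    if (replace) {
      as.integer(stats::rmultinom(1, min(n_cells, sum(cn)), cn / sum(cn)))
    } else {
      sample_census(cn, n_cells)
    }
  })
}

# Expected (noiseless) trajectory, with optional proliferation weighting:
# x_{t+1} proportional to (x_t * 2^(1/d)) P.
expected_trajectory <- function(model, x0, days) {
  P <- model$P_true
  g <- model$doubling_times
  horizon <- max(days)
  x <- x0
  out <- list()
  if (0L %in% days) out[["0"]] <- x
  for (day in seq_len(horizon)) {
    if (!is.null(g)) {
      x <- x * 2^(1 / g)
      x <- x / sum(x)
    }
    x <- as.vector(x %*% P)
    if (day %in% days) out[[as.character(day)]] <- x
  }
  out
}

#' Simulate a phenotyping experiment under a ground-truth model
#'
#' Emulates the pure-start multipotency design (every state sorted to purity
#' and re-phenotyped at chosen days) or an admixture experiment. In
#' `expected` mode compositions follow the deterministic propagation
#' `x0 P^t` exactly (with proliferation, daily reweighting by the per-state
#' growth factor `2^(1/d_i)` before the transition step). In `per-cell` mode
#' every cell divides with daily probability `2^(1/d_i) - 1`, then switches
#' state by sampling its transition row; phenotyping draws `n_cells` cells
#' without replacement from the harvest (all cells when fewer). All
#' randomness derives from `seed` via a per-culture seed split, so any single
#' culture is independently reproducible.
#'
#' @param model a `ground_truth_model`.
#' @param design `"pure-start"` (default; one culture per state) or
#'   `"admixture"` (requires `x0`).
#' @param days measurement days (positive integers; 0 allowed and returns the
#'   exact initial composition).
#' @param n_cells cells phenotyped per measurement.
#' @param mode `"expected"` (noiseless fractions) or `"per-cell"`
#'   (stochastic counts).
#' @param seed master seed.
#' @param x0 initial composition for the admixture design.
#' @param n0 initial cells per culture in per-cell mode (default `n_cells`).
#' @param condition condition label written into the table.
#' @param replace phenotype with replacement instead (multinomial draw).
#' @return object of class `simulated_experiment`: `table` (an
#'   `observation_table` in the CSV dialect [read_observation_table()]
#'   accepts), `value_kind`, `design`, `days`, `n_cells`, `mode`, `seed`.
#' @export
simulate_experiment <- function(model, design = c("pure-start", "admixture"),
                                days = c(20L, 30L, 70L), n_cells = 1e5,
                                mode = c("expected", "per-cell"), seed = 1L,
                                x0 = NULL, n0 = n_cells, condition = "sim",
                                replace = FALSE) {
  design <- match.arg(design)
  mode <- match.arg(mode)
  stopifnot(inherits(model, "ground_truth_model"))
  if (any(days < 0) || any(days != round(days))) {
    stop("days must be non-negative integers", call. = FALSE)
  }
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  days <- sort(unique(as.integer(days)))
  K <- model$K
  states <- model$states
  starts <- if (design == "pure-start") {
    lapply(seq_len(K), function(i) replace(rep(0, K), i, 1))
  } else {
    if (is.null(x0)) stop("admixture design requires x0", call. = FALSE)
    list(validate_composition(x0, K))
  }
  start_labels <- if (design == "pure-start") states else "mix"
  culture_seeds <- split_seed(seed, length(starts))
  records <- list()
  for (ci in seq_along(starts)) {
    set.seed(culture_seeds[ci])
    if (mode == "expected") {
      snaps <- expected_trajectory(model, starts[[ci]], days)
    } else {
      counts0 <- as.integer(round(starts[[ci]] * n0))
      snaps <- simulate_culture_cells(model, counts0, days, n_cells, replace)
    }
    for (day in names(snaps)) {
      records[[length(records) + 1L]] <- data.frame(
        condition = condition,
        initial_state = start_labels[ci],
        time_days = as.integer(day),
        observed_state = states,
        value = as.numeric(snaps[[day]]),
        replicate = 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  table <- do.call(rbind, records)
  value_kind <- if (mode == "expected") "fractions" else "counts"
  table <- as_observation_table(table, value_kind = value_kind)
  structure(
    list(table = table, value_kind = value_kind, design = design,
         days = days, n_cells = n_cells, mode = mode, seed = seed,
         model_structure = model$structure),
    class = "simulated_experiment"
  )
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat("Simulated", x$design, "experiment (", x$mode, "mode ):",
      length(x$days), "measurement days,", x$n_cells, "cells phenotyped\n")
  invisible(x)
}

#' Run the full recovery benchmark on a ground-truth model
#'
#' Simulates the pure-start design, rebuilds proportion matrices, estimates
#' the transition matrix through the root / regularize / average pipeline,
#' and scores the estimate against the ground truth: maximum and mean
#' absolute entry error of the estimated matrix and the total-variation
#' distance between estimated and true stationary compositions.
#'
#' @param model a `ground_truth_model`.
#' @param days measurement days.
#' @param n_cells cells phenotyped per measurement (per-cell mode).
#' @param seeds integer vector; one pipeline run per seed.
#' @param mode `"per-cell"` or `"expected"` (noiseless).
#' @param n0 initial cells per culture.
#' @return data.frame with one row per seed (`max_abs_error`,
#'   `mean_abs_error`, `tv_stationary`) and attribute `summary` holding the
#'   across-seed means.
#' @export
recovery_benchmark <- function(model, days = c(20L, 30L, 70L), n_cells = 1e5,
                               seeds = 1:5, mode = c("per-cell", "expected"),
                               n0 = n_cells) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "ground_truth_model"))
  pi_true <- stationary_distribution(model$P_true)
  rows <- lapply(seeds, function(s) {
    sim <- simulate_experiment(model, design = "pure-start", days = days,
                               n_cells = n_cells, mode = mode, seed = s, n0 = n0)
    W_list <- lapply(days, function(t) {
      build_proportion_matrix(sim$table, model$states, t = t)
    })
    P_hat <- estimate_transition_matrix(W_list, days = days)
    err <- abs(P_hat - model$P_true)
    tv <- if (pi_true$unique) {
      eq_hat <- stationary_distribution(P_hat)
      if (eq_hat$unique) tv_distance(eq_hat$pi, pi_true$pi) else NA_real_
    } else NA_real_
    data.frame(seed = s, max_abs_error = max(err), mean_abs_error = mean(err),
               tv_stationary = tv)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- colMeans(out[, -1, drop = FALSE])
  out
}
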