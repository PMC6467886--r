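# Recurrent-class decomposition used by stationary_distribution and
# classify_states: strongly connected components of the tau-thresholded
# transition graph, and which components are closed (no exits).
recurrent_structure <- function(P, tau = 0) {
  tau_eff <- max(tau, 1e-12)
  K <- nrow(P)
  A <- (P > tau_eff)
  diag(A) <- TRUE # self-loops never change SCCs, keep isolated nodes in play
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  n_comp <- comp$no
  closed <- rep(TRUE, n_comp)
  off <- which(P > tau_eff & row(P) != col(P), arr.ind = TRUE)
  if (nrow(off)) {
    leaves <- memb[off[, 1]] != memb[off[, 2]]
    closed[unique(memb[off[leaves, 1]])] <- FALSE
  }
  list(membership = memb, n_comp = n_comp, closed = closed)
}

# Stationary vector of an irreducible stochastic matrix by solving the
# linear system (t(P) - I) pi = 0, sum(pi) = 1 in least squares.
solve_stationary <- function(P) {
  K <- nrow(P)
  A <- rbind(t(P) - diag(K), rep(1, K))
  b <- c(rep(0, K), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  pi / sum(pi)
}

#' Stationary (equilibrium) composition of the transition chain
#'
#' Computes the left eigenvector of the transition matrix for eigenvalue 1,
#' normalized to a composition — the predicted long-run phenotypic
#' heterogeneity. When the chain is reducible with several closed recurrent
#' classes the stationary distribution is not unique; all extremal solutions
#' (one per closed class) are reported and `unique` is FALSE.
#'
#' @param P K x K row-stochastic transition matrix.
#' @param tau threshold defining the support graph (default 0 with 1e-12
#'   floor).
#' @return object of class `equilibrium_result`: `pi` (the stationary
#'   composition; for non-unique chains the first extremal solution), `unique`,
#'   `extremals` (list of compositions, one per closed recurrent class).
#' @examples
#' P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
#' stationary_distribution(P)$pi # (2/3, 1/3)
#' @export
stationary_distribution <- function(P, tau = 0) {
  assert_row_stochastic(P, what = "transition matrix")
  K <- nrow(P)
  states <- rownames(P) %||% paste0("P", seq_len(K))
  rs <- recurrent_structure(P, tau)
  closed_ids <- which(rs$closed)
  # report closed classes in state order, not SCC-discovery order
  closed_ids <- closed_ids[order(vapply(closed_ids, function(cid) {
    min(which(rs$membership == cid))
  }, integer(1)))]
  extremals <- lapply(closed_ids, function(cid) {
    members <- which(rs$membership == cid)
    pi <- rep(0, K)
    if (length(members) == 1L) {
      pi[members] <- 1
    } else {
      pi[members] <- solve_stationary(P[members, members, drop = FALSE] /
                                        rowSums(P[members, members, drop = FALSE]))
    }
    stats::setNames(pi, states)
  })
  unique_flag <- length(extremals) == 1L
  pi <- if (unique_flag) {
    # solve on the full matrix so transient mass is exactly zero in the limit
    stats::setNames(solve_stationary(P), states)
  } else {
    extremals[[1]]
  }
  structure(
    list(pi = pi, unique = unique_flag, extremals = extremals,
         n_recurrent_classes = length(extremals)),
    class = "equilibrium_result"
  )
}

#' @export
print.equilibrium_result <- function(x, ...) {
  if (x$unique) {
    cat("Unique stationary composition:\n")
    print(round(x$pi, 4))
  } else {
    cat("Stationary distribution not unique (", x$n_recurrent_classes,
        "closed recurrent classes ); extremal solutions in $extremals\n")
  }
  invisible(x)
}

#' Forward-predict a population composition
#'
#' Propagates an initial composition t days through the chain: `x0 P^t`,
#' computed by repeated multiplication so simplex membership is preserved
#' exactly.
#'
#' @param P K x K row-stochastic transition matrix.
#' @param x0 length-K composition (non-negative, sums to 1).
#' @param t days (non-negative integer).
#' @return length-K composition after t days.
#' @export
predict_composition <- function(P, x0, t) {
  assert_row_stochastic(P, what = "transition matrix")
  if (t < 0 || t != round(t)) stop("t must be a non-negative integer", call. = FALSE)
  x0 <- validate_composition(x0, nrow(P))
  x <- x0
  for (k in seq_len(t)) x <- as.vector(x %*% P)
  stats::setNames(x, rownames(P))
}

validate_composition <- function(x0, K) {
  if (length(x0) != K) stop("composition length must match the state space",
                            call. = FALSE)
  if (any(x0 < -1e-12)) stop("composition entries must be non-negative", call. = FALSE)
  if (abs(sum(x0) - 1) > 1e-9) stop("composition must sum to 1", call. = FALSE)
  pmax(as.numeric(x0), 0)
}

# Period of the (unique) recurrent class: gcd over within-class edges of
# depth(u) + 1 - depth(v) from a BFS. 1 means aperiodic.
chain_period <- function(P, tau = 0) {
  tau_eff <- max(tau, 1e-12)
  rs <- recurrent_structure(P, tau)
  cid <- which(rs$closed)[1]
  members <- which(rs$membership == cid)
  sub <- P[members, members, drop = FALSE]
  n <- length(members)
  if (any(diag(sub) > tau_eff)) return(1L) # any self-loop kills periodicity
  depth <- rep(NA_integer_, n)
  depth[1] <- 0L
  queue <- 1L
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in which(sub[u, ] > tau_eff)) {
      if (is.na(depth[v])) {
        depth[v] <- depth[u] + 1L
        queue <- c(queue, v)
      }
    }
  }
  g <- 0L
  for (u in seq_len(n)) for (v in which(sub[u, ] > tau_eff)) {
    g <- gcd_int(g, abs(depth[u] + 1L - depth[v]))
  }
  if (g == 0L) 1L else g
}

gcd_int <- function(a, b) {
  while (b != 0L) { tmp <- a %% b; a <- b; b <- tmp }
  a
}

#' Days until an initial composition approximately reaches equilibrium
#'
#' Finds the smallest integer day t at which the propagated composition
#' `x0 P^t` is within `eps` of the stationary composition under the chosen
#' metric (default total variation, eps = 0.01). Requires a unique stationary
#' distribution and an aperiodic chain; periodic chains are refused rather
#' than reported via Cesaro limits.
#'
#' @param P K x K row-stochastic transition matrix.
#' @param x0 initial composition.
#' @param eps tolerance (> 0).
#' @param metric `"tv"` (total variation, default), `"l1"`, `"l2"` or `"max"`.
#' @param t_max cutoff in days; if equilibrium is not reached by then the
#'   result carries `reached = FALSE` and the last distance.
#' @return list of class `relaxation_time`: `days` (NA if not reached),
#'   `reached`, `distance` at the returned day, `eps`, `metric`, `t_max`.
#' @export
time_to_equilibrium <- function(P, x0, eps = 0.01, metric = "tv", t_max = 1000L) {
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  eq <- stationary_distribution(P)
  if (!eq$unique) {
    stop("stationary distribution is not unique; relaxation time undefined",
         call. = FALSE)
  }
  if (chain_period(P) > 1L) {
    stop("chain is periodic; no convergence to the stationary composition",
         call. = FALSE)
  }
  x <- validate_composition(x0, nrow(P))
  pi <- eq$pi
  t <- 0L
  d <- composition_distance(x, pi, metric)
  while (d >= eps && t < t_max) {
    x <- as.vector(x %*% P)
    t <- t + 1L
    d <- composition_distance(x, pi, metric)
  }
  reached <- d < eps
  structure(
    list(days = if (reached) t else NA_integer_, reached = reached,
         distance = d, eps = eps, metric = metric, t_max = as.integer(t_max)),
    class = "relaxation_time"
  )
}

#' @export
print.relaxation_time <- function(x, ...) {
  if (x$reached) {
    cat("Equilibrium (", x$metric, "<", x$eps, ") reached after",
        x$days, "days\n")
  } else {
    cat("Equilibrium not reached within", x$t_max, "days (last",
        x$metric, "distance", format(x$distance), ")\n")
  }
  invisible(x)
}

#' Classify chain states as transient, recurrent or absorbing
#'
#' Decomposes the tau-thresholded transition graph into strongly connected
#' components. States in non-closed components are transient; closed
#' components are the recurrent classes. A state is absorbing when its
#' self-transition probability exceeds `1 - tau_abs` and every other entry of
#' its row is at most `tau` (no exit possible). The chain is irreducible when
#' a single component covers all states.
#'
#' @param P K x K row-stochastic transition matrix.
#' @param tau edge threshold (default 0 with 1e-12 floor).
#' @param tau_abs tolerance on exit probability for absorbing detection.
#' @return object of class `state_classification`: per-state `status`
#'   (transient/recurrent), `absorbing` flags, `irreducible`,
#'   `recurrent_classes` (list of state-label vectors), `transient_states`.
#' @export
classify_states <- function(P, tau = 0, tau_abs = 1e-9) {
  assert_row_stochastic(P, what = "transition matrix")
  K <- nrow(P)
  states <- rownames(P) %||% paste0("P", seq_len(K))
  rs <- recurrent_structure(P, tau)
  tau_eff <- max(tau, 1e-12)
  status <- ifelse(rs$closed[rs$membership], "recurrent", "transient")
  absorbing <- vapply(seq_len(K), function(i) {
    diag(P)[i] > 1 - tau_abs && all(P[i, -i] <= tau_eff)
  }, logical(1))
  rec_classes <- lapply(which(rs$closed), function(cid) {
    states[rs$membership == cid]
  })
  structure(
    list(states = states,
         status = stats::setNames(status, states),
         absorbing = stats::setNames(absorbing, states),
         irreducible = rs$n_comp == 1L,
         recurrent_classes = rec_classes,
         transient_states = states[status == "transient"]),
    class = "state_classification"
  )
}

#' @export
print.state_classification <- function(x, ...) {
  cat("Chain is", if (x$irreducible) "irreducible" else "reducible", "\n")
  if (length(x$transient_states)) {
    cat("Transient states:", paste(x$transient_states, collapse = ", "), "\n")
  }
  if (any(x$absorbing)) {
    cat("Absorbing states:", paste(names(which(x$absorbing)), collapse = ", "), "\n")
  } else {
    cat("No absorbing state\n")
  }
  invisible(x)
}

#' Design an admixture with a target relaxation time
#'
#' Seeded random search over the composition simplex for an initial admixture
#' whose time to approximate equilibrium is closest to `target_days`.
#' Candidates are uniform-Dirichlet draws plus the stationary composition and
#' all pure states; the achieved time is reported alongside the composition.
#'
#' @param P K x K row-stochastic transition matrix with unique stationary
#'   state.
#' @param target_days desired relaxation time in days.
#' @param eps,metric,t_max forwarded to [time_to_equilibrium()].
#' @param seed integer seed (deterministic search).
#' @param n_candidates number of random simplex draws.
#' @return list of class `admixture_design`: `composition`, `achieved_days`,
#'   `target_days`, `eps`, `metric`.
#' @export
design_admixture <- function(P, target_days, eps = 0.01, metric = "tv",
                             t_max = 1000L, seed = 1L, n_candidates = 200L) {
  eq <- stationary_distribution(P)
  if (!eq$unique) stop("stationary distribution is not unique", call. = FALSE)
  K <- nrow(P)
  set.seed(seed)
  cands <- c(
    list(eq$pi),
    lapply(seq_len(K), function(i) stats::setNames(replace(rep(0, K), i, 1),
                                                   names(eq$pi))),
    lapply(seq_len(n_candidates), function(k) {
      g <- stats::rexp(K)
      stats::setNames(g / sum(g), names(eq$pi))
    })
  )
  times <- vapply(cands, function(x0) {
    r <- time_to_equilibrium(P, x0, eps = eps, metric = metric, t_max = t_max)
    if (r$reached) as.numeric(r$days) else Inf
  }, numeric(1))
  best <- which.min(abs(times - target_days))
  structure(
    list(composition = cands[[best]], achieved_days = times[best],
         target_days = target_days, eps = eps, metric = metric),
    class = "admixture_design"
  )
}

#' @export
print.admixture_design <- function(x, ...) {
  cat("Admixture targeting", x$target_days, "days; achieved",
      x$achieved_days, "days\n")
  print(round(x$composition, 4))
  invisible(x)
}
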