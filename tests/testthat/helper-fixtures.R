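# Shared fixtures and independent oracles used across the suite.

# Strip dimnames and bookkeeping attributes for pure numeric comparison.
bare <- function(M) matrix(as.numeric(M), nrow(M), ncol(M))

# The 2-state worked chain: off-diagonals 0.1 and 0.2, stationary (2/3, 1/3).
two_state_chain <- function() {
  matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE,
         dimnames = list(c("P1", "P2"), c("P1", "P2")))
}

# Independent matrix-power oracle (naive repeated multiplication).
naive_power <- function(P, n) {
  out <- diag(nrow(P))
  for (k in seq_len(n)) out <- out %*% P
  dimnames(out) <- dimnames(P)
  out
}

# Random reversible row-stochastic matrix: row-normalized symmetric weights
# mixed with the identity, hence real distinct positive eigenvalues almost
# surely. The 0.8 identity mass keeps every eigenvalue >= 0.6, so powers up
# to n = 30 stay numerically full-rank and the n-th root is identifiable at
# machine precision (an eigenvalue whose n-th power underflows below the
# matrix entries' precision carries no recoverable information).
random_reversible_chain <- function(K, seed, lazy = 0.8) {
  set.seed(seed)
  S <- matrix(stats::runif(K * K), K, K)
  S <- (S + t(S)) / 2
  Q <- S / rowSums(S)
  P <- lazy * diag(K) + (1 - lazy) * Q
  dimnames(P) <- list(paste0("P", 1:K), paste0("P", 1:K))
  P
}

# Power-iteration oracle for the stationary distribution.
power_iteration_stationary <- function(P, iters = 20000) {
  x <- rep(1 / nrow(P), nrow(P))
  for (k in seq_len(iters)) x <- as.vector(x %*% P)
  x / sum(x)
}

# Build a transition_graph directly from an edge list (unit weights).
graph_from_edges <- function(nodes, from, to) {
  K <- length(nodes)
  P <- diag(K)
  dimnames(P) <- list(nodes, nodes)
  for (k in seq_along(from)) {
    i <- match(from[k], nodes); j <- match(to[k], nodes)
    P[i, j] <- 0.1
  }
  P <- P / rowSums(P)
  extract_graph(P, tau = 0)
}

# Two-marker chain in which marker-A transitions are gated on the marker-B
# level: A is lost (A+ -> A-) only while B is positive, regained only while
# B is negative, and B+ is a rare level. Strongly violates marker
# independence in the transient the day-3/6/10 design samples.
gated_dependence_chain <- function() {
  states <- c("P1", "P2", "P3", "P4") # order: A+B+, A+B-, A-B+, A-B-
  P <- matrix(0, 4, 4, dimnames = list(states, states))
  b_down <- 0.10  # B+ -> B-
  b_up <- 0.005   # B- -> B+ (B+ rare at equilibrium)
  for (i in 1:4) {
    a_pos <- i %in% c(1, 2)
    b_pos <- i %in% c(1, 3)
    a_loss <- if (b_pos) 0.30 else 0     # A+ -> A- gated on B+
    a_gain <- if (b_pos) 0 else 0.01     # A- -> A+ gated on B-
    for (j in 1:4) {
      a_j <- j %in% c(1, 2)
      b_j <- j %in% c(1, 3)
      p_a <- if (a_pos) (if (a_j) 1 - a_loss else a_loss) else
        (if (a_j) a_gain else 1 - a_gain)
      p_b <- if (b_pos) (if (b_j) 1 - b_down else b_down) else
        (if (b_j) b_up else 1 - b_up)
      P[i, j] <- p_a * p_b
    }
  }
  P
}
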