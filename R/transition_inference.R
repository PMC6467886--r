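#' Estimate the raw n-th matrix root of a proportion matrix pair
#'
#' Solves `W0 %*% P^n = Wn` for the daily transition matrix by computing the
#' principal n-th root of `A = solve(W0) %*% Wn` via eigendecomposition: each
#' eigenvalue is taken to its principal complex n-th root and real parts are
#' kept, recording the largest discarded imaginary magnitude as a diagnostic.
#' The result is generally not yet stochastic; pass it to [regularize()].
#' When `A` is numerically defective (ill-conditioned eigenvector basis) the
#' estimate falls back to [fit_root_by_optimization()].
#'
#' @param W0 K x K proportion matrix at day 0 (the identity in the pure-start
#'   design; any invertible matrix is accepted, with a warning).
#' @param Wn K x K proportion matrix at day `n`.
#' @param n number of days between `W0` and `Wn` (>= 1).
#' @param fallback_seed seed for the optimization fallback.
#' @return a list of class `raw_root_matrix`: `values` (real K x K), `t` = n,
#'   `max_imaginary` discarded, `method` ("eigen" or "optimization").
#' @export
estimate_root <- function(W0, Wn, n, fallback_seed = 1L) {
  stopifnot(is.matrix(W0), is.matrix(Wn), all(dim(W0) == dim(Wn)))
  if (n < 1 || n != round(n)) stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  K <- nrow(W0)
  if (rcond(W0) < 1e-12) stop("W0 is singular", call. = FALSE)
  if (max(abs(W0 - diag(K))) > 1e-12) {
    warning("W0 is not the identity; using its inverse (non-standard design)",
            call. = FALSE)
  }
  A <- solve(W0, Wn)
  eg <- eigen(A)
  V <- eg$vectors
  diagonalizable <- rcond(V) > 1e-10
  if (diagonalizable) {
    root_vals <- as.complex(eg$values)^(1 / n)
    R <- V %*% diag(root_vals, K) %*% solve(V)
    values <- Re(R)
    max_imag <- max(abs(Im(R)))
    method <- "eigen"
  } else {
    fit <- fit_root_by_optimization(Wn, n, seed = fallback_seed)
    values <- unclass(fit$P)
    max_imag <- 0
    method <- "optimization"
  }
  dimnames(values) <- dimnames(Wn)
  structure(
    list(values = values, t = n, max_imaginary = max_imag, method = method),
    class = "raw_root_matrix"
  )
}

#' Regularize a raw root matrix into a stochastic transition matrix
#'
#' Entries are clipped to `[0, 1]` and each row is renormalized to sum 1. A
#' row whose clipped sum is 0 carries no evidence about exits from its state
#' and becomes the unit self-transition row. Already-stochastic input is a
#' fixed point; the operation is idempotent.
#'
#' @param raw a `raw_root_matrix` or a real square matrix.
#' @return K x K row-stochastic matrix (dimnames preserved).
#' @export
regularize <- function(raw) {
  M <- if (inherits(raw, "raw_root_matrix")) raw$values else raw
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("need a square matrix", call. = FALSE)
  if (any(!is.finite(M))) stop("non-finite entries", call. = FALSE)
  P <- pmin(pmax(M, 0), 1)
  rs <- rowSums(P)
  for (i in seq_len(nrow(P))) {
    if (rs[i] <= 0) {
      P[i, ] <- 0
      P[i, i] <- 1
    } else {
      P[i, ] <- P[i, ] / rs[i]
    }
  }
  dimnames(P) <- dimnames(M)
  assert_row_stochastic(P, what = "regularized matrix")
  P
}

#' Average transition-matrix estimates across measurement days
#'
#' Entrywise unweighted arithmetic mean of root estimates obtained at
#' different days, the final estimator of the daily transition matrix.
#'
#' @param estimates list of K x K row-stochastic matrices on the same state
#'   space.
#' @return K x K row-stochastic matrix.
#' @export
average_estimates <- function(estimates) {
  if (!is.list(estimates) || length(estimates) == 0) {
    stop("need at least one estimate", call. = FALSE)
  }
  dims <- vapply(estimates, function(m) dim(m), integer(2))
  if (any(dims != dims[1])) stop("estimates differ in shape", call. = FALSE)
  P <- Reduce(`+`, estimates) / length(estimates)
  assert_row_stochastic(P, what = "averaged estimate")
  P
}

#' Estimate the daily transition matrix from proportion matrices
#'
#' Full estimator: for each measurement day t with matrix W(t), compute the
#' regularized principal t-th root of W(t) (W(0) is the identity), then
#' average the per-day estimates unweighted.
#'
#' @param W_list named or unnamed list of proportion matrices; days are taken
#'   from each matrix's `t` attribute unless `days` is given.
#' @param days integer vector of measurement days matching `W_list`.
#' @param W0 optional non-identity day-0 matrix.
#' @return K x K row-stochastic matrix with attribute `diagnostics`: a
#'   data.frame of per-day `max_imaginary` and estimation `method`.
#' @export
estimate_transition_matrix <- function(W_list, days = NULL, W0 = NULL) {
  if (is.matrix(W_list)) W_list <- list(W_list)
  if (is.null(days)) {
    days <- vapply(W_list, function(W) {
      t <- attr(W, "t")
      if (is.null(t)) stop("no `days` given and matrix lacks a `t` attribute",
                           call. = FALSE)
      as.integer(t)
    }, integer(1))
  }
  stopifnot(length(days) == length(W_list))
  K <- nrow(W_list[[1]])
  if (is.null(W0)) {
    W0 <- diag(K)
    dimnames(W0) <- dimnames(W_list[[1]])
  }
  roots <- Map(function(W, t) estimate_root(W0, W, t), W_list, days)
  ests <- lapply(roots, regularize)
  P <- average_estimates(ests)
  attr(P, "diagnostics") <- data.frame(
    t = days,
    max_imaginary = vapply(roots, function(r) r$max_imaginary, numeric(1)),
    method = vapply(roots, function(r) r$method, character(1))
  )
  P
}

#' Fit a transition matrix root by projected gradient descent
#'
#' Minimizes the Frobenius norm of `P^n - Wn` over row-stochastic matrices by
#' gradient descent with per-row Euclidean projection onto the probability
#' simplex and backtracking line search. Serves as the estimation route when
#' the eigendecomposition root is unavailable (defective matrix) and as an
#' independent cross-check. Deterministic given `seed`.
#'
#' @param Wn K x K proportion matrix at day n.
#' @param n days (>= 1).
#' @param seed integer seed for the perturbed start.
#' @param max_iter,tol iteration cap and residual tolerance.
#' @return list with `P` (row-stochastic), `residual` (Frobenius norm),
#'   `iterations`, `converged`.
#' @export
fit_root_by_optimization <- function(Wn, n, seed = 1L, max_iter = 2000L,
                                     tol = 1e-12) {
  stopifnot(is.matrix(Wn), nrow(Wn) == ncol(Wn))
  if (n < 1 || n != round(n)) stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  K <- nrow(Wn)
  set.seed(seed)
  # start near the convex-combination guess I + (Wn - I)/n, perturbed
  P <- diag(K) + (Wn - diag(K)) / n + matrix(stats::runif(K * K, 0, 1e-3), K, K)
  P <- t(apply(P, 1, project_simplex))
  objective <- function(P) {
    R <- mat_power(P, n) - Wn
    sum(R^2)
  }
  gradient <- function(P) {
    R <- mat_power(P, n) - Wn
    G <- matrix(0, K, K)
    # d/dP ||P^n - W||^2 = 2 * sum_k (P^T)^k R (P^T)^(n-1-k)
    pows <- vector("list", n)
    pows[[1]] <- diag(K)
    if (n > 1) for (k in 2:n) pows[[k]] <- pows[[k - 1]] %*% P
    for (k in 0:(n - 1)) {
      G <- G + t(pows[[k + 1]]) %*% R %*% t(pows[[n - k]])
    }
    2 * G
  }
  f <- objective(P)
  step <- 1
  iter <- 0L
  while (iter < max_iter && f > tol) {
    iter <- iter + 1L
    G <- gradient(P)
    gnorm <- sqrt(sum(G^2))
    if (gnorm < 1e-15) break
    accepted <- FALSE
    for (bt in 1:40) {
      cand <- t(apply(P - step * G, 1, project_simplex))
      fc <- objective(cand)
      if (fc < f) {
        P <- cand
        f <- fc
        step <- step * 1.5
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  converged <- f <= tol
  if (!converged && f > 1e-6) {
    warning("optimization did not converge; returning best found (residual ",
            format(sqrt(f)), ")", call. = FALSE)
  }
  dimnames(P) <- dimnames(Wn)
  list(P = P, residual = sqrt(f), iterations = iter, converged = converged)
}

#' Extract the directed graph of occurring transitions
#'
#' Off-diagonal transition probabilities above the threshold `tau` become
#' directed edges i -> j weighted by the probability. With K states there are
#' K(K-1) possible direct transitions.
#'
#' @param P K x K row-stochastic transition matrix.
#' @param tau probability threshold (default 0 with a 1e-12 numerical floor).
#' @return object of class `transition_graph`: list with `nodes`, `edges`
#'   (data.frame from/to/weight), `tau`, `n_edges`, `n_possible`.
#' @export
extract_graph <- function(P, tau = 0) {
  assert_row_stochastic(P, what = "transition matrix")
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  tau_eff <- max(tau, 1e-12) # numerical floor over exact zeros
  K <- nrow(P)
  nodes <- rownames(P) %||% paste0("P", seq_len(K))
  idx <- which(P > tau_eff & row(P) != col(P), arr.ind = TRUE)
  edges <- data.frame(
    from = nodes[idx[, 1]],
    to = nodes[idx[, 2]],
    weight = P[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(match(edges$from, nodes), match(edges$to, nodes)), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges, tau = tau,
         n_edges = nrow(edges), n_possible = K * (K - 1L)),
    class = "transition_graph"
  )
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("Transition graph:", length(x$nodes), "states;",
      x$n_edges, "of", x$n_possible,
      "possible direct transitions occurring (tau =", x$tau, ")\n")
  invisible(x)
}

# Adjacency matrix (logical, no self-loops) of a transition graph.
graph_adjacency <- function(graph) {
  stopifnot(inherits(graph, "transition_graph"))
  K <- length(graph$nodes)
  A <- matrix(FALSE, K, K, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    A[cbind(match(graph$edges$from, graph$nodes),
            match(graph$edges$to, graph$nodes))] <- TRUE
  }
  A
}

#' Write a transition graph as a Graphviz DOT file
#'
#' @param graph a `transition_graph`.
#' @param path output path.
#' @param style_mutual if TRUE, mutual (reciprocated) edges are drawn in blue.
#' @export
write_graph_dot <- function(graph, path, style_mutual = FALSE) {
  A <- graph_adjacency(graph)
  lines <- c("digraph transitions {")
  for (k in seq_len(nrow(graph$edges))) {
    e <- graph$edges[k, ]
    mutual <- style_mutual && A[e$to, e$from]
    attrs <- sprintf("label=\"%.3g\"%s", e$weight,
                     if (mutual) ", color=blue" else "")
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [%s];", e$from, e$to, attrs))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
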