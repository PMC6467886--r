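# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-stochasticity check used by every consumer of a transition or
# proportion matrix. tol matches the contract on the containers.
assert_row_stochastic <- function(M, tol = 1e-9, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(M))) stop(what, " contains non-finite entries", call. = FALSE)
  if (any(M < -tol) || any(M > 1 + tol)) {
    stop(what, " has entries outside [0, 1]", call. = FALSE)
  }
  rs <- rowSums(M)
  if (any(abs(rs - 1) > tol)) {
    stop(what, " rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  invisible(TRUE)
}

is_row_stochastic <- function(M, tol = 1e-9) {
  is.matrix(M) && nrow(M) == ncol(M) && all(is.finite(M)) &&
    all(M >= -tol) && all(M <= 1 + tol) && all(abs(rowSums(M) - 1) <= tol)
}

# Matrix power by repeated multiplication (exactness over eigendecomposition
# for stochastic matrices; n is small, days-scale).
mat_power <- function(P, n) {
  stopifnot(n >= 0, n == round(n))
  K <- nrow(P)
  out <- diag(K)
  dimnames(out) <- dimnames(P)
  if (n == 0) return(out)
  base <- P
  m <- n
  while (m > 0) {
    if (m %% 2 == 1) out <- out %*% base
    base <- base %*% base
    m <- m %/% 2
  }
  out
}

# Euclidean projection of a vector onto the probability simplex
# (sort-based algorithm; O(K log K)). Used by the optimization fallback.
project_simplex <- function(v) {
  K <- length(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_len(K) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Total-variation distance between two compositions.
tv_distance <- function(x, y) 0.5 * sum(abs(x - y))

composition_distance <- function(x, y, metric = c("tv", "l1", "l2", "max")) {
  metric <- match.arg(metric)
  switch(metric,
    tv  = tv_distance(x, y),
    l1  = sum(abs(x - y)),
    l2  = sqrt(sum((x - y)^2)),
    max = max(abs(x - y))
  )
}

# Derive child seeds from a single master seed so that sub-runs are
# independently reproducible (documented splitting scheme: the master seed
# seeds one draw of n integers below 2^31).
split_seed <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
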