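#' Coarse-grain a proportion matrix to a single marker
#'
#' Collapses the K-state phenotype proportion matrix to a 2 x 2 matrix over
#' positive versus low/negative status of one marker: observed-state columns
#' sharing the marker sign are summed, and initial pure-start rows sharing the
#' sign are averaged unweighted (rows aggregate experiments, not cells).
#' Rows of the result sum to 1.
#'
#' @param W K x K proportion matrix (rows = initial pure states).
#' @param space a `state_space`.
#' @param marker marker name in `space$markers`.
#' @return 2 x 2 matrix with dimnames `<marker>+` / `<marker>-`, carrying the
#'   `t` attribute of `W`.
#' @export
coarse_grain_proportions <- function(W, space, marker) {
  stopifnot(inherits(space, "state_space"), is.matrix(W),
            all(dim(W) == space$K))
  pos <- marker_positive_states(space, marker)
  col_pos <- rowSums(W[, pos, drop = FALSE])
  col_neg <- rowSums(W[, !pos, drop = FALSE])
  labs <- paste0(marker, c("+", "-"))
  M <- matrix(c(mean(col_pos[pos]),  mean(col_neg[pos]),
                mean(col_pos[!pos]), mean(col_neg[!pos])),
              2, 2, byrow = TRUE, dimnames = list(labs, labs))
  assert_row_stochastic(M, what = "coarse-grained matrix")
  attr(M, "t") <- attr(W, "t")
  M
}

#' Test marker-wise independence of state transitions
#'
#' For each marker, estimates a 2-state transition chain from the
#' coarse-grained proportion matrices (same root / regularize / average
#' pipeline as the full model), computes its steady state, and compares it
#' with the marginal steady state of the full K-state chain (stationary mass
#' summed over states sharing the marker sign). Nearly equal proportions
#' indicate that transitions between the two levels of the marker are
#' independent of the remaining markers; large differences indicate
#' dependency. The `threshold` on the absolute difference that separates the
#' two verdicts is a reporting convention, not a significance test.
#'
#' @param W_list list of K x K proportion matrices over time (each with a `t`
#'   attribute, or supply `days`).
#' @param P_full K x K transition matrix estimated from the same data.
#' @param space a `state_space`.
#' @param days optional integer vector of measurement days.
#' @param threshold verdict threshold on the absolute steady-state difference
#'   (default 0.05).
#' @return object of class `marker_independence_report`: per-marker list with
#'   the 2 x 2 chain, its steady state, the marginalized full-model steady
#'   state, the absolute difference and a verdict; plus a summary data.frame.
#' @export
marker_independence_test <- function(W_list, P_full, space, days = NULL,
                                     threshold = 0.05) {
  stopifnot(inherits(space, "state_space"))
  if (is.matrix(W_list)) W_list <- list(W_list)
  if (is.null(days)) {
    days <- vapply(W_list, function(W) as.integer(attr(W, "t")), integer(1))
  }
  eq_full <- stationary_distribution(P_full)
  if (!eq_full$unique) {
    stop("full-model stationary distribution is not unique", call. = FALSE)
  }
  per_marker <- lapply(space$markers, function(mk) {
    W2 <- lapply(W_list, coarse_grain_proportions, space = space, marker = mk)
    P2 <- estimate_transition_matrix(W2, days = days)
    eq2 <- stationary_distribution(P2)
    if (!eq2$unique) {
      stop("coarse-grained stationary distribution not unique for marker ", mk,
           call. = FALSE)
    }
    pos <- marker_positive_states(space, mk)
    marginal <- stats::setNames(
      c(sum(eq_full$pi[pos]), sum(eq_full$pi[!pos])),
      paste0(mk, c("+", "-"))
    )
    diff <- abs(eq2$pi - marginal)
    list(marker = mk, P2 = P2, steady_state = eq2$pi, marginal = marginal,
         abs_difference = diff,
         verdict = if (max(diff) <= threshold) "independent" else "dependent")
  })
  names(per_marker) <- space$markers
  summary_df <- data.frame(
    marker = space$markers,
    steady_pos_2state = vapply(per_marker, function(r) r$steady_state[1], numeric(1)),
    steady_pos_marginal = vapply(per_marker, function(r) r$marginal[1], numeric(1)),
    abs_difference = vapply(per_marker, function(r) max(r$abs_difference), numeric(1)),
    verdict = vapply(per_marker, function(r) r$verdict, character(1)),
    row.names = NULL
  )
  structure(
    list(per_marker = per_marker, summary = summary_df, threshold = threshold),
    class = "marker_independence_report"
  )
}

#' @export
print.marker_independence_report <- function(x, ...) {
  cat("Marker independence (threshold", x$threshold, "on |steady-state difference|):\n")
  print(x$summary, digits = 4)
  invisible(x)
}
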