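# Reachability (transitive closure) of a transition graph, self-pairs
# excluded. Uses unweighted shortest-path existence.
reachability_matrix <- function(graph) {
  A <- graph_adjacency(graph)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  D <- igraph::distances(g, mode = "out", weights = NA)
  R <- is.finite(D)
  diag(R) <- FALSE
  R
}

#' Krackhardt hierarchy score of a transition graph
#'
#' Measures the degree of hierarchy of the directed transition structure as
#' `1 - p`, where p is the proportion of tied (ordered-unordered) state pairs
#' whose tie is reciprocated. In the default `reachability` mode dyads are
#' evaluated on the transitive closure: a pair \{i, j\} is tied when i reaches
#' j or j reaches i (directly or via intermediates), and reciprocated when
#' both hold. `direct` mode uses only direct edges. A perfect out-tree has no
#' reciprocated ties and scores 1; a structure in which every tied pair is
#' mutual (e.g. any strongly connected graph in reachability mode) scores 0.
#' Self-loops are ignored throughout.
#'
#' @param graph a `transition_graph` (see [extract_graph()]).
#' @param mode `"reachability"` (default) or `"direct"`.
#' @return object of class `hierarchy_report`: `score` (NA when the graph has
#'   no tied dyads), `p`, `mode`, `tied_dyads`, `reciprocated_dyads`.
#' @export
krackhardt_hierarchy <- function(graph, mode = c("reachability", "direct")) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "transition_graph"))
  if (length(graph$nodes) < 2) stop("graph needs at least 2 nodes", call. = FALSE)
  R <- if (mode == "reachability") reachability_matrix(graph) else {
    A <- graph_adjacency(graph)
    diag(A) <- FALSE
    A
  }
  up <- upper.tri(R)
  tied <- (R | t(R))[up]
  recip <- (R & t(R))[up]
  n_tied <- sum(tied)
  n_recip <- sum(recip)
  p <- if (n_tied == 0) NA_real_ else n_recip / n_tied
  structure(
    list(score = if (n_tied == 0) NA_real_ else 1 - p,
         p = p, mode = mode,
         tied_dyads = n_tied, reciprocated_dyads = n_recip),
    class = "hierarchy_report"
  )
}

#' @export
print.hierarchy_report <- function(x, ...) {
  if (is.na(x$score)) {
    cat("Krackhardt hierarchy undefined: no tied dyads (", x$mode, "mode )\n")
  } else {
    cat("Krackhardt hierarchy =", x$score, "(", x$reciprocated_dyads, "of",
        x$tied_dyads, "tied dyads reciprocated;", x$mode, "mode )\n")
  }
  invisible(x)
}

#' Dyad census of direct transitions
#'
#' Counts mutual (both directions present), asymmetric (exactly one) and null
#' (neither) unordered state pairs of the direct-edge structure; the three
#' counts sum to K(K-1)/2.
#'
#' @param graph a `transition_graph`.
#' @return named list `mutual`, `asymmetric`, `null`, `total_dyads`.
#' @export
reciprocity_summary <- function(graph) {
  stopifnot(inherits(graph, "transition_graph"))
  K <- length(graph$nodes)
  if (K < 2) stop("graph needs at least 2 nodes", call. = FALSE)
  A <- graph_adjacency(graph)
  diag(A) <- FALSE
  up <- upper.tri(A)
  mutual <- sum((A & t(A))[up])
  tied <- sum((A | t(A))[up])
  list(
    mutual = mutual,
    asymmetric = tied - mutual,
    null = K * (K - 1L) / 2L - tied,
    total_dyads = K * (K - 1L) / 2L
  )
}
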