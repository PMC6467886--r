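#' Build the marker-combination state space
#'
#' Enumerates the K = 2^m phenotypic states defined by positive (`+`) versus
#' low/negative (`-`) status of m binary cell-surface markers. States are
#' ordered lexicographically over sign vectors with the all-positive state
#' first and the last marker varying fastest, and labeled `P1`..`PK`. With the
#' four markers CD133, CD44, CD15 and A2B5 this yields the 16 subpopulations
#' P1-P16 commonly used to phenotype glioblastoma cultures.
#'
#' @param markers character vector of m unique marker names, 1 <= m <= 8.
#' @return An object of class `state_space`: a list with `markers`, `states`
#'   (the K labels), `signs` (K x m logical matrix, TRUE = positive) and `K`.
#' @examples
#' build_state_space(c("CD133", "CD44", "CD15", "A2B5"))
#' @export
build_state_space <- function(markers) {
  if (length(markers) < 1 || length(markers) > 8) {
    stop("between 1 and 8 markers are required", call. = FALSE)
  }
  markers <- as.character(markers)
  if (anyDuplicated(markers)) stop("marker names must be unique", call. = FALSE)
  m <- length(markers)
  K <- 2L^m
  # + encoded TRUE; all-positive first, last marker fastest
  signs <- as.matrix(expand.grid(rev(replicate(m, c(TRUE, FALSE), simplify = FALSE)),
                                 KEEP.OUT.ATTRS = FALSE))[, m:1, drop = FALSE]
  dimnames(signs) <- list(NULL, markers)
  states <- paste0("P", seq_len(K))
  rownames(signs) <- states
  structure(
    list(markers = markers, states = states, signs = signs, K = K),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space:", x$K, "states over", length(x$markers), "markers (",
      paste(x$markers, collapse = ", "), ")\n")
  lab <- apply(x$signs, 1, function(s) {
    paste0(x$markers, ifelse(s, "+", "-"), collapse = " ")
  })
  print(data.frame(state = x$states, phenotype = lab, row.names = NULL))
  invisible(x)
}

#' Human-readable sign labels for each state
#'
#' @param space a `state_space`.
#' @return named character vector, e.g. `P1 = "CD133+CD44+"`.
#' @export
state_sign_labels <- function(space) {
  stopifnot(inherits(space, "state_space"))
  out <- apply(space$signs, 1, function(s) {
    paste0(space$markers, ifelse(s, "+", "-"), collapse = "")
  })
  stats::setNames(out, space$states)
}

# Logical vector: which states are positive for `marker`.
marker_positive_states <- function(space, marker) {
  stopifnot(inherits(space, "state_space"))
  if (!marker %in% space$markers) {
    stop("unknown marker: ", marker, call. = FALSE)
  }
  space$signs[, marker]
}
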