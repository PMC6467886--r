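#' Read a long-format observation table
#'
#' Reads a CSV/TSV table of phenotyping observations with header columns
#' `condition, initial_state, time_days, observed_state, value` and an
#' optional `replicate` column. `value` holds either cell counts or fractions
#' in `[0, 1]`; percentages must be declared explicitly via `percent = TRUE`
#' (they are divided by 100), never auto-detected.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, otherwise CSV.
#' @param value_kind `"counts"` or `"fractions"`; `"auto"` treats the table as
#'   counts when any value exceeds 1 and as fractions otherwise.
#' @param percent if TRUE, values are percentages and divided by 100 (forces
#'   `value_kind = "fractions"`).
#' @return a data.frame of class `observation_table` with attribute
#'   `value_kind`.
#' @export
read_observation_table <- function(path, value_kind = c("auto", "counts", "fractions"),
                                   percent = FALSE) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_observation_table(df, value_kind = value_kind, percent = percent)
}

#' Validate a data.frame as an observation table
#'
#' @param df data.frame with the observation-table columns.
#' @inheritParams read_observation_table
#' @export
as_observation_table <- function(df, value_kind = c("auto", "counts", "fractions"),
                                 percent = FALSE) {
  value_kind <- match.arg(value_kind)
  required <- c("condition", "initial_state", "time_days", "observed_state", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (any(!is.finite(df$value))) stop("non-finite values in table", call. = FALSE)
  if (any(df$value < 0)) stop("negative values in table", call. = FALSE)
  # chain step is one day: fractional measurement days are rejected, not rounded
  if (any(df$time_days != round(df$time_days)) || any(df$time_days < 0)) {
    stop("time_days must be non-negative integers (1-day chain step)",
         call. = FALSE)
  }
  df$time_days <- as.integer(df$time_days)
  if (percent) {
    df$value <- df$value / 100
    value_kind <- "fractions"
  }
  if (value_kind == "auto") {
    value_kind <- if (any(df$value > 1)) "counts" else "fractions"
  }
  if (value_kind == "fractions") {
    if (any(df$value > 1 + 1e-9)) {
      stop("fractions exceed 1; use value_kind = 'counts' or percent = TRUE",
           call. = FALSE)
    }
    grp <- interaction(df$condition, df$initial_state, df$time_days,
                       df$replicate, drop = TRUE)
    sums <- tapply(df$value, grp, sum)
    if (any(abs(sums - 1) > 1e-6)) {
      stop("fractions do not sum to 1 within 1e-6 for every ",
           "(condition, initial_state, day, replicate) group", call. = FALSE)
    }
  }
  structure(df, class = c("observation_table", "data.frame"),
            value_kind = value_kind)
}

#' Write an observation table to CSV
#'
#' @param table an `observation_table` (or plain data.frame with its columns).
#' @param path output path.
#' @export
write_observation_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Turn a proportion matrix into long-format observation records
#'
#' Inverse of [build_proportion_matrix()] for round-tripping and for emitting
#' simulated data in the same dialect the reader accepts.
#'
#' @param W K x K proportion matrix with state dimnames.
#' @param t measurement day.
#' @param condition condition label.
#' @param replicate replicate id.
#' @return data.frame of observation records (fractions).
#' @export
observations_from_matrix <- function(W, t, condition = "cond", replicate = 1L) {
  stopifnot(is.matrix(W), !is.null(rownames(W)))
  data.frame(
    condition = condition,
    initial_state = rep(rownames(W), each = ncol(W)),
    time_days = as.integer(t),
    observed_state = rep(colnames(W), times = nrow(W)),
    value = as.vector(t(W)),
    replicate = replicate,
    stringsAsFactors = FALSE
  )
}

#' Assemble the phenotype proportion matrix W(t)
#'
#' Builds the K x K row-stochastic matrix whose row i is the observed state
#' composition at day `t` of a culture initiated as pure state i. Counts are
#' normalized to fractions per (initial state, replicate); replicates are then
#' averaged unweighted. Observed states absent from a present row count as 0.
#' The day-0 matrix of the pure-start design is the identity: requesting t = 0
#' with no day-0 records returns it.
#'
#' @param table an `observation_table` (see [as_observation_table()]).
#' @param space a `state_space`, or a bare character vector of state labels
#'   when only the ordering matters.
#' @param t measurement day (non-negative integer).
#' @param condition restrict to one condition label (required when the table
#'   holds several).
#' @return K x K matrix with state labels as dimnames and attributes `t` and
#'   `condition`; rows sum to 1.
#' @export
build_proportion_matrix <- function(table, space, t, condition = NULL) {
  if (is.character(space)) {
    # bare state labels are accepted wherever only the ordering matters
    space <- list(K = length(space), states = space, markers = character(0))
  } else {
    stopifnot(inherits(space, "state_space"))
  }
  if (t < 0 || t != round(t)) stop("t must be a non-negative integer", call. = FALSE)
  t <- as.integer(t)
  df <- as.data.frame(table)
  if (!is.null(condition)) {
    df <- df[df$condition == condition, , drop = FALSE]
  } else if (length(unique(df$condition)) > 1) {
    stop("table holds several conditions; pass `condition`", call. = FALSE)
  }
  df <- df[df$time_days == t, , drop = FALSE]
  K <- space$K
  if (t == 0L && nrow(df) == 0L) {
    W <- diag(K)
    dimnames(W) <- list(space$states, space$states)
    attr(W, "t") <- 0L
    attr(W, "condition") <- condition %||% NA_character_
    return(W)
  }
  unknown <- setdiff(unique(c(df$initial_state, df$observed_state)), space$states)
  if (length(unknown)) {
    stop("state labels not in the state space: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(df$value < 0)) stop("negative values", call. = FALSE)
  W <- matrix(NA_real_, K, K, dimnames = list(space$states, space$states))
  for (i in seq_len(K)) {
    st <- space$states[i]
    rows <- df[df$initial_state == st, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("no observations at day ", t, " for initial state ", st, call. = FALSE)
    }
    reps <- split(rows, rows$replicate)
    per_rep <- vapply(reps, function(r) {
      v <- stats::setNames(rep(0, K), space$states)
      v[r$observed_state] <- r$value
      tot <- sum(v)
      if (tot <= 0) stop("zero total for initial state ", st, " at day ", t,
                         call. = FALSE)
      v / tot
    }, numeric(K))
    W[i, ] <- rowMeans(per_rep)
  }
  assert_row_stochastic(W, what = "proportion matrix")
  attr(W, "t") <- t
  attr(W, "condition") <- condition %||% unique(df$condition)[1]
  W
}

#' Write a labeled matrix to CSV with a JSON metadata sidecar
#'
#' @param M matrix with dimnames.
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @param meta named list of extra metadata fields.
#' @export
write_matrix_csv <- function(M, path, meta = list()) {
  utils::write.csv(as.data.frame(M), path, row.names = TRUE, quote = FALSE)
  meta <- c(list(rows = rownames(M), cols = colnames(M),
                 t = attr(M, "t"), condition = attr(M, "condition")), meta)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a labeled matrix written by [write_matrix_csv()]
#' @param path CSV path.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Population doubling time
#'
#' Computes `(t2 - t1) / log2(n2 / n1)` from two census points of an
#' exponentially growing culture. A negative result (shrinking population) is
#' returned with a warning rather than an error.
#'
#' @param t1,t2 census days, `t2 > t1`.
#' @param n1,n2 cell numbers at `t1` and `t2`; both positive, `n1 != n2`.
#' @return doubling time in days.
#' @examples
#' doubling_time(0, 30, 300, 1200) # 15
#' @export
doubling_time <- function(t1, t2, n1, n2) {
  if (t2 <= t1) stop("t2 must exceed t1", call. = FALSE)
  if (n1 <= 0 || n2 <= 0) stop("cell numbers must be positive", call. = FALSE)
  if (n2 == n1) stop("doubling time undefined for equal cell numbers", call. = FALSE)
  dt <- (t2 - t1) / log2(n2 / n1)
  if (dt < 0) warning("negative doubling time: population shrank", call. = FALSE)
  dt
}
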