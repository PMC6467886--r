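#' Validate and normalize a pipeline run configuration
#'
#' A configuration is a named list (or a YAML/JSON file path) with fields:
#' `input` (observation CSV/TSV path), `markers` (marker names defining the
#' state space), `days` (measurement days), and optional `condition`,
#' `value_kind`, `percent`, `tau` (transition threshold), `eps`, `metric`,
#' `t_max` (equilibrium settings), `independence_threshold`, `seed`,
#' `out_dir`. Unknown fields are rejected; defaulted fields are filled in so
#' the fully resolved configuration can be serialized for provenance.
#'
#' @param config named list or path to a YAML/JSON file.
#' @return the resolved configuration list, with attribute `hash` (MD5 of its
#'   canonical JSON serialization).
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a file path", call. = FALSE)
  allowed <- c("input", "markers", "days", "condition", "value_kind", "percent",
               "tau", "eps", "metric", "t_max", "independence_threshold",
               "seed", "out_dir")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (req in c("input", "markers", "days")) {
    if (is.null(config[[req]])) stop("config field missing: ", req, call. = FALSE)
  }
  defaults <- list(condition = NULL, value_kind = "auto", percent = FALSE,
                   tau = 0, eps = 0.01, metric = "tv", t_max = 1000L,
                   independence_threshold = 0.05, seed = 1L, out_dir = ".")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[nm] <- list(defaults[[nm]])
  }
  if (any(config$days <= 0) || any(config$days != round(config$days))) {
    stop("days must be positive integers", call. = FALSE)
  }
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA, null = "null")
  attr(config, "hash") <- unname(tools::md5sum(tf))
  config
}

#' Run the full state-transition analysis pipeline
#'
#' Orchestrates every stage over one observation table: read and validate the
#' input, assemble the phenotype proportion matrices, estimate the daily
#' transition matrix (root / regularize / average), extract the transition
#' graph, classify states, compute the stationary composition and the
#' per-pure-start relaxation times, score Krackhardt hierarchy (both modes),
#' and run the marker-independence analysis. All artifacts are written under
#' `out_dir` with the resolved configuration and its hash embedded for
#' provenance.
#'
#' @param config a configuration list or file path (see [load_run_config()]).
#' @return (invisibly) a list with all computed objects: `space`, `W_list`,
#'   `P`, `graph`, `classification`, `equilibrium`, `relaxation` (data.frame),
#'   `hierarchy`, `independence`, `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- build_state_space(cfg$markers)

  table <- read_observation_table(cfg$input, value_kind = cfg$value_kind,
                                  percent = cfg$percent)
  W_list <- lapply(cfg$days, function(t) {
    build_proportion_matrix(table, space, t = t, condition = cfg$condition)
  })
  P <- estimate_transition_matrix(W_list, days = cfg$days)
  graph <- extract_graph(P, tau = cfg$tau)
  classification <- classify_states(P, tau = cfg$tau)
  equilibrium <- stationary_distribution(P, tau = cfg$tau)

  relaxation <- NULL
  if (equilibrium$unique) {
    rel <- lapply(seq_len(space$K), function(i) {
      x0 <- replace(rep(0, space$K), i, 1)
      time_to_equilibrium(P, x0, eps = cfg$eps, metric = cfg$metric,
                          t_max = cfg$t_max)
    })
    relaxation <- data.frame(
      initial_state = space$states,
      days = vapply(rel, function(r) as.numeric(r$days %||% NA), numeric(1)),
      reached = vapply(rel, function(r) r$reached, logical(1)),
      last_distance = vapply(rel, function(r) r$distance, numeric(1))
    )
  }

  hierarchy <- list(
    reachability = krackhardt_hierarchy(graph, mode = "reachability"),
    direct = krackhardt_hierarchy(graph, mode = "direct"),
    reciprocity = reciprocity_summary(graph)
  )
  independence <- if (equilibrium$unique) {
    marker_independence_test(W_list, P, space, days = cfg$days,
                             threshold = cfg$independence_threshold)
  } else NULL

  write_pipeline_outputs(cfg, space, W_list, P, graph, classification,
                         equilibrium, relaxation, hierarchy, independence)
  invisible(list(space = space, W_list = W_list, P = P, graph = graph,
                 classification = classification, equilibrium = equilibrium,
                 relaxation = relaxation, hierarchy = hierarchy,
                 independence = independence, config = cfg))
}

write_pipeline_outputs <- function(cfg, space, W_list, P, graph, classification,
                                   equilibrium, relaxation, hierarchy,
                                   independence) {
  out <- function(f) file.path(cfg$out_dir, f)
  hash <- attr(cfg, "hash")
  meta <- list(config = cfg[order(names(cfg))], config_hash = hash)

  write_matrix_csv(P, out("transition_matrix.csv"),
                   meta = c(meta, list(diagnostics = attr(P, "diagnostics"))))
  utils::write.csv(graph$edges, out("transition_graph_edges.csv"),
                   row.names = FALSE, quote = FALSE)
  write_graph_dot(graph, out("transition_graph.dot"), style_mutual = TRUE)
  if (!is.null(relaxation)) {
    utils::write.csv(relaxation, out("relaxation_times.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  report <- list(
    config_hash = hash,
    config = cfg[order(names(cfg))],
    n_states = space$K,
    transitions_occurring = graph$n_edges,
    transitions_possible = graph$n_possible,
    irreducible = classification$irreducible,
    transient_states = classification$transient_states,
    absorbing_states = names(which(classification$absorbing)),
    stationary_unique = equilibrium$unique,
    stationary = if (equilibrium$unique) as.list(equilibrium$pi) else NULL,
    hierarchy = list(
      reachability = hierarchy$reachability[c("score", "p", "tied_dyads",
                                              "reciprocated_dyads")],
      direct = hierarchy$direct[c("score", "p", "tied_dyads",
                                  "reciprocated_dyads")],
      reciprocity = hierarchy$reciprocity
    ),
    eps = cfg$eps, metric = cfg$metric
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(independence)) {
    utils::write.csv(independence$summary, out("marker_independence.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  lines <- c(
    paste0("state-transition analysis (config ", hash, ")"),
    paste0("states: ", space$K, " (markers: ",
           paste(space$markers, collapse = ", "), ")"),
    paste0("direct transitions occurring: ", graph$n_edges, " of ",
           graph$n_possible),
    paste0("chain: ", if (classification$irreducible) "irreducible" else "reducible"),
    paste0("transient states: ",
           if (length(classification$transient_states))
             paste(classification$transient_states, collapse = ", ") else "none"),
    paste0("absorbing states: ",
           if (any(classification$absorbing))
             paste(names(which(classification$absorbing)), collapse = ", ")
           else "none"),
    paste0("Krackhardt hierarchy (reachability): ",
           format(hierarchy$reachability$score)),
    paste0("Krackhardt hierarchy (direct): ", format(hierarchy$direct$score))
  )
  if (!is.null(relaxation)) {
    lines <- c(lines, paste0("relaxation times (days, eps = ", cfg$eps, " ",
                             cfg$metric, "): ",
                             paste(ifelse(relaxation$reached,
                                          relaxation$days,
                                          paste0("> ", cfg$t_max)),
                                   collapse = ", ")))
  }
  writeLines(lines, out("summary.txt"))
  invisible(NULL)
}
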