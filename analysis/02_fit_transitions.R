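#!/usr/bin/env Rscript
# Stage 2: estimate the daily transition matrices.
#
# For each condition the phenotype proportion matrices W(t) are assembled
# from the observation tables, the principal t-th matrix root of each W(t)
# is regularized to a stochastic matrix, and the per-day estimates are
# averaged (normoxia: days 20/30/70; hypoxia: the single day-60 estimate).
# The estimates are scored against the stored ground truths and the
# thresholded transition graphs are exported.

suppressPackageStartupMessages(library(phenflux))

dat <- "results/data"
out <- "results"
space <- build_state_space(c("CD133", "CD44", "CD15", "A2B5"))

fit_condition <- function(name, days) {
  tab <- read_observation_table(file.path(dat, paste0(name, "_observations.csv")),
                                value_kind = "counts")
  W_list <- lapply(days, function(t) build_proportion_matrix(tab, space, t))
  P_hat <- estimate_transition_matrix(W_list, days = days)
  P_true <- read_matrix_csv(file.path(dat, paste0(name, "_P_true.csv")))
  g <- extract_graph(P_hat, tau = 0.001) # drop sub-0.1% estimation noise
  write_matrix_csv(P_hat, file.path(out, paste0(name, "_P_hat.csv")))
  utils::write.csv(g$edges, file.path(out, paste0(name, "_graph_edges.csv")),
                   row.names = FALSE, quote = FALSE)
  write_graph_dot(g, file.path(out, paste0(name, "_graph.dot")),
                  style_mutual = TRUE)
  cat(sprintf("%s: mean |P_hat - P_true| = %.4f (max %.4f); %d of %d direct transitions occurring\n",
              name, mean(abs(P_hat - P_true)), max(abs(P_hat - P_true)),
              g$n_edges, g$n_possible))
  invisible(P_hat)
}

fit_condition("normoxia", c(20L, 30L, 70L))
fit_condition("hypoxia", 60L)
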