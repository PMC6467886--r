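#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Two culture conditions over the 16 CD133/CD44/CD15/A2B5 phenotypes:
#   - "normoxia": a fully plastic (irreducible) ground-truth chain, pure-start
#     multipotency design re-phenotyped at days 20/30/70;
#   - "hypoxia": a reducible ground truth with one transient state (no other
#     state can enter it, it keeps exits), one measurement at day 60.
# Per-cell simulation, 1e5 cells phenotyped per measurement. Ground truths
# are serialized so later stages can score recovery.

suppressPackageStartupMessages(library(phenflux))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

space <- build_state_space(c("CD133", "CD44", "CD15", "A2B5"))

normoxia <- generate_ground_truth(space$K, "irreducible", seed = 2026)
hypoxia <- generate_ground_truth(space$K, "with-transient", seed = 2027)

sim_n <- simulate_experiment(normoxia, design = "pure-start",
                             days = c(20L, 30L, 70L), n_cells = 1e5,
                             mode = "per-cell", seed = 11,
                             condition = "normoxia")
sim_h <- simulate_experiment(hypoxia, design = "pure-start", days = 60L,
                             n_cells = 1e5, mode = "per-cell", seed = 12,
                             condition = "hypoxia")

write_observation_table(sim_n$table, file.path(out, "normoxia_observations.csv"))
write_observation_table(sim_h$table, file.path(out, "hypoxia_observations.csv"))
write_matrix_csv(normoxia$P_true, file.path(out, "normoxia_P_true.csv"))
write_matrix_csv(hypoxia$P_true, file.path(out, "hypoxia_P_true.csv"))

cat("normoxia: ", nrow(sim_n$table), "records over days 20/30/70\n")
cat("hypoxia:  ", nrow(sim_h$table), "records at day 60; transient state:",
    hypoxia$states[hypoxia$transient_state], "\n")
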