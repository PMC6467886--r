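# phenflux

Markov chain inference of phenotypic cell-state transitions from
time-resolved proportion data of sorted subpopulations.

## The problem

Tumor cell populations phenotyped with a panel of m binary cell-surface
markers (e.g. CD133/CD44/CD15/A2B5 in glioblastoma cultures) distribute over
K = 2^m states (P1–P16 for four markers). When each subpopulation is sorted
to purity and re-phenotyped after weeks in culture, every one of them
reconstitutes the full heterogeneity — evidence of plasticity rather than a
fixed hierarchy. phenflux quantifies that plasticity. It is aimed at
experimentalists and modelers with post-gating FACS proportion or count
tables who want the transition probabilities behind them, and at anyone
studying the identifiability of such estimates by simulation.

## The model and estimator

A discrete-time Markov chain with a 1-day step: a cell in state i is in
state j one day later with probability `P[i, j]`, independent of its
history, with proliferation assumed equal across states. The pure-start
design gives phenotype proportion matrices `W(t)` (row i = composition at
day t of the culture started pure in state i; `W(0) = I`), connected by

    W(0) P^n = W(n)   =>   P_hat(n) = ( W(0)^{-1} W(n) )^{1/n}

Each measurement day yields a principal matrix n-th root (eigendecomposition;
projected-gradient fallback for defective cases), regularized to a
stochastic matrix (clip to [0, 1], renormalize rows, zero rows become unit
self-transitions) and averaged across days. On top of the estimated chain
the package computes:

* the **stationary composition** π (πP = π) — the predicted equilibrium
  heterogeneity — and the **relaxation time** from any initial composition
  (first day within a total-variation tolerance of π);
* **state classification**: transient / recurrent / absorbing states,
  irreducibility (the signature of fully reversible, non-hierarchical
  transitions);
* the **Krackhardt hierarchy score** `1 − p` of the transition graph
  (p = proportion of tied dyads reciprocated; 1 for a perfect tree, 0 for a
  strongly connected graph);
* a per-marker **independence test** comparing coarse-grained 2-state
  chains with the marginalized full-model steady state;
* a seeded **synthetic-data generator** (ground-truth chains of several
  structural classes, per-cell simulation with optional state-specific
  doubling times, multinomial phenotyping) and a parameter-recovery
  benchmark.

## Worked example

Simulate the 16-state pure-start design (per-cell, 1e5 cells phenotyped at
days 20/30/70), estimate the chain, and interrogate it:

```r
library(phenflux)
space <- build_state_space(c("CD133", "CD44", "CD15", "A2B5"))
model <- generate_ground_truth(space$K, "irreducible", seed = 2026)
sim <- simulate_experiment(model, design = "pure-start", days = c(20L, 30L, 70L),
                           n_cells = 1e5, mode = "per-cell", seed = 11)
W <- lapply(c(20L, 30L, 70L), function(t) build_proportion_matrix(sim$table, space, t))
P <- estimate_transition_matrix(W, days = c(20L, 30L, 70L))
round(P[1:4, 1:4], 4)
#>        P1     P2     P3     P4
#> P1 0.9531 0.0032 0.0009 0.0033
#> P2 0.0000 0.9507 0.0029 0.0057
#> P3 0.0093 0.0017 0.9498 0.0020
#> P4 0.0047 0.0042 0.0001 0.9548
```

The diagonal dominates: cells keep their phenotype with ~95% probability
per day and leak a fraction of a percent into each other state. The graph
of occurring transitions, its hierarchy, and the equilibrium:

```r
g <- extract_graph(P, tau = 0.001)
g
#> Transition graph: 16 states; 184 of 240 possible direct transitions occurring (tau = 0.001 )
krackhardt_hierarchy(g)
#> Krackhardt hierarchy = 0 ( 120 of 120 tied dyads reciprocated; reachability mode )
round(head(stationary_distribution(P)$pi, 4), 4)
#>     P1     P2     P3     P4
#> 0.0662 0.0706 0.0563 0.0621
time_to_equilibrium(P, replace(rep(0, 16), 1, 1))
#> Equilibrium ( tv < 0.01 ) reached after 97 days
```

A hierarchy score of 0 with an irreducible chain means every state can
(re)generate every other — no hierarchy, fully reversible plasticity; the
pure P1 culture needs ~97 days to come within 1% total variation of the
equilibrium composition. The estimate here deviates from the known
ground-truth matrix by at most 5.5e-4 per entry.

The numbered scripts under `analysis/` run the same machinery as a
narrative workflow — simulation of a plastic (normoxia-like) and a
reducible one-transient-state (hypoxia-like) condition, transition fitting,
equilibrium/relaxation analysis, hierarchy and marker-independence scoring,
and a recovery benchmark — writing tables under `results/`.

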