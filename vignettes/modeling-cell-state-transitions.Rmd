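---
title: "Markov modeling of phenotypic cell-state transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov modeling of phenotypic cell-state transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenflux)
```

## The model

Tumor cell populations phenotyped by a panel of m binary cell-surface
markers occupy one of K = 2^m states (with CD133/CD44/CD15/A2B5, the 16
subpopulations P1–P16). phenflux models the day-scale dynamics of such a
population as a discrete-time Markov chain: each cell switches state once
per day with probabilities that depend only on its current state (and on
the fixed environmental condition under which the experiment is run). The
assumptions this rests on:

* **Memorylessness.** A cell's next state depends on its current phenotype
  only, not on its history.
* **Equal proliferation.** All states divide at approximately the same
  rate, so composition changes are attributed to switching, not selection.
  The simulator can violate this deliberately (state-specific doubling
  times) to study the resulting bias.
* **No cell–cell interaction and no spatial structure.** Transition
  probabilities are constants, not functions of the current composition.

The data are phenotype proportion matrices `W(t)`: row i is the observed
composition, at day t, of a culture initiated as pure state i. At day 0 the
pure-start design makes `W(0)` the K×K identity.

## Estimating the daily transition matrix

Markov chain theory connects the snapshots: `W(0) P^n = W(n)`, so each
measurement day n yields an estimate

    P_hat(n) = ( W(0)^{-1} W(n) )^{1/n}

computed as the principal n-th matrix root via eigendecomposition: each
eigenvalue is taken to its principal complex n-th root, the matrix is
reassembled, and real parts are kept (the largest discarded imaginary
magnitude is recorded as a diagnostic — it is tiny when the model fits).
Raw roots need not be stochastic; `regularize()` clips entries to [0, 1]
and renormalizes each row. A row whose clipped sum is zero carries no
evidence and becomes a unit self-transition. Per-day estimates from several
measurement days are averaged entrywise with equal weight
(`estimate_transition_matrix()`); with three days 20/30/70 this is the mean
of three regularized roots.

When the intermediate matrix is numerically defective (ill-conditioned
eigenvector basis, `rcond < 1e-10`), estimation falls back to a projected
gradient descent minimizing ‖P^n − W(n)‖_F over row-stochastic matrices
(`fit_root_by_optimization()`), with per-row Euclidean projection onto the
probability simplex, backtracking line search, and a seeded start — the
same routine doubles as an independent cross-check of the eigen route.

**Identifiability limit.** An eigenvalue λ of P contributes λ^n to W(n);
once λ^n falls below the floating-point resolution of the matrix entries
(λ ≈ 0.3 already gives λ^24 ≈ 1e-13) its root carries no recoverable
information, and no estimator can reconstruct it from W(n) alone. Recovery
tests therefore use lazy chains (diagonal-dominant, eigenvalues ≥ 0.6),
which is also the biologically relevant regime: day-scale phenotype data
with switching probabilities of a few percent per day.

## Equilibrium, relaxation, classification

The stationary composition π solves πP = π (`stationary_distribution()`,
via the least-squares solution of the stationarity system with the sum
constraint; a power-iteration oracle confirms it in the tests). For
reducible chains with several closed recurrent classes the stationary
distribution is not unique; all extremal solutions are reported and the
result is flagged.

`predict_composition()` propagates any composition forward by repeated
vector–matrix multiplication, which preserves simplex membership exactly —
preferred over eigendecomposition for that reason. `time_to_equilibrium()`
returns the smallest integer day at which the propagated composition is
within `eps` of π. Defaults: total variation distance and `eps = 0.01`; the
experimental literature states no metric or tolerance for "approximate
equilibrium", so both are explicit parameters recorded in every output.
Relaxation times are integers because the chain's step is one day; no
interpolation is attempted. Periodic chains (possible only when regularized
diagonals are exactly zero) are refused rather than summarized by Cesàro
averages, and runs that exceed `t_max` report "not reached" together with
the last distance, so a "> 250 days" statement is always distinguishable
from non-convergence of the computation.

`classify_states()` decomposes the thresholded transition graph into
strongly connected components: states in non-closed components are
transient, closed components are recurrent classes, and a state is
absorbing when its self-transition exceeds `1 − tau_abs` (default
`tau_abs = 1e-9`, an explicit tolerance because regularized matrices are
floating-point) with no exit above the edge threshold. An irreducible chain
— every state reachable from every other — is the non-hierarchical,
fully reversible regime.

`design_admixture()` searches the simplex (seeded uniform-Dirichlet draws,
plus π and all pure states as candidates) for an initial mixture whose
relaxation time is closest to a target; ties resolve to the first candidate
in draw order, and the achieved time is always reported next to the target.

## Hierarchy scoring

The Krackhardt hierarchy of the transition graph is `1 − p`, with p the
proportion of tied dyads that are reciprocated. Two readings of "tied" are
implemented. The default `reachability` mode evaluates dyads on the
transitive closure, which is the convention of the classical R
implementation of the measure: a strongly connected graph scores 0, a
perfect out-tree scores 1, and a 16-state chain with a single
enter-proof state scores exactly 0.125 (15 of 120 dyads non-reciprocated).
`direct` mode uses only direct edges; both are reported by the pipeline
because the verbal definition of the measure admits either. A graph with no
ties at all has an undefined score, returned as `NA`. Self-loops are
excluded throughout: hierarchy concerns order between states.

The edge threshold `tau` defaults to 0 with a `1e-12` numerical floor —
"occurring" transitions are the nonzero entries after regularization — and
is exposed everywhere because printed analyses rarely state it.

## Marker independence

To ask whether transitions of one marker depend on the others, the K-state
data are coarse-grained per marker: observed-state columns sharing the
marker sign are summed, initial pure-start rows sharing the sign are
averaged with equal weight (rows aggregate experiments, not cells — cell
numbers are equalized by sorting, so the unweighted mean is the defensible
aggregation). The resulting 2×2 proportion matrices go through the same
root/regularize/average pipeline, and the 2-state chain's steady state is
compared with the marginalized steady state of the full model. For a chain
that is exactly a Kronecker product of independent per-marker chains the
difference vanishes; gated dependencies (a marker switching only at one
level of another) separate clearly. The default verdict threshold of 0.05
absolute difference is a labeled reporting convention, not a significance
test — no sampling distribution is attached to it.

A caveat the tests make explicit: because the stationary distribution of a
2×2 chain is invariant under matrix powers, coarse-grained matrices taken
*at* equilibrium always agree with the marginal steady state. The
discrimination power of the test lives in measurement days that sample the
transient, which is where the package's dependence fixtures place them.

## The synthetic-data generator

`generate_ground_truth()` draws seeded K-state chains of four structural
classes — irreducible (fully plastic), tree hierarchy (perfect lineage),
with-transient (one state no other state can enter, with exits and no
absorbing state), and Kronecker-independent (product of per-marker 2-state
chains). `simulate_experiment()` then emulates the pure-start multipotency
design: every state sorted to purity, cultured, and re-phenotyped at chosen
days (defaults 20/30/70, the normoxia design), or an admixture start.

* **Expected mode** produces the exact propagated fractions — useful for
  noiseless identifiability tests.
* **Per-cell mode** advances every cell daily: optional division with
  probability `2^(1/d_i) − 1` (state-specific doubling time d_i), then a
  draw from the cell's transition row; division precedes transition within
  a day, a fixed documented order since the verbal model has none.
  Phenotyping draws `n_cells` without replacement from the harvest
  (multivariate hypergeometric; all cells when fewer), mimicking FACS
  counting of a finite sample.

Defaults and why: `self_mass = 0.95` bounds daily switching at 5%, placing
bulk relaxation near 50 days and pure-start relaxation near 100 days — the
weeks-to-months re-equilibration scale reported for marker-sorted glioma
cultures, and the regime in which a day-20/30/70 design carries
information. `n_cells = 1e5` reflects a routine FACS acquisition; the
initial census defaults to the same value so the phenotyped sample never
exceeds the harvest when proliferation is off.

All randomness flows from one master seed through a documented split (the
seed generates one vector of per-culture seeds), so any single culture can
be re-simulated independently.

What the generator does **not** emulate: spatial/sphere structure and
cell–cell interactions, death as distinct from net growth, instrument noise
beyond finite-sample counting, and gating uncertainty. Multinomial counting
is the minimal noise stand-in. Passing recovery tests therefore show that
the estimator inverts the model class it assumes at realistic sampling
depth — not that real flow-cytometry data satisfy that model class.

`recovery_benchmark()` wires the generator to the full pipeline and scores
mean/max absolute error of the estimated matrix and the total-variation
error of the stationary composition. On noiseless expected-mode data the
pipeline is exact to numerical precision; at 1e5 cells per measurement the
mean entry error is ~1e-4 and shrinks with cell number; deliberately
unequal doubling times reintroduce bias, quantifying the cost of the
equal-proliferation assumption.

## Problem sizes

The test-suite and workflow use K ≤ 16 states, horizons to 70 days,
1e3–1e5 phenotyped cells, and five simulation seeds for stochastic
recovery summaries; the root-estimation oracle runs 100 random chains at
K ≤ 6 and n ≤ 30. These sizes match the experimental design the package
models (16 subpopulations, three measurement days) and keep every analysis
reproducible on a laptop in seconds.

## Known limitations

* The estimator assumes time-homogeneity; a chain drifting across the
  measurement window biases the averaged roots toward a compromise matrix.
* The matrix root is computed from averaged proportions; no uncertainty is
  propagated (no bootstrap or posterior — deliberately out of scope).
* Eigenvalues whose n-th powers underflow are unidentifiable from late
  snapshots (see above); very fast-switching subpopulations need early
  measurement days.
* The marker-independence verdict threshold is a convention; treat the
  reported differences, not the verdict strings, as the result.
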