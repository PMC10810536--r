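# targetctrl

Gramian-based target controllability analysis for **effective connectivity
(EC)** networks of brain regions.

## The problem

Resting-state fMRI can be fit with a linear latent model `dx/dt = A x + noise`,
where `A` is a signed, *asymmetric* effective connectivity matrix: `A[i, j]`
is the directed influence of region `j` on region `i` (units 1/TR). Network
control theory then asks: if external input (e.g. neurostimulation) is applied
at a few *driver* nodes — columns of an input matrix `B` in
`dx/dt = A x + B u(t)` — how expensive is it to steer the activity of a chosen
set of *target* regions, and which drivers should be picked?

The machinery is the controllability Gramian of the stable system,

```
W = ∫₀^∞ e^{At} B Bᵀ e^{Aᵀt} dt   (solves A W + W Aᵀ + B Bᵀ = 0)
```

with target (output) controllability read off the principal submatrix
`W_C = C W Cᵀ` on the target rows. Worst-case control energy for unit-norm
boundary states is `1/λ_min(W_C)`; for one driver `i` and one target `j` it
collapses to `E_{i→j} = 1 / W^{(i)}_{jj} = 1 / ∫ [e^{At}]²_{ji} dt`. A Gramian
whose minimum eigenvalue falls below `ε = 1e-12` is flagged *not practically
controllable* (energy `+Inf`).

On top of this core the package provides:

* a **synthetic cohort generator** for stable, signed, sparse EC matrices
  (74 nodes in 8 resting-state networks by default, link density ≈ 0.39,
  ≈ 60/40 positive/negative links, calibrated inter-subject correlation),
  with model functional connectivity derived from the stationary Lyapunov
  covariance;
* **driver centralities** — in-/out-strength, their ratio, PageRank on the
  binarized graph, the Gramian-trace `pq` centrality (which scales exactly as
  accessibility `β²`), and energy centralities `E_i^d`, `E_i^t`;
* **driver selection**: rankings, target-excluded selection, random baselines
  and z-scores, per-target-set optimal-centrality identification, group rank
  aggregation, Fisher-exact RSN enrichment with BH-FDR;
* **experiments**: energy scaling versus driver/target counts, pairwise-energy
  correlates (direct links, propagator `e^{AT}`, shortest paths, FC), hub and
  consistency analyses, RSN control tables, perturbation sensitivity, and
  accessibility-weighted control, all orchestrated by `run_all()` and a small
  CLI (`exec/targetctrl`).

## Worked example

```r
library(targetctrl)

cfg <- generator_config(n_nodes = 74, n_subjects = 5, seed = 1)
co  <- generate_cohort(cfg)
ec  <- co$subjects[[1]]
ec
#> <tc_ec> subject 'sub-001': 74 nodes, density 0.383, spectral abscissa -0.05 (TR = 1.40s)

E <- pairwise_energies(ec)          # E[i, j] = energy to control j from i alone
range(log10(E[is.finite(E)]))
#> -0.22  4.55                        # single-pair control spans ~5 decades

tab <- centrality_table(ec, with_fc = TRUE)
head(tab[order(tab$driver_energy),
         c("node_id", "out_strength", "pq", "driver_energy", "target_energy")], 3)
#>    node_id out_strength     pq driver_energy target_energy
#> 43      42        7.135  3.875        36.147        96.355
#> 55      54        6.906  2.718        40.966       102.875
#> 21      20        9.518 13.551        53.303      1225.356
# the cheapest drivers are out-hubs: large total outgoing influence

oc <- optimal_centrality(co, targets = which(co$nodes$rsn == "VIS"), n_d = 5)
oc$name
#> "pagerank"
round(oc$mean_log10_energy, 3)
#> driver_energy  out_strength            pq         ratio      pagerank
#>         2.962         2.918         2.984         2.827         2.820
# mean log10 worst-case energy to control the visual network with 5 remote
# drivers, per candidate ranking; the winner is returned with the full table

g <- controllability_gramian(ec, matrix(1, 74, 1))   # one broadcast input
g$lambda_min; g$practically_controllable
#> -5.6e-13
#> FALSE      # Kalman-controllable in theory, useless in practice
```

## Layout

* `R/` — generator (`generator.R`), dynamics/FC (`dynamics.R`), Lyapunov and
  Gramian core (`lyapunov.R`, `gramian.R`), centralities, selection,
  experiments, CLI.
* `vignettes/targetctrl-methods.Rmd` — model, assumptions, numerical choices,
  and what the synthetic cohorts do and do not establish.
* `tests/testthat/` — oracle-backed unit, property and acceptance suites.
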