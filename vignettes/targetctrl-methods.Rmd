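---
title: "targetctrl: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{targetctrl: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the model and its
assumptions, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator emulates (and deliberately does not), and
the numerical and design decisions made where the design was genuinely open.
It states no empirical result that the test suite does not itself compute.

## The model

Regional brain activity at rest is modeled as a stable linear time-invariant
system

$$\dot{x}(t) = A\,x(t) + \nu(t),$$

where $A$ is the **effective connectivity** (EC) matrix: $A_{ij}$ is the
directed influence of region $j$ on region $i$, in units of inverse
repetition time (1/TR). Unlike structural or functional connectivity, $A$ is
signed (excitatory and inhibitory couplings) and asymmetric (in- and
out-connections differ), and it has strictly negative diagonal entries — the
self-decay that makes the dynamics Hurwitz. Stability is not incidental: the
infinite-horizon controllability Gramian only exists for Hurwitz $A$, and all
the analyses here live in that regime.

Control enters through a driver set: $\dot{x} = A x + B u$, with one column
of $B$ per driver node. The worst-case energy to steer unit-norm states is
$1/\lambda_{\min}(W)$ with $W$ the Gramian $\int_0^\infty e^{At} B B^\top
e^{A^\top t}\,dt$; for targeted control of an output $y = C x$ the relevant
object is the projected Gramian $C W C^\top$, and for one driver $i$ and one
target $j$ the energy collapses to $E_{i\to j} = 1/W^{(i)}_{jj}$. This last
identity is what makes cohort-scale pairwise analyses cheap: $n$ Lyapunov
solves instead of $n^2$ integrals, and in this implementation a single
spectral factorization of $A$ shared by all $n$ drivers.

Time is measured in TR units throughout; `tr_seconds` (default 1.4 s) is
carried on each subject purely for reporting.

## Numerical choices

**Lyapunov solves.** `lyap_solve()` dispatches between two routes. The fast
route diagonalizes $A = V D V^{-1}$ and solves elementwise in the eigenbasis;
it is validated once per factorization by a probe solve whose residual must
be below $10^{-7}$, and is refused when the eigenvector basis is ill
conditioned (Frobenius condition estimate above $10^7$). The robust route is
Bartels–Stewart on the real Schur form (`Matrix::Schur`) with 1×1/2×2 block
back-substitution. The split matters because defective matrices — e.g. the
Jordan-like chain `[[-1, 0], [c, -1]]` used in the closed-form tests — break
any pure eigendecomposition solver. Tests verify both routes against two
independent oracles: composite-Simpson quadrature of the Gramian integrand
and a dense Kronecker (vec) solve.

**Practical controllability.** An eigenvalue below $\epsilon = 10^{-12}$ is
treated as zero: the system is flagged not practically controllable and the
corresponding energy is $+\infty$. Eigenvalues in $[-10^{-8}, \epsilon]$ are
numerical noise and are clipped at zero for PSD reporting. Infinite energies
are never averaged away silently: they propagate through the energy
centralities, are excluded from cohort means (with a count or warning), and
sort last in every ranking regardless of ranking direction.

**Finite horizons.** The minimum-energy input synthesis needs a finite-time
Gramian; the default horizon is $t_f = 50$ TR with a 5,000-point grid
(composite trapezoid), long enough that the finite-horizon Gramian has
converged to the infinite-horizon one for the stability margins used here.
The controlled simulation uses exact exponential stepping with
piecewise-linear input interpolation (Van Loan block discretization), so its
only error is the input interpolation itself; the forward-simulation check in
the acceptance suite reaches its target to $10^{-4}$.

## The synthetic cohort: a stated world

The generator emulates the statistics the analyses assume, not any real
anatomy:

* **74 nodes** partitioned as CON 10, DMN 16, DAN 9, LIM 5, VAN 11, SMN 6,
  VIS 5, SUB 12 (62 cortical + 12 subcortical). One source text gives an
  alternative 58 + 16 split; the printed per-network sizes used here are the
  ones that sum consistently.
* **Off-diagonal density 0.39** via a Bernoulli support mask drawn once per
  cohort and shared by all subjects.
* **Sign split 60/40**: each link is positive with probability 0.6. Subject
  matrices mix a shared base with subject noise, $A_s = \rho A_{base} +
  (1-\rho) A_{noise,s}$, on the shared support; because both components draw
  signs the same way, the probability that a mixed link ends up positive is
  exactly 0.6 for any $\rho$.
* **Weight magnitudes** are lognormal($-1.5$, $0.7$). No weight distribution
  is published; a heavy-tailed choice is what gives the network genuine in-
  and out-hubs, and the hub-based driver-selection results are only
  meaningful under some such tail.
* **Diagonals** $-(0.5 + U[0, 0.5])$ before stabilization; every matrix is
  then shifted by a uniform diagonal constant so its spectral abscissa is
  exactly $-0.05$ (the `stability_margin` default, in 1/TR). The uniform
  shift moves all eigenvalues rigidly, so it never changes eigenvectors or
  off-diagonal structure.
* **Inter-subject correlation** is controlled by $\rho$ and calibrated by
  bisection (`calibrate_intersubject_mix()`) against the target mean pairwise
  Pearson correlation of 0.49. The shared support alone puts a small positive
  floor (~0.02) under the correlation; with shared signs as well the floor
  would sit near 0.6 — above the target — which is why the noise component
  draws its own signs.
* **Coordinates** are deterministic pseudo-anatomical blobs (per-network
  Gaussian clusters mirrored across the midline, fixed seed) so spatial
  gradient analyses execute; they carry no anatomical claim.
* **Model FC** is the correlation matrix of the stationary Lyapunov
  covariance $A\Sigma + \Sigma A^\top + \sigma^2 I = 0$. $\sigma^2$ (default
  1) cancels out of correlations, so its value is immaterial to every FC-based
  result.

**What a green test establishes.** Cohort-level tests on this generator check
*directions* — energy grows with target count, out-hubs are cheap drivers,
positive/negative links correlate with energy with opposite signs, centrality
beats random — not published magnitudes. Real EC matrices differ in ways the
generator does not emulate: subject-specific support, spatially structured
(not i.i.d.) weights, distance-dependent connection probability, and
inter-regional heterogeneity of time constants. Quantities like specific
Table-style energies or coefficient-of-variation values are cohort-specific
and are deliberately out of scope.

## Centralities and ranking conventions

Strength centralities exclude the diagonal by default: the diagonal encodes
leak, not inter-areal coupling (this is configurable). PageRank runs on the
binarized directed graph (signed weights would break the random-walk
interpretation) with damping 0.85 — unstated in the source literature, so the
standard value is used. The energy centralities $E^d_i$, $E^t_i$ are means of
the pairwise energy matrix *including* the self pair $j = i$, the literal
reading of the defining sums; on connected graphs the rankings are insensitive
to this choice.

Ranking directions: energies ascend (cheap is good), strengths and pq descend
(big is good). PageRank *ascends*: the source text is ambiguous ("ranked in
decreasing order"), but its own FC-based result — that the optimal FC
centrality selects nodes that do *not* receive many incoming connections —
only makes sense if low PageRank is preferred, so that reading is adopted and
flagged. Ties always break by ascending node index, and $+\infty$ scores sort
last under every direction.

The `pq` centrality is the one centrality that sees the input matrix: with
accessibility weights $\beta_i$ on the drivers, $p_i$ scales exactly by
$\beta_i^2$ and so does $pq_i$ — an algebraic identity the tests assert at
`1e-12`, and the reason `pq` is the natural ranking when nodes differ in how
well stimulation can reach them.

## Selection, aggregation and enrichment

The optimal-centrality search ranks, selects `n_d` drivers outside the target
set, and scores by worst-case target energy; "single-node" ranking means the
driver-energy centrality $E^d_i$ (an alternative reading — per-target
single-pair energies summed over the target set — is noted but not
implemented). Group selection aggregates per-subject rankings by mean rank
position (fractional ranks within ties), the most basic aggregation rule;
Borda-type variants are out of scope. The individual-vs-group energy gap
`deltaE` is reported in log10 units; converting to an energy factor is
$10^{\Delta E}$ (note the source text's printed "factor 1.3" for
$\Delta E = 0.075$ is inconsistent with $10^{0.075} \approx 1.19$; the
$10^{\Delta E}$ conversion is what this package means).

Enrichment uses a **two-sided** Fisher exact test: both over- (+) and under-
(−) representation are marked, with the direction read from the odds ratio,
so a one-sided test would be incoherent. Significance is $q < 0.05$ after
Benjamini–Hochberg adjustment over the $8 \times 8 - 8 = 56$ ordered RSN
pairs. Degenerate margins return $p = 1$ and are flagged. z-scores against
random driver baselines divide by the baseline standard deviation
($M - 1$ denominator); mean-only centering is available via `scale = FALSE`
since the source captions only guarantee the centering.

The FC-based selection variant needs centralities computable from a dense
correlation matrix; FC strength (descending) and PageRank on the FC graph
binarized at the median absolute off-diagonal correlation (ascending) are
used. This is a package choice — the source does not specify its FC
centralities — and only the *differences* between FC- and EC-based energies
are reported.

## Perturbation sensitivity

`perturb_connectome()` adds $\epsilon \sim N(0, (f|A_{ji}|)^2)$ to every
nonzero entry. The printed rule $N(0, f A_{ji})$ is ill-defined for negative
entries; the absolute value is the only self-consistent reading and preserves
sparsity exactly. Re-stabilization (uniform shift back to the original
margin) happens only if the perturbed matrix went unstable, which keeps
$f = 0$ an exact identity. The `pq` centrality is expected to be the most
fragile under this perturbation: noise perturbs the spectrum of $A$, and the
Gramian traces respond nonlinearly to eigenvalues approaching the imaginary
axis.

## Known limitations

* Infinite-horizon energies assume the Hurwitz property; systems at or beyond
  marginal stability are rejected, not regularized.
* The eigen route degrades gracefully to Schur, but extremely non-normal
  stable matrices may still lose a few digits in $\lambda_{\min}$; quantities
  thresholded at $10^{-12}$ are reported as practically uncontrollable rather
  than trusted.
* The generator's inter-subject model is exchangeable across subjects; it has
  no age/sex structure, no subject-specific support, and no hemispheric
  asymmetry beyond coordinates.
* No structural-controllability machinery (maximum matching), no discrete-time
  framework, no noise-aware covariance steering, and no inferential statistics
  against published cohort-specific values.
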