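---
title: "Multiscale functional states of weighted networks: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale functional states of weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcstate)
library(dplyr)
```

## The model

A weighted undirected network with weight matrix $W$ and strengths
$K_i = \sum_j W_{ij}$ carries a diffusing field $\phi$:
$$\partial_\tau \phi = -L\,\phi, \qquad L = \mathrm{diag}(K) - W.$$
The solution operator is the heat kernel $U(\tau) = e^{-\tau L}$. Because
$L$ is symmetric with zero row sums, $U(\tau)$ is symmetric, doubly
stochastic and entrywise nonnegative; $U_{ij}(\tau)$ is the fraction of a
unit field started on $i$ found on $j$ after time $\tau$.

Three derived objects drive everything in this package:

1. **Emergent functional state**
   $\tilde W_{ij}(\tau) = \phi_0\, U_{ij}(\tau)\,(1-\delta_{ij})$ — a
   network of pairwise flow exchange at scale $\tau$. For
   $\tau \to 0^+$, $\tilde W \approx \phi_0 \tau W$; for $\tau \to \infty$
   on a connected network every entry tends to $\phi_0/N$. Its mean
   strength $\bar k = \frac{1}{N}\sum_{ij} \tilde W_{ij}$ rises
   monotonically from $0$ to $\phi_0 (N-1)/N$.
2. **Network Gibbs state** $\rho(\tau) = U(\tau)/\mathrm{Tr}\,U(\tau)$,
   whose eigenvalues are the Boltzmann weights
   $p_\ell = e^{-\tau\lambda_\ell}/Z$ of the Laplacian modes, and the
   **Von Neumann entropy** $S(\tau) = -\sum_\ell p_\ell \log p_\ell$.
   $S(0) = \log N$; $S$ is non-increasing in $\tau$ (it is the Shannon
   entropy of a Gibbs distribution with increasing inverse temperature)
   and converges to $\log C$ on a network with $C$ components.
3. **Functional modules**: Louvain modularity maximisation on the dense
   $\tilde W(\tau)$. Because $\tilde W$ interpolates between the
   structure and the complete graph, the partition coarsens from many
   neighbourhood-scale modules to a single one as $\tau$ grows.

Scales are made comparable across networks through the diffusion time
$\tau_d = 1/\lambda_2$: at $\tau = \tau_d$ the slowest non-trivial mode
has decayed to $1/e$ (equivalently, the second propagator eigenvalue is
exactly $e^{-1}$ — a useful end-to-end test of the spectral machinery).
All sweeps run over log-spaced $\tau/\tau_d \in [10^{-10}, 10]$, the
range that spans "no flow has left any node" to "diffusion fully
equilibrated" on every topology we generate.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `phi0` | 1 | initial field per node; a pure scale on $\tilde W$, never on partitions or entropy. Strength curves are reported per unit $\phi_0$. |
| `ratio_bounds` | $10^{-10}, 10$ | sweep range in $\tau/\tau_d$ |
| `n_points` | 100 | grid resolution (log-spaced) |
| `n_restarts` | 10 | Louvain restarts per scale; the best-modularity partition is kept |
| `n_null` | 20 | RWCM realizations per comparison; stabilises the null mean curve |
| `max_nodes` | 500 | corpus size cap — the dense eigendecomposition is $O(N^3)$ and a 100-point sweep with Louvain at every scale is comfortable at desk scale up to a few hundred nodes |

## Numerical choices

- **One decomposition per network.** $L$ is diagonalised once
  (`eigen(symmetric = TRUE)`); every $\tau$ on the grid reuses it, so a
  full sweep costs one $O(N^3)$ step plus $O(N^2)$ per scale. Series or
  Padé matrix exponentials would repeat work per $\tau$ and are avoided.
- **Entropy from eigenvalues, log-sum-exp stabilised.** $S(\tau)$ is
  computed from the $\lambda_\ell$ directly, never by exponentiating and
  re-diagonalising $\rho$; with $\log p_\ell = -\tau\lambda_\ell - \log Z$
  kept in log space, the computation is exact even where
  $e^{-\tau\lambda}$ underflows, so extreme scales cost nothing in
  accuracy. The test suite cross-checks this route against a dense
  scaling-and-squaring construction of $\rho$ on small graphs.
- **Nonnegativity clipping.** $e^{-\tau L}$ is provably nonnegative;
  entries below zero by less than $10^{-12}$ are clipped, anything more
  negative aborts (it would indicate a broken decomposition, not
  roundoff).
- **Zero-eigenvalue threshold.** $\lambda < 10^{-10}\lambda_{max}$ counts
  as a zero mode; the count of such modes is the component count, and
  $\tau_d$ is defined only when it is 1. Disconnected networks are valid
  data (their entropy is well-defined, and the large-$\tau$ limit
  $\log C$ matters for understanding why rewiring nulls fail), but
  rescaled grids, sweeps and gap curves refuse them with an explicit
  $\lambda_2 = 0$ error.
- **Louvain determinism.** igraph's Louvain is randomized; we run it
  inside a seeded RNG scope with `n_restarts` independent restarts and
  keep the highest-modularity partition, so results are reproducible from
  the seed. Module ids are relabelled to contiguous integers in
  first-appearance order. Resolution is fixed at 1: the multiscale
  behaviour comes from $\tau$, not from a resolution knob.
- **Dense states, no thresholding.** The functional state fed to Louvain
  keeps all $N(N-1)/2$ entries; `functional_state_edges()` offers a
  `min_weight` cut for export only, because silently sparsifying
  $\tilde W$ would change module counts at large $\tau$.
- **Non-uniform initial conditions.** An initial distribution $\Pi$
  ($\Pi_{ii} = \phi_i/\phi_0$) folds into the propagator as $\Pi U$; the
  resulting asymmetric state is symmetrised as
  $(\tilde W + \tilde W^T)/2$ before modularity optimisation, since
  modularity has no directed-state convention here.
- **Node ordering.** Canonical order is first appearance (input file or
  generator); all matrices are indexed by it. An edge-list round trip
  reproduces weights bit-exactly (17 significant digits) with node order
  following first appearance in the written file.

## The RWCM null

Erdős–Rényi and rewiring configuration models disconnect sparse networks
— for a tree, almost surely — which trivially collapses large-scale
entropy to the component count and makes the comparison meaningless. The
randomized-weight configuration model therefore keeps every edge where it
is and only redraws weights: one Uniform(0,1) draw per edge (zero draws
resampled), then a global rescale so total weight is conserved exactly.
The uniform's bounds are irrelevant after rescaling; only the shape
matters. Gap curves match empirical and null networks on $\tau/\tau_d$
(each network at its own $\tau_d$, the convention that makes networks
comparable); matching absolute $\tau$ is available as an option.

## What the synthetic generators emulate — and what they do not

The generators (random geometric, Barabási–Albert, Watts–Strogatz,
stochastic block, plus deterministic cliques/paths/complete graphs)
cover the topological regimes the framework distinguishes: spatial
embedding, hubs, small worlds, planted mesoscale structure, and the
sparse tree-like limit where null-model choice is most delicate. Random
topologies are redrawn until connected. Stochastic-block defaults keep
the dis-assortative parameterisation (within $10^{-3}$, between $0.5$);
planted-community experiments pass the assortative orientation
explicitly, with blocks of 50 so the weak inter-block coupling still
connects the draw.

Two deliberate choices document what random fixtures can and cannot show
about real transport networks:

- **Planted-partition recovery** is asserted at $\tau = 0.1\,\tau_d$. We
  probed the recovery curve across scales: adjusted Rand against the
  planted 4 blocks is 1.0 for $\tau/\tau_d \le 0.1$ and degrades through
  $0.3\tau_d$–$2\tau_d$ as the functional modules genuinely coarsen past
  the planted scale — that degradation is the phenomenon, not a failure,
  so the test sits on the plateau where the planted scale is the right
  answer.
- **The mid-scale entropy gap needs structured weights.** With weights
  drawn independently of topology (uniform or spanning three decades),
  the sign of the mid-scale empirical-minus-RWCM gap fluctuates from
  draw to draw: an unstructured weight configuration is statistically
  the null's equal. Real cord conductances are not unstructured — flow
  concentrates on trunks. `transport_weights()` reweights a topology by
  unweighted edge betweenness (a transported-flow proxy), and on such
  fixtures the gap is large and reliably positive at middle scales while
  vanishing at both extremes. Passing that test shows the machinery
  resolves weight–topology correlation; it does not certify any
  particular biological network, whose weight structure must speak for
  itself.

Problem sizes in the tests and the acceptance script (networks of
40–200 nodes, grids of 6–40 points, 10–20 nulls, 10–20 planted-recovery
seeds) were chosen as the smallest at which each property is stable and
well-resolved; every quantity recomputes in seconds.

## Known limitations

- Dense spectral machinery: $N$ much beyond $10^3$ calls for
  Krylov/sparse exponentials, which are out of scope (hence the
  `max_nodes` guard).
- Undirected networks only; no multigraphs, no temporal edge lists, and
  no normalized-Laplacian (random-walk) variant.
- Louvain is a greedy heuristic; restarts make it reproducible and, on
  every $N \le 8$ fixture we enumerate exhaustively, optimal — but
  global optimality at scale is not guaranteed by any modularity
  heuristic.
- The modules–entropy regression is fit by OLS on pooled
  $(\log n_{modules}, S)$ points; with entropy nearly constant over the
  small-$\tau$ plateau the pooled points are strongly autocorrelated, so
  its $r^2$ should be read descriptively, not inferentially.
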