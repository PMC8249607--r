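---
title: "Cluster synchronization in directed multilayer networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster synchronization in directed multilayer networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustersync)
```

## The model

`clustersync` analyzes networks of $N$ coupled dynamical nodes connected
through $L$ link types (layers). Node $i$ has state
$x_i \in \mathbb{R}^n$ and evolves as

$$\dot{x}_i = f_i(x_i(t)) + \sum_{k=1}^{L} \sigma_k \sum_{j=1}^{N}
A^k_{ij}\, h^k\!\big(x_i(t),\, x_j(t-\delta_k)\big),$$

where $f_i$ is the isolated vector field (equal for nodes of the same
type), $A^k$ the weighted adjacency of layer $k$ oriented
receiver-row/sender-column, $\sigma_k$ its coupling strength, $h^k$ the
pairwise interaction, and $\delta_k \ge 0$ its transmission delay.
Cluster synchronization (CS) means $x_i(t) = x_j(t)$ for all $i, j$ in
the same cluster of some partition of the node set.

### Balanced partitions and quotients

A partition is *balanced* (equitable) when nodes sharing a cluster share
a node type and receive, in every layer, the same total input weight from
every cluster. Balanced partitions are exactly the candidate CS patterns:
each corresponds to an invariant synchrony subspace of the dynamics.
They form a lattice under refinement whose top element, the *minimal
balanced coloring*, is computed by `minimal_balanced_coloring()` through
iterated splitting on input-sum signatures. The full lattice is
enumerated either exactly (`strategy = "bruteforce"`, every
type-compatible set partition, compiled, refused above 12 nodes) or by
`seeded_closure`: coarsest balanced refinements of seeds obtained by
splitting one cluster of an already-found balanced partition into two
parts, over all such splits, iterated to closure. This is exhaustive
whenever no cluster exceeds the split cutoff (12 nodes): any balanced
partition $R$ strictly refining a found partition $P$ refines the seed
that splits one $P$-cluster into one $R$-cluster and the rest, hence
refines that seed's coarsest balanced refinement, which the closure
visits. (Isolating single nodes or pairs only — a natural first idea —
is *not* complete: on random planted digraphs it misses coarse members
such as the planted bipartition itself.) Above the cutoff the closure
falls back to isolation seeds and warns. The test suite cross-validates
the closure against brute force on every fixture and on random
planted-partition digraphs up to $N = 10$.

Some networks have astronomically many balanced partitions — as soon as
a group of nodes is driven but not otherwise coupled (or receives no
input at all), any grouping of it is balanced, giving a Bell-number
blow-up; the two-layer neuron network with one interlayer direction
removed is exactly such a case. The closure therefore stops at
`max_partitions` members (default 5000) with a warning. Because the
closure is breadth-first from the base partition, the truncated lattice
contains the coarsest members first, which is what the transform
construction and the dependency classifications consume.

The synchronous motions live on the *quotient network*
(`quotient_network()`): one node per cluster, with layer weights given by
per-cluster input sums of any representative (well defined exactly by
balance).

### Breaking vectors and the irreducible transformation

For a base partition $\mathcal{P}$ with clusters $C_q$, every finer
balanced partition $\mathcal{P}^j$ defines, for each cluster it splits, a
*breaking vector*: a length-$N$ pattern, zero outside $C_q$ and constant
on each subcluster. Its *intertwining index* $n_q^j$ counts the other
clusters of $\mathcal{P}$ forced to split alongside $C_q$. These objects
drive two independent views of cluster interdependence:

* **Lattice view** (`classify_from_lattice()`): cluster $a$ *depends on*
  $b$ when every lattice member that splits $b$ also splits $a$. Mutual
  dependence = intertwined; one direction = one-way dependent; neither =
  independent.
* **Matrix view** (`assemble_transform()` + `classify_from_blocks()`):
  an orthonormal $T = [T_\parallel; T_\perp]$ is built cluster by
  cluster. The uniform row $1/\sqrt{N_q}$ spans the synchronous
  direction; the remaining $N_q - 1$ rows are orthonormalized
  subcluster-indicator contrasts taken from breaking patterns in order of
  ascending intertwining index, then descending number of occurrences in
  the lattice, then lexicographic pattern. Because the all-singletons
  partition is always balanced, its pattern spans every contrast, so the
  fallback completion is rarely exercised (it logs a warning when it is).
  $B^k = T A^k T^\top$ is block upper triangular — the lower-left block
  $T_\perp A^k T_\parallel^\top$ vanishes identically because the
  synchrony subspace is $A^k$-invariant — and the summed transverse block
  $B_\perp$ decomposes into irreducible diagonal blocks. Upper-triangular
  blocks expose one-way dependence, full blocks intertwining.

The test suite checks that both views agree on every fixture and on
random planted networks.

Row ordering inside $B_\perp$ uses connected components of the
symmetrized nonzero pattern, then the topological order of the
strongly-connected-component condensation of the directed dependency
graph (dependents first, so acyclic blocks become upper triangular), with
ascending row index as tie-break, and blocks sorted by decreasing size.
This realizes "block-diagonal with minimal blocks, sizes decreasing along
the diagonal" directly; a bandwidth-reduction pre-pass would add nothing
because the ordering is already fully deterministic.

Sign conventions: contrast rows are flipped so the entry of largest
magnitude is positive, ties resolved by making the last nonzero entry
positive. $T$ is unique up to this convention; tests compare row spans
or absolute entries.

### Transverse stability

Linearizing about the synchronous solution $s(t)$ and transforming with
$T$ gives, for the transverse coordinates $\eta$,

$$\dot{\eta} = \Psi_1[s(t)]\,\eta(t) + \sum_k \Psi_2^k[s(t-\delta_k)]\,
\eta(t-\delta_k),$$

where the block of $\Psi_1$ for a transverse row attached to cluster $q$
is $Df_q(s_q) + \sum_k \sigma_k \sum_{q'} R^k_{qq'}
D_1 h^k(s_q, s_{q'}(t-\delta_k))$ (receiver-side derivatives through the
quotient weights $R^k$), and $\Psi_2^k$ carries the sender-side
derivatives weighted by $B_\perp^k$. This is well defined because every
transverse row is supported on a single cluster. The forms follow from
differentiating the network equations; they are validated against direct
nonlinear simulation rather than assumed (the test suite fits the growth
rate of within-cluster spread in full-network simulations and compares it
with the block exponent).

`transverse_mle()` co-integrates the quotient and one irreducible block
with a fixed-step RK4 scheme sharing one delay history buffer (linear
interpolation between grid points, constant pre-history), renormalizing
$\eta$ to unit norm at fixed intervals (Benettin). For delayed systems
the norm is taken over the current state only and the renormalization
rescales the stored $\eta$ history — a documented choice; norms over the
full history segment are a known alternative. A cluster's exponent
$\Lambda_q$ is the largest exponent among blocks containing one of its
rows; intertwined clusters share one exponent by construction.

## Built-in models and parameters

* **Delayed phase oscillators** (`violin_system()`): $\dot\varphi_i =
  \omega + \kappa \sum_j A_{ij} \sin(\varphi_j(t-\delta) - \varphi_i(t))$
  with $\omega = 0.25$, $\kappa = 0.2$ (inverse seconds), and a
  row-normalized 8-ring in three regimes — undirected (weights 1/2),
  "arrowhead" (one player leads, signals travel both arcs), and
  unidirectional. Row normalization keeps the total input volume of each
  player constant. Phases are unwrapped on the real line.
* **Two-layer bursting neurons** (`neuron_system()`): layer II
  (nodes 1–10), $\dot{x} = a x^2 - x^3 - y - z$,
  $\dot{y} = (a+\alpha) x^2 - y$, $\dot{z} = c(bx - z + e)$ with
  $a = 2.8$, $b = 9$, $c = 0.001$, $e = 5$, $\alpha = 1.7$, coupled
  electrically (diffusive in $x$, $\sigma_1 = 0.005$, $P = 6$ nearest
  ring neighbors) and chemically to the uncoupled layer I
  ($\alpha = 1.6$) through the sigmoidal synapse
  $(d - x_i)\,/\,(1 + e^{-\lambda(x_j - \Theta)})$ with $d = 2$,
  $\lambda = 10$, $\Theta = -0.25$. Both interlayer directions carry the
  full chemical strength $\sigma_2$, exactly as the layer equations
  above are written for both layers; a quarter-strength upward synapse
  remains available via `neuron_two_layer(up_weight = 0.25)`, but with
  that weighting the two-cluster pattern never stabilizes below
  $\sigma_2 \approx 3.5$ (checked both variationally and by independent
  full-network simulation), while the full-strength form places the
  threshold near $\sigma_2 = 1.5$ — which is why it is the default.

## Numerical choices

* Balance tolerance: relative $10^{-9}$ on input sums (exact comparisons
  are recovered for integer and dyadic-rational weights); signature
  refinement keys use 9 significant digits.
* Structural-zero threshold in $B_\perp$: $10^{-9}$ after scaling each
  layer by $\max|A^k|$, separating exact zeros (which arise from the
  invariance proof) from rounding.
* Integrator: fixed-step RK4, default $dt = \min(0.02, \delta_{\min}/20)$;
  steps larger than a tenth of the smallest positive delay are refused.
  Non-finite states abort with the divergence time.
* Lyapunov accumulation: renormalization every 1 time unit; neuron sweeps
  use a $3\times10^3$ transient and $10^4$ accumulation (exponents are
  stable to $\sim10^{-4}$ from $5\times10^3$ on, checked against
  $5\times10^4$ runs), phase-oscillator sweeps $5\times10^2$ and
  $2\times10^3$. The standard error is estimated from the last half of
  the accumulated log-increments.
* Initial conditions: per-cluster base states plus Gaussian jitter
  (magnitude 0.1, seeds documented at call sites). For the 12-cluster
  neuron pattern the quotient's diagonal (the 2-cluster state) is itself
  attracting inside the synchrony subspace once that pattern is stable,
  so the sweep linearizes about the solution the quotient actually
  reaches; burst-phase-staggered initial states were also tried and reach
  the same attractor. Consequently the measured 12-cluster threshold
  essentially coincides with the 2-cluster one — see "Known limitations".

## What the synthetic generator emulates

`random_planted()` draws digraphs in which every node of cluster $p$
receives arrows from exactly $d_{pq}$ uniformly chosen senders of cluster
$q$, so the planted partition is balanced by construction. It emulates
the combinatorial structure that the partition and transform machinery
relies on — exact input-sum balance, directed and possibly multilayer
links — and none of the messiness of real systems: no weight
heterogeneity beyond the degree table, no noise, no parameter mismatch
between "identical" nodes. Tests passing on planted networks therefore
validate the combinatorics and the linear-algebraic construction, not
robustness of CS to imperfect balance.

## Known limitations

* Enumeration is exponential; `seeded_closure` is a tested heuristic, not
  a completeness theorem.
* The 12-cluster neuron pattern: within its synchrony subspace the
  distinct-trace solution is only weakly distinguished from the diagonal
  (spread $\lesssim 0.05$ in $x$ for $\sigma_2 \gtrsim 1.5$), so a
  separate, higher stabilization threshold for this pattern is not
  resolved by this implementation — the measured crossing tracks the
  2-cluster one.
* The antiphase state of the undirected player ring at $\delta = 3.5$ is
  stable but weakly so (linear rate $\approx -1.7\times10^{-3}$); its
  basin in $\Delta\varphi(0)$ is narrow at that delay and widens by
  $\delta \approx 3.8$.
* Fixed-step integration only; no adaptive error control or event
  detection.
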