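---
title: "Validating centrality measures: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating centrality measures: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keynodes)
```

## The problem

Centrality measures promise to rank nodes by structural importance, but the
promise is rarely checked: if degree, betweenness, closeness, eccentricity
and eigenvector centrality each nominate a "most important" node, which of
them — if any — nominates a node that is *actually* important in the system
the graph describes? `keynodes` operationalises that question. It computes
the five measures from first principles, summarises their extremes and
mutual agreement, and scores each measure against an explicit, machine-
readable ground truth: the influential individuals documented in the field
studies behind three classic benchmark networks, or nodes planted by
construction in synthetic graphs.

The three benchmarks span network types deliberately: a human social network
(Zachary's karate club, 34 nodes / 78 edges, where the club instructor,
node 1, and the club president, node 34, were the two information sources in
the club's fission), an animal social network (the Doubtful Sound bottlenose
dolphins, 62 / 159, where `Grin` and `SN100` are the individuals singled out
in published analyses), and a connectome (the C. elegans neural network,
297 nodes, with no documented node identities — its ground-truth set is
deliberately empty and the pipeline reports that honestly). A seeded
Erdős–Rényi graph G(50, 0.1) serves as the structureless baseline.

## The measures and the conventions behind them

All measures are defined on undirected, simple, unweighted graphs with
hop-count geodesics. Directed or multi-edge input (the C. elegans records)
is collapsed to that form on read, with a warning.

**Degree** is normalised to `deg(v)/(n-1)`. The normalisation constant is a
convention (Freeman's); raw degree is available via `normalized = FALSE`.

**Betweenness** sums `σ_st(v)/σ_st` over unordered pairs with endpoints
excluded and no normalisation, computed by Brandes' dependency accumulation
(one BFS per source, exact on unweighted graphs). The formula as usually
printed carries no normalising factor, so unnormalised is the default;
dividing by `C(n-1, 2)` is a flag. The independent test oracle evaluates the
same sum from explicitly enumerated shortest paths.

**Closeness** is raw inverse farness, `1/Σ_t d(v,t)` (Sabidussi), because
that is the verbatim textbook phrase ("the inverse of the farness"); the
Freeman-style `(n-1)/farness` rescaling is a flag. Closeness is undefined
across components, so on disconnected input it is computed on the largest
connected component only — ties on component size are broken by the
lexicographically smallest member label — and the restriction is recorded on
the result and warned about. Degree, betweenness and eigenvector centrality
remain on the full graph.

**Eccentricity** is reported as the distance itself (`max_t d(v,t)`), where
*small* means *central*. Every consumer that needs a "high = central" scale
(rank correlation, top-k, ground-truth scoring) flips the sign internally
and records having done so. Keeping the raw value preserves the radius/
diameter reading (`min`/`max` over nodes).

**Eigenvector centrality** is the dominant adjacency eigenvector, computed
by power iteration from the uniform positive start vector with Euclidean
renormalisation, stopping when successive iterates differ by less than
`tol = 1e-10` in max-norm (cap `max_iter = 1000`). On bipartite graphs the
spectrum is symmetric (±λ) and the iteration can oscillate between two
phases — the path P3 and stars do exactly that. When non-convergence is
detected the iteration is re-run on `A + I`, whose dominant eigenvector is
identical but whose spectrum is no longer symmetric; the shift is recorded
in the result and the reported eigenvalue and residual are computed against
the original `A` (Rayleigh quotient; max-norm residual). A graph that fails
even damped iteration errors out carrying the residual rather than returning
a silently wrong vector.

## Tie handling and printed tie counts

Scores are rounded to 12 significant digits and compared with absolute
tolerance `1e-9` before any tie decision, so values equal by mathematics but
not by floating point count as tied. "Most central node" outputs are
therefore *sets* (`extreme_node_sets()`), never a single argmax.

Published figure captions often report "k nodes having the minimum value"
from histogram charts, and such counts need not equal exact tie counts: a
first histogram bin can absorb many distinct small values. The extremes
report therefore carries both the exact tie counts and a 10-bin equal-width
histogram fallback (`hist_n_min`, `hist_n_max`), without asserting which one
any given publication used.

## Synthetic generators: what they emulate

`erdos_renyi(n, p, seed)` includes each of the `C(n,2)` pairs independently
with probability `p`, visiting pairs in a fixed order so a seed pins down
the edge set on any platform. The classic baseline configuration is
G(50, 0.1); a single historical realisation of it is sometimes quoted with
135 edges, which is simply one draw from Binomial(1225, 0.1) (mean 122.5,
about 1.2 standard deviations off) — the generator reproduces the
*distribution*, and the acceptance suite checks its mean and variance, not
any particular draw.

`planted_hub(n_spokes, rewire, seed)` builds a star plus a sparse random
ring among the spokes (each ring edge kept with probability `rewire`,
default 0.1 — sparse enough that spokes stay near degree 1–3 while the hub
holds `n_spokes`). The hub is ground truth: degree and eigenvector
centrality must rank it first. `planted_bridge(clique_size)` joins two
cliques through a single degree-2 broker; every cross-clique geodesic passes
through it, so betweenness must rank the broker first even though its degree
is minimal. These two constructions separate "locally well-connected" from
"globally load-bearing", which is precisely the distinction the measures
are supposed to capture.

What the generators do *not* emulate: degree heterogeneity (no scale-free
tails), clustering, assortativity, weights, or temporal structure. A green
planted-recovery test establishes that a measure finds the structure it is
mathematically aimed at — it does not establish performance on real
networks, which is why the bundled empirical fixtures with documented key
nodes exist alongside.

## Comparison stages

`rank_correlation()` uses Kendall's tau-b by default (Spearman as an
option): eccentricity takes very few distinct values, so a tie-aware
coefficient is mandatory. `top_k_overlap()` reports |top-k ∩ top-k|/k for
every measure pair with `k = 5` by default (no canonical k exists; it is a
config knob), ties at the k-boundary broken lexicographically and flagged.
`score_against_ground_truth()` reports, per measure, the hit count within
the top k and the reciprocal competition rank of the best-ranked ground-
truth node; hit counts are monotone in k by construction.

## The diffusion probe

The spreading model is discrete-time susceptible–infected (SI): each step,
every infected node independently transmits to each susceptible neighbour
with probability `beta`, i.e. a susceptible node with `m` infected
neighbours turns with probability `1 - (1-beta)^m`. SI (no recovery) is the
minimal model matching a bare "diffusion rate" question; SIR-style recovery
is out of scope. Defaults: `beta = 0.3`, 200 replicates, step cap
10 × diameter. Diffusion *speed* from a seed is the reciprocal of the mean
time to half coverage — more robust to stragglers than time-to-full. With
`beta = 1` the process is exactly a BFS front, so time-to-full equals the
seed's eccentricity; the test suite uses that identity as an oracle.

`centrality_diffusion_association()` seeds an SI run at every node,
correlates each measure's *raw* scores with speed (eccentricity deliberately
not flipped here: the direction label answers "does a higher raw value speed
up diffusion?"), and labels the direction `increases`/`decreases` by the
sign of tau at |tau| ≥ 0.2, else `inconclusive`. Direction labels for
closeness and eccentricity in the literature are ambiguous about whether the
raw value or its reciprocal is meant; this module measures and reports,
and asserts nothing about those two a priori.

## Numerical and reproducibility choices

All generator and simulation randomness flows through explicit integer
seeds, and seeded helpers restore the caller's RNG state. Pipeline output is
rounded to 12 significant digits, so a fixed config and seed give
byte-identical bundles. GML export writes numbers with `%.12g` and
round-trips through the package's own reader. Competition ranks (ties share
the best rank) are used wherever a scalar rank is reported.

## Known limitations

* **Printed tie counts.** Two caption counts from the source literature —
  19 minimum-betweenness nodes on the karate network and 22 on the dolphins
  network — do not hold on the canonical datasets: the exact counts are 12
  and 9 (nodes of betweenness 0), and no single histogram binning reproduces
  both printed numbers (the same captions elsewhere report counts that *are*
  exact, e.g. 9 minimum-degree dolphins, which this package reproduces).
  The corresponding acceptance expectations are asserted faithfully and left
  failing rather than weakened; the extremes report always carries both
  exact and 10-bin counts.
* **Correlation threshold.** The acceptance suite's operationalised claim
  that tau(closeness, eccentricity-flipped) exceeds tau(degree, betweenness)
  on most G(30, 0.15) samples fails: tau-b's tie correction caps the
  closeness–eccentricity coefficient near 0.57 on such graphs while
  degree–betweenness sits near 0.77. The *qualitative* claim — closeness and
  flipped eccentricity are strongly positively correlated — does hold on
  every bundled network.
* **C. elegans edge count.** The canonical file carries 2359 directed
  synaptic records; as an undirected simple graph it has 2148 edges. Both
  numbers are reported, in their own units.
* Pure-R Brandes is exact but O(nm); it is comfortable at the bundled sizes
  (≤ 300 nodes, a few seconds) and not intended for large graphs.
* Weighted/directed centralities, Katz/PageRank, approximation algorithms,
  community detection and rendered visualisations are out of scope.
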