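---
title: "Heterogeneous network alignment with colored graphlets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous network alignment with colored graphlets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgalign)
```

## The problem

Global pairwise network alignment (NA) seeks an injective mapping $f$ from
the nodes of a network $G$ into the nodes of a (no smaller) network $H$ that
places topologically similar nodes onto each other and maps edges onto
edges. In biology the canonical instance is aligning protein-protein
interaction (PPI) networks of two species to transfer functional annotation
across the conserved regions. Classical NA is *homogeneous*: all nodes and
edges are of one type. Real data increasingly carry types — proteins
vs. Gene Ontology terms as nodes, physical vs. genetic interactions as
edges. `cgalign` implements *heterogeneous* NA for node- and edge-colored
networks: colored-graphlet node signatures, a color-aware edge-conservation
score, and heterogeneous versions of three alignment strategies
(seed-and-extend, simulated annealing, genetic search), together with a
synthetic noise-robustness evaluation harness.

## Colored graphlet signatures

Graphlets are the connected non-isomorphic graphs on 2–5 nodes; there are
30 of them, and their node automorphism classes (*orbits*) number 73 in
total. A node's graphlet degree vector (GDV) counts, for each orbit, how
many induced occurrences of the corresponding graphlet the node touches at
that orbit. Occurrences are induced subgraphs, each counted once per
(node, orbit) incidence — the standard graphlet semantics.

For a network with $k$ node colors, an exhaustive colored-graphlet
extension would distinguish *which position* carries which color; its space
and time complexity grow exponentially with $k$ (for the 3-node path, 6
position-specific variants at $k=2$ and 18 at $k=3$). `cgalign` instead
tracks only the *set* of colors present in an occurrence: every graphlet
has exactly $2^k - 1$ colored variants (3 at $k=2$, 7 at $k=3$), and
counting costs the same as homogeneous counting — each homogeneous
occurrence is enumerated once and binned by its color set in $O(1)$. The
resulting node-colored GDV (NCGDV) has $73 \times (2^k-1)$ entries; the
edge-colored analogue (ECGDV) bins occurrences by the colors of their
induced edges. Summing any NCGDV/ECGDV over combinations within an orbit
recovers the homogeneous GDV exactly (the *marginalization invariant*,
enforced in the tests). The counted node's own color is part of the
occurrence's combination: a combination records the colors present anywhere
in the occurrence, with no exclusion. Combination slots with more colors
than the graphlet has nodes (or edges) can never be hit but are kept so all
vectors have a fixed width; with $k \le 4$ the width stays $\le 1095$.

Two implementation routes exist and are tested against each other:

* the production counter (C++) enumerates every connected vertex subset of
  size 2–5 exactly once with Wernicke's ESU scheme and resolves the orbit
  of each touched node by a canonical-form lookup table;
* a brute-force reference (`count_signatures_brute`) enumerates subsets
  with `combn` and classifies them with igraph's VF2 isomorphisms.

The orbit numbering is the package's own deterministic ordering (node
count, then edge count, then canonical adjacency form). It coincides with
the conventional ordering for the small graphlets; nothing downstream
depends on the specific numbering because similarities only compare
like-indexed columns computed against a shared catalog and color set.

## Node similarity (NC)

Signature matrices of the two networks (rows: nodes, columns:
orbit-by-combination counts over a *shared* ordered color set) are stacked,
optionally reduced by PCA, and compared by cosine similarity per
cross-network pair, mapped affinely to $[0,1]$ as $(\cos + 1)/2$. Design
choices the graphlet-similarity literature leaves open are fixed here as
follows:

* **PCA convention** — columns are mean-centered, not variance-scaled
  (all columns are counts on comparable scales). The number of retained
  components $r$ is the smallest explaining $\ge 90\%$ of variance,
  floored at 2.
* **Cosine scaling** — the affine map $(\cos+1)/2$ is data-independent and
  stable across network pairs, unlike min–max scaling.
* **Zero vectors** (isolated nodes) have undefined cosine; their
  similarity is defined as the neutral 0.5.

`build_similarity()` defaults to PCA. For
desk-scale networks, however, the 90%-variance rule tends to select only
$r = 2$–3 components on raw graphlet counts (one magnitude-dominated
direction carries most variance), which discards nearly all discriminative
signal: measured at $n = 300$, the fraction of nodes whose true counterpart
is their nearest neighbor drops an order of magnitude relative to raw
(NoPCA) cosine. The sweep harness (`sweep_config()`) therefore defaults to
`reduction = "none"`, the documented close-second variant; this is a
deliberate package design decision for the reduced-scale experiment, not a
claim about full-scale behavior.

## Edge conservation (EC): homogeneous and heterogeneous S³

Under an alignment $f$, a G-edge $(u,v)$ is *conserved* when
$(f(u), f(v))$ is an H-edge; a G-edge mapped to a non-edge, or an H-edge
between two images whose preimages are not adjacent, is *non-conserved*.
H-edges outside the image of $f$ are ignored (the standard symmetric
substructure denominator over the induced subgraph on aligned nodes).
Homogeneous $S^3$ is conserved / (conserved + non-conserved).

The heterogeneous version weights each conserved edge by how many of its
two aligned endpoint pairs match in color: weight 1 for both, 2/3 for
exactly one, 1/3 for none (configurable; these defaults are one reasonable
choice, not a law). Heterogeneous $S^3$ replaces the conserved count by
the weight total in both numerator and denominator, so it reduces exactly
to homogeneous $S^3$ when all colors agree and is never larger than it.
Degenerate alignments with an empty denominator (edgeless networks) raise
an error rather than returning a score.

## The blended objective and its incremental form

Search aligners maximize $\alpha \cdot NC + (1-\alpha) \cdot EC$ with
$\alpha = 0.5$ by default. NC is the *mean* similarity of aligned pairs —
a normalization choice made here so both terms live in $[0,1]$. EC is
homogeneous or heterogeneous $S^3$, selecting the four evaluation
scenarios HomNC-HomEC, HetNC-HomEC, HomNC-HetEC, HetNC-HetEC.

For annealing, the objective is updated incrementally: a swap (two sources
exchange images) or change (one source re-images to an unused node)
touches only edges incident to the moved nodes, so the conserved count,
weight total, number of in-image H-edges, and similarity sum are adjusted
locally. `delta_objective()` exposes this in R; the test suite drives
1,000+ random moves and checks each delta against a from-scratch
recomputation at $10^{-9}$ tolerance. The C++ annealing core repeats the
same bookkeeping for speed.

## Alignment strategies

**Seed-and-extend (`wave_align`)** seeds with the best cross-network
similarity pair, then maintains a candidate pool of pairs (g, h) where g
neighbors an aligned source and h neighbors its image, scored by
similarity plus one vote per aligned neighbor pair supporting the
candidate. Ties break lexicographically on node order; when the frontier
empties (disconnected remainders), it re-seeds by best similarity among
unaligned pairs. This is an explicit, documented reconstruction of the
WAVE-style seed-and-extend strategy (the original tool's internal
weighting differs in detail); EC is optimized only implicitly.

**Simulated annealing (`sana_align`)** starts from a seeded uniformly
random injective mapping; proposes swaps and (when $|V(H)| > |V(G)|$)
changes 50/50; accepts improvements always and worsenings with probability
$\exp(\Delta/T)$. The schedule is geometric: $T_0$ is calibrated from
~200 sampled moves so that even large worsening deltas (the 90th
percentile) start at ~50% acceptance — the walk is initially nearly free —
and decays over four decades to $10^{-4} T_0$, keeping the whole budget
inside the temperature band where acceptance actually changes; late
acceptance is effectively zero. (A first cut anchored $T_0$ at the *mean*
worsening delta with an 8-decade decay; on 0%-noise self-alignments, where
the identity optimum is known reachable, it measurably under-converged.) Budgets are in iterations for exact
reproducibility (an optional wall-clock mode estimates an iteration count
from a timed calibration and is therefore machine-dependent). The
final-iteration alignment is returned, and its reported objective equals a
from-scratch recomputation. Equal-sized networks admit only swap moves.

**Genetic search (`magna_align`)** evolves a population of injective
mappings: fitness-proportional parent selection, uniform-mask crossover
with repair (collided images are replaced by random unused ones), and
elitism (the generation best survives; the best-ever alignment is
returned). Defaults mirror the MAGNA++ documentation's suggested
population of 15,000 and 2,000 generations; tests and desk-scale runs use much smaller
values, where the search still reaches within 5% of the exhaustively
computed optimum on 8-node instances.

## The synthetic world

The generators implement the standard synthetic benchmark for alignment
robustness studies:

* **Geometric (GEO)**: $n$ points uniform in the unit 3-cube, the $m$
  closest pairs connected. The dimension (3) and the exact-$m$ radius
  realization are package choices; geometric random graphs are a model
  family, not a single constructor.
* **Scale-free (SF)**: preferential attachment with per-step attachment
  $\approx m/n$, then random edge additions/removals to hit exactly $m$.
* **Coloring**: $k \in \{1..4\}$ colors assigned uniformly with class
  sizes within one of $n/k$; a membership-list scheme mirrors
  annotation-derived colorings (list A takes precedence, scheme 4 adds an
  "in both" color).
* **Noise**: $x\%$ of edges are removed and the same number of node pairs
  that are non-edges of the *original* network (and distinct from each
  other) are added, so $|V|$, $|E|$ and all node colors are preserved and
  exactly $1-x$ of the original edges survive. The true node mapping is
  the identity.

Full scale is 1,000 nodes / 6,000 edges; the desk-scale harness default is
300 / 1,800 at the same density. What the generator does **not** emulate:
real PPI degree correlations, clustering beyond what GEO/SF induce,
annotation-correlated colors (synthetic colors are independent of
topology), or multiple edge types. A green trend test therefore
establishes that the pipeline extracts color information under controlled
rewiring noise — not that it reproduces any real-data result.

## Evaluation and the trend experiment

`node_correctness()` is the percentage of aligned pairs agreeing with the
true mapping (random baseline $100/n$%). `run_sweep()` crosses
generators × colors × noise × replicates × methods from one master seed;
`rank_summary()` reproduces rank-frequency reporting: within each case all
levels of a factor are ranked by mean node correctness, ties sharing the
best applicable rank (a convention this package fixes explicitly), and 100%-noise rows are excluded by
default.

The acceptance trend test asserts, at desk scale (both generators,
$k \in \{1,2,4\}$, noise 0/25/50%, seed-and-extend + annealing at
$3\times10^7$ iterations, 3 replicates): node correctness non-decreasing
in $k$ at noise $\le 25\%$, non-increasing in noise, and HetNC-HetEC at
least matching the homogeneous baseline at 0–25% noise. Because individual
cells hold only 3 stochastic runs, medians are pooled over generators and
replicates per method — cells of three annealing runs are too small to
order reliably; rank-frequency reporting likewise aggregates over cases.
This interpretation was fixed before the test was first run. The annealing
budget was chosen from convergence measurements (the 0%-noise
self-alignment cell keeps improving through $10^7$–$3\times10^7$
iterations) subject to the experiment's 15-minute budget.

## Numerical and degenerate-input choices

* Duplicate edges collapse on construction; self-loops are errors;
  uncolored nodes default to color `"c1"` so a bare edge list is a valid
  homogeneous network.
* Similarity files print 6 decimals; round-trips are exact at that
  precision.
* Cosines are clamped to $[-1, 1]$ before the affine map to absorb
  floating-point drift.
* `round()` on rewired-edge counts is R's default; at the benchmark noise
  levels (multiples of 5% of 6,000 edges) it never matters.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; the C++ annealer uses its own seeded generator
  so results are bit-reproducible across runs for an iteration budget.

## Known limitations

* The seed-and-extend candidate scoring is a reconstruction, not the
  original implementation; absolute scores can differ from the original
  WAVE tool even where trends agree.
* Annealing at desk scale is run far below the multi-minute wall-clock
  budgets the original SANA tool uses; per-run node correctness has high seed variance (medians are
  the stable statistic).
* The exhaustive position-specific colored-graphlet machinery exists only
  as the brute-force variant counter used to justify the combination
  scheme's economy; it is not a counting mode.
* Networks are undirected, simple, single-color-per-node/edge; multigraph
  and directed data are out of scope.
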