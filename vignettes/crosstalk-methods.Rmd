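---
title: "Differential betweenness centrality for cross-talk target discovery"
author: "netCrosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential betweenness centrality for cross-talk target discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netCrosstalk)
```

## The problem

Two cellular processes — the motivating application is autophagy and
mitochondrial dysfunction in a neurotoxin model of Parkinsonian cell death —
rarely act in isolation: their protein machineries exchange information
through physical interactions. Proteins that *broker* that exchange are
attractive intervention points, but they need not be central within either
process on its own, so per-process centrality rankings miss them.

The approach implemented here nominates such cross-talk proteins from a
protein–protein interaction (PPI) database and two curated seed lists, one
per process:

1. curate the PPI database to a single species and to experimentally
   supported records, and build a background network;
2. for each seed list, extract a process sub-network by all-shortest-path
   sampling;
3. form the union of the two sub-networks;
4. compute betweenness centrality (BC) on both sub-networks and the union,
   and rank nodes by the differential statistic
   \[\Delta BC(v) \;=\; BC_{union}(v) \;-\; BC_{auto}(v) \;-\; BC_{mito}(v),\]
   where a node absent from a sub-network contributes 0 for that term (an
   absent node has no betweenness to subtract; output tables print `-`).

BC of a node $v$ is $\sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ over
unordered pairs, with $\sigma_{st}$ the number of shortest $s$–$t$ paths and
$\sigma_{st}(v)$ those passing through $v$ as an *interior* node; endpoints
earn no credit, and pairs in different components contribute nothing. A high
$\Delta BC$ therefore flags a node whose path-brokering role *emerges* only
when the two processes are combined — exactly the cross-talk signature.

## Curation

`readMitab()` parses the 15-column PSI-MI TAB core (configurable for
2.5/2.6/2.7 layouts through `mitabDialect()`). `curateInteractions()` then
applies, in order:

* **taxon filter** — both interactors must carry the required taxon
  (default 9606); records with an unknown taxon are dropped under the
  default strict reading (`requireBothTaxaMatch = TRUE`);
* **prediction filter** — detection methods in the policy's predicted set
  are removed. PSI-MI codes are the only machine-readable handle on
  "predicted interaction"; the packaged default is `MI:0063` (interaction
  prediction) with its prediction-branch descendants (`MI:0064`, `MI:0085`,
  `MI:0087`, `MI:0105`), overridable in the policy;
* **self-interaction filter**.

The curation report prints both surviving-record and unique-pair counts:
interaction databases quote either convention, and the two differ whenever
several experiments support one pair.

Node identifiers follow a configurable preference order over MITAB columns
(default: gene-symbol alias, falling back to the raw unique identifier).
Two records merge into one node only when they resolve to the same
preferred identifier — deterministic and auditable, with no attempt at
ortholog or cross-namespace mapping.

## Shortest-path sampling

For a seed list $S$, the sub-network node set is the union over all
unordered pairs of present seeds of **every node on any shortest path**
between the pair, and the edge set is the induced subgraph of the
background on those nodes ("all edges between this list of nodes"). Three
deliberate choices:

* *All* shortest paths, not one representative: the plural set is
  deterministic and independent of seed order, whereas picking one path per
  pair would need an arbitrary tie-break.
* Seeds are asserted process members, so a present seed enters the node set
  even when it is disconnected from every other seed; disconnected seed
  pairs are counted in the `SamplingReport`, not treated as errors (real
  interactomes have singleton components). The inclusion is recorded in the
  run manifest (`isolated_seeds_included`).
* Membership is decided by the distance criterion
  $d(s,v) + d(v,t) = d(s,t)$ from breadth-first distance fields, so no path
  enumeration is ever performed on the full interactome.

## The union network and its completion

The union merges the two sub-networks by identifier: nodes
$N_a \cup N_b$, edges $E_a \cup E_b$. For sub-networks that were sampled
from one common curated background — the only situation the pipeline
produces — `unionNetwork(a, b, background =)` additionally restores every
background edge whose endpoints were sampled into *different* sub-networks,
i.e. it returns the induced subgraph of the background on $N_a \cup N_b$.
The pipeline uses this completion by default (`unionCompletion =
"background"`).

The rationale: both sub-networks are induced subgraphs of the same curated
interactome, so an edge between an auto-only node and a mito-only node is a
real curated interaction — and it is precisely the process-to-process
contact the statistic is designed to expose. At full interactome scale the
two conventions nearly coincide, because seed lists of tens to hundreds of
proteins produce heavily overlapping sub-networks. On small or weakly
overlapping sub-networks they differ sharply: under the plain edge union a
bridge protein sampled into only one sub-network keeps only its same-side
edges, the union stays disconnected through it, and its $\Delta BC$
collapses to zero; the completed union restores its cross-side edges and
the statistic behaves as intended. The plain edge union remains available
(`unionCompletion = "none"`, or `unionNetwork()` without a background) and
is what the algebraic identities below are stated for.

## Normalization

Whether BC should be normalized before subtraction is genuinely open. We
compute $\Delta BC$ on **unnormalized** values: the three networks differ
in size, normalization divides each table by its own $(n-1)(n-2)/2$, and a
difference of quantities measured on different scales is not meaningful.
Normalized tables can still be written for display
(`normalizedReport = TRUE`), so either convention can be inspected.

## Ranking

Records are ordered by $\Delta BC$ descending, ties broken by node
identifier ascending. The tie-break is arbitrary but fixed: ranked output
must be reproducible byte for byte. `rankTargets()` returns the top-$k$
prefix; the full table is always written to disk.

Algebraic identities used as self-checks (plain edge union):

* self union: $\Delta BC = -BC(a)$ elementwise (the union *is* $a$, and the
  sub-network term is subtracted twice);
* node- and edge-disjoint sub-networks: $\Delta BC \equiv 0$ (shortest
  paths are component-local);
* $\sum_v BC(v) = \sum_{(s,t)} (d_{st} - 1)$ over connected pairs in
  unweighted graphs.

## Synthetic benchmarks

No public snapshot reproduces the original interactome (a 2012 download)
or its supplementary seed lists, so validation is property-based on
synthetic data with known ground truth.

**Planted-bridge generator.** `generatePlantedBridge()` builds two
Erdős–Rényi communities joined *only* through dedicated bridge nodes, each
wired to a fixed number of uniformly chosen partners per side, with seed
lists drawn uniformly from each community. Reference conditions: 30 nodes
per community, edge probability 0.15, 2 bridges with degree 3 per side, 5
seeds per community. Erdős–Rényi is the default because the property under
test is *cut structure*, not degree distribution; a preferential-attachment
option (`attachment = "preferential"`) is available for heavier-tailed
degrees. Instances whose seeds do not share one connected component are
re-drawn (bounded retries): the benchmark is about recovering bridges
between connected processes. One integer seed drives graph, seeds and
MITAB-annotation draws through a single stream, and the generator restores
the caller's RNG state, so everything it emits is reproducible
byte-for-byte. Optional decoy fractions assign non-human taxa or predicted
detection codes to MITAB rows, so the curation filters have real work and
their output can be checked against the generator's recorded truth
(`truthCuratedCount()`).

The recovery property checked in the test suite: over 20 fixed instances
(generator seeds 1–20) at the reference conditions, every planted bridge
that enters the union network ranks in the top 5 by $\Delta BC$ in at
least 18 instances. Bridges that are never pulled onto a shortest path
between seeds do not enter any sub-network and are excluded — the method
can only rank what sampling reaches, which is itself informative about
seed-list coverage.

What the generator does **not** emulate: realistic degree exponents and
clustering spectra, protein-family redundancy, identifier noise, and
multi-database record duplication beyond simple repeats. Passing these
benchmarks shows the machinery is correct and the statistic recovers
planted cut structure; it does not certify performance on any real
interactome.

**Toy barbell.** `makeToyBarbell()` is the fixed documentation example:
4-cliques $\{A1..A4\}$ and $\{B1..B4\}$ joined by the path $A1 - X - B1$,
with seed lists $\{A2, A3, A4, X\}$ and $\{B2, B3, B4, X\}$ — each process
contributes its clique members plus the junction protein $X$, asserted in
both processes the way shared-process proteins appear in real curated
lists. (Seed lists confined to their cliques would be degenerate: within a
clique every seed pair is adjacent, each sub-network collapses to a
triangle and every $\Delta BC$ is zero.) The sampled sub-networks are
$\{A1..A4, X\}$ and $\{B1..B4, X\}$; their union is the whole barbell; $X$
has zero betweenness inside each sub-network but brokers all 16
cross-clique pairs in the union, so $\Delta BC(X) = 16$ tops the ranking
ahead of the gateways $A1, B1$ ($\Delta BC = 12$). The expected table is
frozen from a brute-force enumeration and re-derived against that oracle
in the tests.

```{r toy}
toy <- makeToyBarbell()
sa <- sampleShortestPaths(toy$network, toy$seedsAuto)
sm <- sampleShortestPaths(toy$network, toy$seedsMito)
u  <- unionNetwork(sa$network, sm$network, background = toy$network)
deltaBC(betweennessTable(u),
        betweennessTable(sa$network),
        betweennessTable(sm$network))
```

## Numerical and engineering choices

* Graphs are simple, undirected, unweighted throughout: the path-count
  definition of BC presumes unweighted paths, and MITAB PPIs carry no
  direction. Duplicate rows and reversed orientations collapse to one
  edge; self loops are dropped at curation and again at construction.
* BC is computed with the Brandes algorithm (igraph). The test suite
  checks it against an independent brute-force oracle (pure-R BFS plus
  depth-limited path enumeration) on batteries of random graphs of 4–12
  nodes — 200 graphs for BC, 100 for sampling — where exhaustive
  enumeration is exact and fast.
* Networks with fewer than 3 nodes have identically zero BC (no interior
  positions); this is returned explicitly rather than relying on
  normalization corner cases.
* The analysis pipeline contains no randomness at all; every random draw
  in the package lives in the synthetic generator under one seeded stream.
  Two runs on identical inputs produce byte-identical outputs, which the
  tests verify at file level.
* Malformed MITAB lines (too few columns) are skipped with a warning that
  names the line numbers — never silently.

## Limitations

* $\Delta BC$ is defined for exactly two processes; the configuration
  layer enforces two seed lists rather than generalising the statistic.
* No statistical significance is attached to $\Delta BC$ (no permutation
  null); ranks are descriptive.
* No homology or paralog expansion of ranked targets, no identifier
  cross-mapping, no live database queries, and no layout/visualisation —
  the GraphML export carries `bc_union` and `delta_bc` node attributes for
  external tools.
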