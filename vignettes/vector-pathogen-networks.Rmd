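---
title: "Models and methods for mosquito vector-pathogen network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for mosquito vector-pathogen network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosqnet)
```

`mosqnet` analyses the global two-mode network of mosquito vectors and
human pathogens: how evidence of varying strength accumulates into
vector-pathogen associations, how compartmentalised the resulting network
is, and how many vectors must disappear before pathogens lose all their
vectors. This vignette documents the underlying models, the parameters
that matter, the numerical choices, and what the synthetic validation
does and does not demonstrate.

## The evidence-scoring model

A literature record links one mosquito (species- or genus-level label) to
one pathogen through one of five evidence categories. Laboratory evidence
forms a ladder — infection (1), dissemination (2), transmission (3) —
because each stage implies the previous ones. Isolation of the pathogen
from a wild-caught female (`wild_infection`) is independent field
evidence: alone it scores 1, and alongside any laboratory evidence it
adds one point. Consensus known-vector status scores 5 outright. A pair's
score is the maximum over its documented evidence, so the same score can
arise in different ways (a 3 is lab transmission, or wild infection plus
lab dissemination).

Two boundary rules deserve justification, since the scheme's prose
description alone does not force them:

* **Wild infection alone scores 1, and the +1 bonus applies only when
  laboratory evidence is present.** Were wild infection a level of its
  own, a "1 + 1" combination of wild and lab infection could not be
  distinguished from the description of either alone.
* **Non-known-vector scores are capped at 4.** The top of the evidence
  ladder (lab transmission + wild infection = 4) must not collide with
  known-vector status; 5 is reserved for the consensus designation so
  that `score == 5` and "known vector" are interchangeable everywhere
  downstream (network filtering, certainty profiles).

Name matching is exact string equality after trimming and collapsing
internal whitespace. Taxonomic synonym resolution, *sensu stricto/lato*
judgements and genus-level disambiguation are upstream curation concerns:
input files must disambiguate genus-level entries per pathogen (e.g.
`"Mansonia sp. [Guama]"`), otherwise distinct records collapse into one
node. Duplicate records are idempotent by design (set semantics), so
re-curated tables with repeated rows score identically.

We expose the raw 1-5 score on every edge rather than a known/potential
dichotomy, so users can filter at any threshold; the built-in
`knownOnly` filter implements the score-5 restriction used throughout
the analysis.

## The network and its metrics

`buildNetwork()` produces a strictly two-mode graph: nodes enter only via
edges, so there are no isolated nodes at construction, and the
known-vector subnetwork drops nodes left isolated by the filter. Evidence
scores ride along as edge weights; each metric states what it does with
them.

**NODF** (nestedness by overlap and decreasing fill) is computed on the
binary incidence matrix. For every pair of rows with strictly decreasing
marginal totals, the paired overlap is `100 x |shared| / fill(sparser)`;
pairs with equal fill contribute zero — the strict form of the
decreasing-fill condition, which makes the statistic invariant under row
and column permutation. NODF is the mean over all row and column pairs.
Weights are ignored: nestedness is a property of presence-absence
structure. The implementation is checked against `vegan::nestednodf` in
the test suite.

**Modularity** is plain one-mode Newman-Girvan
$Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} - \frac{k_i k_j}{2m}\right)\delta(c_i,c_j)$
evaluated on the bipartite graph treated as an ordinary undirected graph.
We deliberately do not use Barber's bipartite modularity: Louvain
optimises the one-mode form, and communities here deliberately mix
vectors and pathogens. Edge weights (evidence scores) are used by
default, treating better-documented associations as stronger ties; an
unweighted switch is provided. Note that "modularity" has occasionally
been described in the applied literature through ad hoc summaries
(e.g. within-cluster dispersion); published values computed with other
toolchains are therefore only qualitatively comparable.

**Louvain clustering** is the standard two-phase algorithm (greedy local
moving, then aggregation of communities into super-nodes, repeated), at
resolution 1, with three implementation details that matter for
reproducibility and quality:

* node visit order is shuffled by a seeded RNG, and the best of
  `nRestarts` (default 10) restarts by Q is kept, so results are
  deterministic given `(seed, nRestarts)` and Q is non-decreasing in the
  number of restarts;
* ties during local moves break by largest modularity gain, then lowest
  community id;
* after the hierarchy bottoms out, local moving is re-run on the
  *original* graph initialised from the solution, and the whole cycle
  iterates until Q stops improving. This node-level refinement
  consistently lifts Q above what the plain hierarchy reaches (the
  aggregated graph cannot split a community once formed) and measurably
  improves recovery of planted community structure.

**Betweenness centrality (BCI)** uses Brandes' algorithm on the
unweighted graph, normalised by $(n-1)(n-2)/2$. Scores are *not* used as
distances: a higher evidence score does not make a path shorter, and any
weight-to-distance transform would be arbitrary. Disconnected pairs
contribute nothing. Degree-one leaves have BCI 0; a vector shared by many
otherwise-unconnected pathogens approaches 1.

## Extinction curves, robustness, break points

The vector-pathogen network is asymmetrical: removing a pathogen does not
harm vectors, so only vectors are removed. After each removal, a pathogen
is extinct iff all its vectors are gone; pathogens are never deleted, so
the curve's denominator (the pathogen count `P`) is fixed. The curve
starts at `(0, 1)` and ends at `(V, 0)`.

* **Robustness** is the area under the curve by the trapezoidal rule on
  the uniform grid `x = k/V` — near 1 for resilient networks, near 0.5
  for one-extinction-per-removal decay, below 0.5 when removals cost more
  than one pathogen each.
* **Break point** is the number of removals at the first secondary
  extinction.
* **Random policy**: `replicates` (default 1000) independent seeded
  permutations; we report the mean and SD of per-replicate robustness
  and break point, the pointwise-mean curve, and the area under that
  mean curve. On a fixed grid the mean of per-replicate areas and the
  area of the mean curve are identical up to floating error; both are
  exposed so users need not take this on faith.
* **Targeted policy**: most connected first, by BCI (or degree), ties by
  degree then name, computed once on the intact network — a static
  attack, matching a fixed published removal order. `recompute = TRUE`
  switches to adaptive re-ranking after every removal, a strictly more
  aggressive attack provided as an extension (with BCI re-ranking it is
  quadratic-ish in network size; degree re-ranking is cheap).

## Certainty versus scale of the problem

`profilePathogens()` summarises each pathogen by `nTotal` (associated
vectors: scale of the problem) and `certainty = nKnown/nTotal`. Quadrant
thresholds: the median of `nTotal` across pathogens (computed from the
data, midpoint rule for even counts — never hard-coded) and certainty
0.5. Boundary cases (exactly the median, exactly half known) classify as
small scale / low certainty, i.e. "large" and "high" are strict. A
pathogen with few vectors, all known, is the easy eradication target; a
pathogen with many vectors and few known is the hard one.

## The synthetic generator

`synthParams()`/`generateEvidence()` produce evidence *tables*, not
networks: each drawn edge is emitted as a minimal set of records whose
score under `scorePair()` equals the drawn score (a 3 becomes either
`{lab_transmission}` or `{wild_infection, lab_dissemination}`, chosen at
random). This keeps the generator honest against the scoring rules — a
round-trip test in the suite re-scores every emitted record set and
requires exact agreement.

The sampling model is a planted-partition bipartite graph: pathogens and
vectors are assigned uniformly to `nClusters` clusters; each
vector-pathogen pair is an edge with probability `pIn` within a cluster
and `pOut` between, multiplied (capped at 1) by `hubBoost` for a
`hubFraction` of hub vectors; every pathogen is guaranteed one edge by
forced attachment to an in-cluster vector. Each edge is a known-vector
edge with probability `knownFraction`, else scores 1-4 are drawn from
`scoreDistribution`.

The defaults emulate the curated global dataset's shape: 78 pathogens,
331 vectors, 11 clusters; `pIn/pOut = 20` (strong compartmentalisation,
as observed in the real network); `hubFraction = 10/331` and
`hubBoost = 4` (a handful of cosmopolitan generalists with a few dozen
associations); `pOut` solved analytically so the expected edge count is
894; `knownFraction = 108/894` (the known-pair fraction of the curated
data). The score distribution over 1-4, `(0.45, 0.25, 0.20, 0.10)`, is a
package choice: most non-established associations in the literature rest
on infection-level evidence alone, with progressively fewer pairs
reaching dissemination, transmission, and transmission-plus-wild
documentation. These values were fixed once, before validation, and are
study conditions, not tuning knobs.

What the generator does **not** emulate — and therefore what passing
tests do *not* establish about real data: taxonomic structure (three
genera dominating the vector side), heavy-tailed degree distributions
beyond the simple hub mechanism, correlation between evidence strength
and degree (well-studied vectors accumulate both), geographic or
phylogenetic correlation, and the curated dataset's exact marginal
counts. Synthetic validation shows the machinery is correct under a
known model; it does not certify published values on the curated table,
which requires that table as input (see `runPipeline()` on any evidence
CSV in the documented dialect).

## Numerical and design notes

* All randomness (Louvain restarts, random removals, synthetic draws)
  flows from explicit integer seeds; internal RNG use saves and restores
  the caller's `.Random.seed`. Replicate r uses seed `seed + r - 1`,
  keeping derived seeds well inside 32-bit range for practical inputs.
* Modularity improvement thresholds use an absolute tolerance of 1e-12;
  Louvain accepts a move only on strict improvement, preventing
  tie-induced oscillation.
* Community ids are contiguous integers from 1 (R convention), ordered
  by first appearance.
* Degenerate inputs fail loudly: empty evidence sets, unknown category
  tokens (named in the error), empty networks after filtering, NODF on
  matrices with fewer than two rows/columns or with empty lines,
  betweenness on fewer than three nodes, non-permutation removal orders.
* Community recovery is assessed with unweighted Louvain: the planted
  signal is topological while synthetic edge scores are independent
  noise, and a random-weight dense component can legitimately possess a
  higher-Q weighted split than the planted partition.
* Reports serialise floats at 4 decimals with stable key order, so
  identical runs are byte-identical.

Test and validation problem sizes are deliberately modest — brute-force
oracles on graphs of up to 8 nodes, exhaustive removal enumeration up to
6 vectors (720 permutations), community recovery at the emulated full
scale (78 x 331), 300-1000 Monte-Carlo replicates — chosen so the whole
suite exercises every contract at exact or 3-standard-error tolerances
while remaining quick to run routinely.

## Known limitations

* Host (vertebrate reservoir) dynamics, zoonotic maintenance cycles, and
  geographic co-occurrence are out of scope; the network is strictly
  vector-pathogen.
* Modularity and cluster counts are optimizer-dependent quantities;
  cross-toolchain comparisons should be qualitative (orderings, not
  third decimals).
* BCI on weighted paths is not provided built-in; users wanting
  weighted betweenness should define an explicit score-to-distance
  transform and use the igraph export (`asIgraph()`).
* The scoring scheme treats evidence as cumulative and error-free;
  contradictory or retracted findings must be resolved upstream.
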