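---
title: "Co-extinction cascades: the model behind netcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-extinction cascades: the model behind netcascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcascade)
```

## The model

netcascade treats a system — a protein interactome, a genetic interaction
map, a plant–pollinator web, a social network — as a simple undirected graph
$G = (V, E)$: unweighted binary ties, no self-loops, no duplicate edges. The
single behavioral assumption is that **a node is functional only while it
retains at least one support link**. A perturbation deletes one or more nodes
(entities) or edges (functions) from the graph; any surviving node whose
degree thereby drops to zero has lost its entire support and undergoes a
*secondary extinction* (a co-extinction) in association with the targeted
loss. Secondaries leave the functional subnetwork together with the
primaries, and all "after" statistics are computed on what remains
functional.

One round of secondary accounting suffices: under the zero-degree rule,
removing an already-isolated node cannot isolate anything else, so there is
no multi-round cascade *within* a single perturbation event. Cascades across
events are exactly what the sequential mode simulates.

Three perturbation modes share this accounting:

* **Single/clustered removals** (`remove_nodes()`, `remove_edges()`): all
  targets are removed simultaneously and secondaries are evaluated once, on
  the final configuration. This makes a grouped perturbation one event, so
  removing `{x, y}` together can differ from removing `x` then `y` — which
  is the scientific point of paired-deletion analyses. Order within the
  group is irrelevant (a property the test suite verifies).
* **Sequential cascades** (`run_cascade()`): one primary removal per step,
  with the full secondary accounting and a topology record after every
  step. The trace, expressed against the percentage of primaries removed,
  is a *co-extinction curve*; the first step after which no functional node
  remains is the *complete collapse* step.
* **Leave-one-out scan** (`leave_one_out_scan()`): every node is removed
  and put back independently; rows never accumulate damage, which makes
  them comparable across nodes and across networks.

## Rankings, ties, and the skip rule

Sequential attacks rank nodes by degree — the canonical generalist
(most-linked) versus specialist (least-linked) contrast — in two flavors.
`static` ranking sorts once on the input network and walks that fixed list;
it is the default because the sorted-order wording of classical extinction
sequences describes a pre-computed list. `dynamic` re-ranks the shrinking
network after every removal; both appear in the robustness literature, so
both are options. Random sequences shuffle the label-sorted node list
(static) or draw uniformly from the current survivors (dynamic); replicate
$r$ of a random cascade uses `seed + (r − 1)` and the realized permutation
is written into the curve CSV header for auditability.

Two bookkeeping rules keep traces well-defined:

* a ranked node that already fell as a secondary is **skipped without
  consuming a step** — it no longer exists, so it cannot be a primary. The
  percentage axis consequently counts realized primary removals over the
  original node count;
* every tie — equal degrees, equal component sizes — is broken
  lexicographically by label in the C locale, so identical inputs give
  byte-identical outputs on any machine regardless of session locale.

A consequence worth knowing: the conservation identity
$|V_0| = \text{primaries} + \text{cumulative secondaries} +
\text{remaining}$ holds at every step of every cascade, and a full node
cascade always ends in collapse (the only way to finish without collapse is
an explicit `max_steps` truncation).

## Topology indicators and their conventions

`summarize_network()` reports size $S$, edge count $|E|$, density
$2|E|/(S(S-1))$ (defined as 0 for $S \le 1$), average degree $K = 2|E|/S$,
average path length, diameter, and the component structure. Average path
length is the mean shortest-path distance over *connected ordered pairs
only*; with no connected pair it is `NA`. The $|V|$-substitution for
unreachable pairs is applied **only** to closeness centrality, where that
convention is stated; letting it leak into the path-length average would
silently change a headline indicator of fragmented networks.

The four per-node measures (`node_metrics()`):

* **degree** $k(i) = |N(i)|$;
* **betweenness**: $\sum_{\{i,j\},\, i \ne v \ne j} \sigma_{ivj} /
  \sigma_{ij}$ with each unordered pair counted once, endpoints excluded,
  no normalization. The formula is silent on double counting; counting
  unordered pairs once is the natural reading for an undirected graph, and
  the suite verifies it against two independent oracles (minimal-walk
  counting via adjacency powers, and exhaustive DFS path enumeration);
* **closeness**: $(|V|-1)/\sum_{i \ne v} d'(v,i)$ with $d'(v,i) = |V|$ when
  $i$ is unreachable from $v$. An isolated node gets exactly $1/|V|$;
* **eigenvector**: the principal eigenvector of the adjacency matrix,
  max-normalized so the largest entry is 1 (the convention that makes the
  star closed form clean: leaf/hub ratio $1/\sqrt{n}$ on $K_{1,n}$).

### Numerical choices

Eigenvector centrality is computed by power iteration **on $A + I$**, not on
$A$. Plain power iteration from a positive vector fails to converge on
bipartite graphs — their adjacency spectrum is symmetric, so iterates
oscillate with period two (on $K_{1,3}$ the naive iteration bounces between
$(1,1,1,1)$ and $(1,\frac13,\frac13,\frac13)$ forever). The identity shift
leaves every eigenvector unchanged, moves the spectrum to
$\lambda_i + 1$, and strictly separates the dominant eigenvalue in modulus,
restoring convergence on every connected graph; plant–pollinator webs are
bipartite by construction, so this is not an edge case here. Defaults:
`tol = 1e-10` on the max-norm difference of successive normalized iterates,
`max_iter = 10000`. Non-convergence raises a condition that carries the last
iterate, so a caller can restart rather than lose the work. On disconnected
graphs the iteration localizes on the component with the largest spectral
radius and other components report (near) zero; the function warns, because
those zeros are a property of the measure, not of the nodes.

Component ids are assigned in decreasing size with ties to the smallest
member label, which makes the component coloring of `render_network()`
reproducible even though the force-directed (Fruchterman–Reingold) layout
itself is stochastic. All scientific content of a run lives in the CSV
outputs; images are explicitly illustrative.

## The synthetic generators

The package generates its own test networks (`make_star()`, `make_path()`,
`make_complete()`, `make_erdos_renyi()`, `make_barabasi_albert()`,
`make_bipartite_web()`, `make_two_modules_bridge()`), all bit-reproducible
for a given seed and none disturbing the caller's RNG stream.

* The Barabási–Albert generator seeds with an $(m+1)$-clique and attaches
  each arriving node to $m$ distinct targets with probability proportional
  to current degree — the standard construction, stated explicitly because
  published variants differ in both choices. Edge count is exactly
  $\binom{m+1}{2} + m(n - m - 1)$ (397 for $n = 200$, $m = 2$). With
  $n \ge 200$, $m = 2$ the degree sequence is reliably right-skewed
  (max $\ge 3\times$ median across seeds), which is the regime where the
  generalist-first/specialist-first contrast is sharp.
* Erdős–Rényi fixtures drop isolated nodes after sampling, because an edge
  list cannot represent them (the same reason freshly parsed networks never
  contain isolates).
* The bipartite web fills an $R \times C$ interaction matrix at a given
  connectance and then guarantees every row and column at least one link, so
  no species begins extinct.
* `make_two_modules_bridge(k)` joins two $k$-cliques through a single
  degree-2 connector: the scenario in which a sparsely connected node is
  structurally critical and degree alone misranks it.

What these emulate — heavy-tailed degree distributions, two-class webs,
module connectors — is the structure that drives co-extinction dynamics.
What they do not emulate: degree–degree correlations, clustering profiles
of real interactomes, sampling noise in empirical webs, or any edge
weighting. Passing tests therefore certify the perturbation *mechanics* and
the topology *arithmetic* on controlled structures; they are not a claim
about any particular empirical dataset.

## Problem sizes and test design

The suite checks the centrality stack exhaustively against brute-force
oracles on every connected graph with up to 6 nodes (one representative per
isomorphism class — all measures are label-permutation equivariant, itself a
tested property) plus 100 random graphs with up to 8 nodes. Cascade
conservation runs over 50 random 30-node fixtures crossed with all six
order × ranking combinations; the attack-tolerance contrast uses
Barabási–Albert networks with $n = 200$, $m = 2$ over 50 seeds, where
generalist-first collapse is expected to beat specialist-first in at least
95% of seeds. These sizes give stable statistics while keeping a full run in
well under a minute; the algorithms themselves carry no such limits, and the
cascade engine touches only plain edge arrays per step, so desk-scale
networks (hundreds of nodes, ~1000 edges) run interactively.

## Known limitations

* Directed edges, edge weights, and self-loops as functional entities are
  out of scope; input is simplified to binary undirected form on parsing.
* Partial "knock-down" perturbations and gain-of-function additions (new
  nodes or edges) are not modeled; removal is the only operator.
* Rankings other than degree (betweenness-, closeness-, eigenvector-ordered
  attacks) are not part of the supported surface.
* `compare_curves()` aligns curves by step/percentage from the same original
  size; it does not interpolate between grids, so curves from different
  networks are rejected rather than resampled.
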