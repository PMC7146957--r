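---
title: "Condensing enriched GO term lists into non-redundant clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condensing enriched GO term lists into non-redundant clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gomclust)
```

## The problem

GO enrichment analysis of a gene list from an -omics experiment routinely
returns hundreds of over-represented terms. Because the Gene Ontology is a
hierarchy, these lists are heavily redundant: parent terms contain or
partially overlap their children, and one gene contributes to many terms.
Interpreting such a list by hand means mentally grouping terms that
describe the same underlying biology.

`gomclust` automates that grouping. Terms become nodes of a similarity
network whose edges are weighted by the overlap of the terms' *test-set
gene members*; the network is partitioned with Markov Clustering (MCL)
into strict, non-overlapping clusters; clusters are then evaluated,
optionally sub-clustered, and exported as tables, figures and Cytoscape
files. The output contract is a strict partition: unlike grouping schemes
that may assign one term to several groups, every term belongs to exactly
one cluster.

## The model

### Similarity between terms

For two terms with test-set gene sets $A$ and $B$:

* Jaccard coefficient, $JC = |A \cap B| / |A \cup B|$ — preferred when
  terms annotate similarly many genes;
* overlap coefficient, $OC = |A \cap B| / \min(|A|, |B|)$ — saturates at 1
  when one set contains the other, which is what removes the
  parent-inside-child redundancy between disproportionately sized terms.

Always $0 \le JC \le OC \le 1$. Similarity is computed over the test-set
members reported by the enrichment tool, not over the full reference
annotation: the input files carry only test-set members, and it is the
experiment's genes whose functional themes are being summarized.

An edge is stored when the similarity reaches the cutoff
(default `0.5`, inclusive — a pair sitting exactly at the cutoff is
connected). Before the network is built, overly broad terms whose
*reference annotation size* `n` exceeds `max_size` are trimmed away
(strictly greater; the default 3500 suits an Arabidopsis-scale
annotation): a term annotating many thousands of genes is rarely a
meaningful functional label and glues otherwise distinct clusters
together. Dialects that do not report `n` leave it as `NA`, and `NA`-sized
terms are never trimmed (their breadth cannot be judged).

### Markov Clustering

MCL simulates flow on the weighted network. The edge-weight matrix (plus a
self-loop of weight 1 on every node, the standard guard for aperiodicity)
is normalized to column-stochastic form and then alternately

* **expanded** — squared, spreading flow along longer paths — and
* **inflated** — taken to an entrywise power $r$ and renormalized,
  sharpening strong currents and starving weak ones.

The iteration converges to a near-idempotent limit in which a few
*attractor* rows hold all the mass; each attractor system's positive row
entries are one cluster. The inflation exponent is the user-facing
granularity: the default `1.5` gives coarse clusters, raising it towards
`2.0` splits them more finely.

Numerical choices (all deterministic, no randomness anywhere in the
clustering path):

* entries below `1e-5` are pruned to zero during inflation;
* iteration stops when the largest entry change falls below `1e-6`
  (at most 100 iterations; non-convergence warns and reads the last
  iterate);
* a node claimed by several attractor systems goes to the system with the
  largest entry; claims within `1e-5` of each other are treated as exact
  ties — the iterate is only converged to a finite tolerance, so
  sub-tolerance differences are rounding noise, not signal. Exact ties
  resolve by the cluster with more total test-set genes, then by the
  lexicographically smallest attractor accession. This makes the partition
  reproducible bit-for-bit across platforms;
* edge *weights* feed the matrix, not a binarized adjacency: a pair of
  terms sharing 90% of members should pull harder than a pair at the
  cutoff.

### Ordering, labels and representatives

Clusters are ordered by the number of genes they cover — the size of the
*union* of their members' gene sets (a sum would double-count genes shared
by sibling terms) — and labeled `C1`, `C2`, ... Ties order by member
count, then by smallest member accession, so labels are reproducible. For
each cluster three candidate representatives are tagged: the member with
most test-set genes, the one with the smallest p-value, and the one
connected to most other members in the network.

### Cluster evaluation and sub-clustering

For every cluster the full distribution of pairwise similarities among its
members is recomputed with the network cutoff ignored, so
non-overlapping member pairs contribute zeros. The headline statistic
`p_above` is the fraction of pairs at or above the threshold (default 0.5;
pairs exactly at the threshold count as above). A cluster whose `p_above`
is low contains members that rarely overlap — a candidate for
sub-clustering. Singleton clusters report `p_above` as `NA`: cohesion of a
one-member cluster is undefined, which is different from 0 or 1.

Sub-clustering re-runs trimming, network construction and MCL on one
cluster's members only, typically with a smaller `max_size` (e.g. 2000)
and higher inflation (e.g. 1.8). Members removed by the tighter trim are
reported as "not passed" rather than silently dropped. Sub-groups are
labeled `C1-1`, `C1-2`, ... (ASCII hyphen, for file-safe, locale-proof
output).

### Ontology handling

The OBO 1.2 flat file is parsed into a validated DAG: accessions must
match `GO:` + seven digits, `is_a` over non-obsolete terms must be
acyclic, alternate accessions map to canonical ones, obsolete terms are
kept but barred from depth/ancestor queries, and enrichment rows naming
unknown or obsolete terms are dropped with a warning and listed in the run
report.

Term *depth* is the length of the **shortest** `is_a` path from the
namespace root (root depth 0). Shortest-path depth over `is_a` only is the
common convention in GO tooling and is deterministic; `part_of` is parsed
and available to hierarchy queries behind the `relations` argument, but
excluded from depth.

The per-cluster hierarchy view computes ancestor reachability in the full
ontology, restricts it to member pairs, and removes every edge that is
implied by a path through another *member* (transitive reduction over the
members). Remaining edges are tagged `direct` when the ontology lists the
parent immediately, `transitive` when the connection runs only through
non-member terms — the solid-black versus grey distinction in the
hierarchy figures. Reduction over members keeps the drawing readable and
is exactly testable against a brute-force reachability oracle.

## Input dialects

Five layouts are read into one normalized record (accession, description,
namespace, corrected p-value, test-set count `x`, annotation size `n`,
gene member set): BiNGO `.bgo`, g:Profiler GEM, agriGO and GOrilla tabular
exports, and a documented generic TAB-separated layout (`GO_ID`,
`Description`, `P_value`, `n`, `Genes`). Where a tool reports both raw and
corrected p-values the corrected one is used — it is the value the tool
itself headlines. Gene identifiers are upper-cased before comparison;
mixed-case symbols across tools would otherwise silently destroy
overlaps. `x` is always recomputed from the deduplicated member list.
GEM exports carry no annotation size, so `n` is `NA` there and size
trimming does not apply to them.

## The synthetic fixture generator

Real enrichment output plus a full ontology is too large and too entangled
to reason about in tests, so the package ships a planted-block generator
(`planted_design()` / `generate_fixture()`) that emits a miniature
ontology and a matching generic-dialect enrichment table:

* each block owns a disjoint gene pool; every term draws a shared core
  (`within_block_shared_fraction`, default 0.8 of its 20 genes) plus
  private genes, so within-block overlap coefficients are at least 0.8 and
  between-block coefficients are exactly 0 (with the default
  `between_block_shared_fraction = 0`);
* two-level designs split each block into two sub-blocks with disjoint
  cores and add one broad *bridge* term per block spanning all the block's
  genes. The bridge welds the sub-blocks into one cluster in a default
  run; its annotation size is drawn large (default 3000), so the usual
  sub-clustering move — tightening `max_size` to 2000 and raising
  inflation to 1.8 — removes it and the sub-blocks separate into
  components. This mirrors how broad parent terms link distinct themes in
  real GO lists, and how trimming them apart exposes the sub-structure;
* ordinary terms draw `n` uniformly from 200–1500 and p-values from
  (1e-10, 0.05) — magnitudes typical of enrichment output; neither value
  affects the planted topology;
* block/sub-block truth labels are returned, so recovery can be scored
  with the adjusted Rand index.

What passing on these fixtures shows — and what it does not: recovery of
planted, well-separated overlap structure is a necessary correctness
check for the whole path (parsing → trimming → network → MCL → labels),
but real GO lists have graded overlaps, shared genes across themes and no
ground truth; on real data cluster boundaries legitimately move with the
cutoff and inflation, which is why the evaluation and sub-clustering
tools exist.

## Problem sizes used in the checks

The test suite verifies the MCL core against an independently coded,
unoptimized dense iteration: exhaustively over every graph on up to 4
nodes with edge weights in {0.5, 1.0} (all 3^6 weightings of the 6
possible edges, plus the smaller families), and over 1500 seeded random
graphs each at 5 and 6 nodes from the same family. Exhausting 5- and
6-node graphs (3^10 and 3^15 weightings) is computationally out of reach
of any reasonable suite; the sampled check covers the same family at the
same parameters. Planted-recovery checks run the full pipeline across ten
generator seeds at both levels. Hierarchy reconstruction is checked
against a brute-force oracle on random DAGs of up to 50 terms.

## Known limitations

* Exact reproduction of cluster memberships published with other MCL
  front-ends can depend on their (often undocumented) self-loop, pruning
  and convergence choices; this package documents its own
  (`self_loop = 1`, `prune = 1e-5`, `tol = 1e-6`) and exposes them.
* The dense matrix implementation targets the hundreds-of-terms scale of
  enrichment summaries, not networks of tens of thousands of nodes.
* Similarity is strictly member-overlap based; semantic similarity
  measures over the ontology graph are a different summarization
  philosophy and are not provided.
* Only OBO 1.2 flat files are parsed (GO-slim ontologies are simply
  smaller OBO files and work unchanged); OWL/RDF is not supported.

## A worked run

```{r example}
fx <- generate_fixture(planted_design(n_blocks = 2, levels = 2, seed = 1))
graph <- read_obo(fx$obo)
enr <- read_enrichment(fx$enrichment)
result <- run_gomcl(enr, graph)
result

result_cohesion(result)

sub <- run_gomcl_sub(result, c("C1", "C2"), max_size = 2000,
                     inflation = 1.8)
sub
```

The same pipeline is available from the shell via the installed
`gomclust` script (`run`, `sub` and `fixture` subcommands); every
subcommand is a thin wrapper over the functions shown above.
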