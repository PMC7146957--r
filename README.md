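# gomclust

Condense long, redundant lists of enriched Gene Ontology (GO) terms into
non-overlapping functional clusters.

GO enrichment analysis of a differential gene list routinely returns
hundreds of over-represented terms, most of which restate each other:
parents overlap children, and one gene feeds many terms. `gomclust`
summarizes such a list by connecting terms that share test-set gene
members into a similarity network and partitioning it with Markov
Clustering (MCL) into a strict partition — every term lands in exactly
one cluster. It is aimed at anyone interpreting GO enrichment output from
RNA-seq, microarray, proteomics or epigenomics experiments.

## Method in brief

For two terms with test-set gene sets *A* and *B*, similarity is either
the Jaccard coefficient *JC* = |A∩B| / |A∪B| or the overlap coefficient
*OC* = |A∩B| / min(|A|, |B|) (default; saturates when one set contains
the other, which is what collapses parent/child redundancy). The
pipeline:

1. drop overly broad terms (reference annotation size *n* > `max_size`,
   default 3500), optionally restrict to BP/MF/CC namespaces;
2. connect term pairs with similarity ≥ `cutoff` (default 0.5);
3. partition the weighted network with a deterministic MCL
   (expansion × inflation; inflation is the granularity, default 1.5);
4. order clusters by the union of member gene sets, label them `C1`,
   `C2`, …, and tag representative terms (most genes / smallest p /
   highest degree);
5. evaluate each cluster by the distribution of all pairwise member
   similarities (`p_above` = fraction of pairs ≥ 0.5), and optionally
   sub-cluster selected clusters with tighter parameters (`C1-1`,
   `C1-2`, …, with trimmed-out members reported as "not passed").

Inputs: a GO ontology in OBO 1.2 flat format, plus enrichment output from
BiNGO, g:Profiler (GEM), agriGO, GOrilla, or a documented generic
TAB-separated layout. Outputs: cluster/summary/cohesion tables, per-term
ontology depth, per-cluster GO hierarchy (direct vs through-intermediate
edges), Cytoscape SIF + attribute tables, and heatmap / network /
CDF / hierarchy figures, each with a machine-readable companion table.

## Worked example

```r
library(gomclust)

# a synthetic fixture: 2 planted blocks, each split into 2 sub-blocks
# welded together by one broad "bridge" term
fx     <- generate_fixture(planted_design(n_blocks = 2, levels = 2, seed = 1))
graph  <- read_obo(fx$obo)
enr    <- read_enrichment(fx$enrichment)   # dialect auto-detected
result <- run_gomcl(enr, graph)            # OC >= 0.5, inflation 1.5
result
#> GO term clustering: 22 terms -> 2 clusters [ OC >= 0.5 , inflation 1.5 , max term size 3500 ]
#>   C1      11 terms,   72 genes; rep: GO:0000015
#>   C2      11 terms,   72 genes; rep: GO:0000029
```

Each planted block came back as one cluster of 11 terms covering 72
genes; the tagged representative is the broad bridge term, which
annotates the most genes. Cohesion shows why these clusters are worth a
second look:

```r
result_cohesion(result)
#> $C1
#> C1: 11 members, 55 pairs, P(>= 0.50) = 0.545
#> $C2
#> C2: 11 members, 55 pairs, P(>= 0.50) = 0.545
```

Only 55% of member pairs overlap strongly — the signature of a cluster
holding two themes. Sub-clustering with a tighter term-size cutoff and
higher granularity separates them:

```r
run_gomcl_sub(result, c("C1", "C2"), max_size = 2000, inflation = 1.8)
#> C1 : 2 sub-groups ( 10 terms passed, 1 not passed )
#>   C1-1       5 terms,   36 genes
#>   C1-2       5 terms,   36 genes
#> C2 : 2 sub-groups ( 10 terms passed, 1 not passed )
#>   C2-1       5 terms,   36 genes
#>   C2-2       5 terms,   36 genes
```

The bridge term fails the tighter trim ("not passed"), and each
sub-group is exactly one planted sub-block.

The same pipeline runs from the shell:

```sh
gomclust run --obo go.obo --input enrichment.bgo --outdir out --cohesion -g
gomclust sub --obo go.obo --input enrichment.bgo --clusters C1 \
         --max-size 2000 --inflation 1.8 --outdir out_sub
```

See `vignettes/go-term-clustering.Rmd` for the model, parameter and
design details.

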