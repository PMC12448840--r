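# ppiEnrich

Network-aware pathway enrichment analysis from protein embedding
correlations.

## The problem

Classical over-representation analysis (ORA) scores a query gene/protein
list against annotated gene sets by counting shared genes, so a pathway
that shares *no* gene with the query is invisible — even when the query's
proteins interact densely with the pathway's proteins in the
protein–protein interaction (PPI) network. `ppiEnrich` addresses this for
anyone running functional interpretation of gene lists (disease gene
panels, proteomics hits, screening results) who also has access to a
STRING-style interaction network.

## The method

Each protein *P* is represented by an embedding vector *h<sub>P</sub>*
learned from the PPI graph by a graph neural network trained on link
prediction (sequence-derived node features, GIN-style sum-aggregation
layers, logistic inner-product edge scores). A query of *N* encoded
proteins and a pathway of *M* encoded proteins give the correlation matrix

&nbsp;&nbsp;&nbsp;&nbsp;C<sub>kl</sub> = cor(h<sub>P_k</sub>, h′<sub>P_l</sub>)&nbsp;&nbsp;(Pearson),

which is then **filtered** (entries not strictly above 0.9 are zeroed) and
**overlap-masked**: when query gene k and pathway gene l are the same
gene, C<sub>kl</sub> is pinned to 1 and the rest of column l is zeroed, so
an exact overlap cannot double as interaction signal. Splitting C into its
overlap indicator part C<sup>ov</sup> and interaction part C<sup>int</sup>,
the weighted enrichment score is

&nbsp;&nbsp;&nbsp;&nbsp;WES = mean<sub>k</sub> max<sub>l</sub> ( C<sup>int</sup> + β·C<sup>ov</sup> )<sub>kl</sub>,

with β ≥ 1 the overlap weight: β = 1 treats a shared gene like a perfect
correlation (the plain enrichment score ES), large β makes the score
overlap-dominated like ORA. Significance is assessed against an empirical
null of random same-size gene lists drawn from the embedding universe
(p = (b+1)/n with b the exceedance count; minimum 1e-5 at the reference
n = 100 000 permutations), followed by Benjamini–Hochberg FDR control per
collection.

## Worked example

Everything below runs from synthetic fixtures generated in code — a
120-protein, 4-community interaction graph with planted-correlation
embeddings, and three pathways: one sharing half the query
(`overlap_rich`), one disjoint from the query but from its network
community (`overlap_free_linked`), one unrelated.

```r
library(ppiEnrich)
paths <- makeFixtures("demo", nNodes = 120, nCommunities = 4, seed = 1)
res <- runEnrich(paths[["query"]], paths[["gmt"]], paths[["embeddings"]],
                 paths[["edges"]], "demo/results.tsv",
                 beta = 1, nPermutations = 1000)
res
#> EnrichmentTable for query 'query' (10 encoded protein(s)): 3 pathway(s), beta 1
#>            pathway_id pathway_size overlap coverage interactions     score pvalue    bh
#> 1        overlap_rich           10       5      0.5           11 0.5000000  0.564 0.846
#> 2 overlap_free_linked           10       0      0.0           33 0.4559613  0.023 0.069
#> 3           unrelated           10       0      0.0            1 0.0000000  1.000 1.000
```

At β = 1 the pathway with **zero gene overlap** but 33 query–pathway PPI
edges gets the smallest p-value: its members' embeddings correlate with
the query's above the 0.9 filter. The half-overlapping pathway scores
exactly 0.5 (5 of 10 query rows pinned to 1, the masked columns
contribute nothing else) — unremarkable against a null in which random
lists also pick up correlated proteins. Scanning β shows the regime
switch:

```r
runBetaScan(paths[["query"]], paths[["gmt"]], paths[["embeddings"]],
            paths[["edges"]], betas = c(1, 10, 40), nPermutations = 1000)
#>           pathway_id beta      score pvalue    bh
#>         overlap_rich    1  0.5000000  0.564 0.846
#>  overlap_free_linked    1  0.4559613  0.023 0.069
#>            unrelated    1  0.0000000  1.000 1.000
#>         overlap_rich   10  5.0000000  0.001 0.003
#>  overlap_free_linked   10  0.4559613  0.590 0.885
#>            unrelated   10  0.0000000  1.000 1.000
#>         overlap_rich   40 20.0000000  0.001 0.003
#>  overlap_free_linked   40  0.4559613  0.590 0.885
#>            unrelated   40  0.0000000  1.000 1.000
```

As β grows the overlap-rich pathway's score scales with β and it becomes
the significant hit, while the interaction-linked pathway loses rank —
the two complementary detection regimes the β weight trades between.

Embeddings can also be trained from scratch instead of using the planted
table:

```r
emb <- runEncode(paths[["edges"]], paths[["fasta"]], "demo/embeddings_trained.tsv")
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/ppienrich.R enrich --query demo/query.txt \
  --gmt demo/pathways.gmt --embeddings demo/embeddings.tsv \
  --edges demo/edges.tsv --out demo/results.tsv --beta 10 --permutations 1000
```

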