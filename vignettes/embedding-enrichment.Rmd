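---
title: "Embedding-correlation pathway enrichment: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding-correlation pathway enrichment: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiEnrich)
```

## The model

`ppiEnrich` scores a query gene/protein list against pathway gene sets
through three layers.

**Protein encoding.** Proteins are nodes of an undirected PPI graph; node
input features come from the amino-acid sequence; a graph neural network
trained on link prediction produces one embedding vector per protein. The
working assumption is that two proteins that are close in the interaction
network (and similar in sequence composition) end up with correlated
embeddings — so embedding correlation is a learned, continuous proxy for
functional relatedness that extends beyond directly annotated overlap.

**Set encoding and scoring.** A query of $N$ encoded proteins and a
pathway of $M$ encoded proteins are stacked into row matrices
$h_\text{query}$ and $h_\text{pathway}$. The score pipeline is, in fixed
order:

1. Pearson correlation matrix $C \in [-1, 1]^{N \times M}$ between all
   query/pathway embedding pairs;
2. filtration: entries **not strictly above** the threshold (default
   0.9) are zeroed, discarding weak or negative association;
3. overlap masking: if query gene $k$ and pathway gene $l$ are the same
   identifier, $C_{kl} := 1$ and every other entry of column $l$ is set
   to 0. Identity is decided by identifier equality, not by testing
   $r = 1$ in floating point: a same-gene pair is definitionally an
   overlap, and a numerically perfect correlation between two *different*
   genes remains interaction signal;
4. decomposition $C = C^\text{ov} + C^\text{int}$ into the binary overlap
   indicator and the remainder;
5. weighting and reduction:
   $\mathrm{WES} = \frac{1}{N} \sum_k \max_l \left(C^\text{int} + \beta\,
   C^\text{ov}\right)_{kl}$, with all-zero rows contributing 0.

The score is bounded by $[0, \beta]$, is non-decreasing in $\beta$, and is
invariant to affine rescaling of the embeddings (Pearson invariance) — the
package asserts all three as properties, plus exact agreement with a
straight-line nested-loop re-implementation, in its test suite.

**Significance.** The null distribution of the score for a pathway is
estimated by drawing random identifier lists of the same size as the
encoded query, uniformly without replacement from the embedding universe,
and re-scoring each against the pathway with the identical configuration.
One batch of lists is shared by all pathways of a run; because the score
depends on $\beta$ and the threshold, null scores are recomputed whenever
those change. The p-value is the add-one exceedance estimator
$p = \min(1, (b+1)/n)$, never 0, with minimum $1/n$ (1e-5 at the
reference 100 000 permutations). BH adjustment is applied per collection,
excluding pathways that had no encodable member.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 10 | overlap weight (unitless, $\ge 1$); 1 = pure ES, large = ORA-like. 10 is the trade-off point where both overlap- and interaction-driven hits surface |
| `corrThreshold` | 0.9 | correlation filtration cutoff, strict `>` |
| `missingAsZero` | FALSE | whether query genes without embeddings count as zero rows in the score's mean (default: dropped; the mean runs over encoded query proteins, which is also the size used for null lists) |
| `nPermutations` | 100000 | null lists; cost scales as permutations × pathways. Reference analyses use 1e5; the test suite uses 500 |
| `embeddingDim` | 64 | protein embedding length (≥ 3; Pearson needs ≥ 3 coordinates) |
| `epochs`, `learningRate` | 200, 0.01 | Adam training budget of the encoder |
| `trainFraction` | 0.8 | edge split for link-prediction validation |
| `maxLength` | 512 | residue featurization truncation/padding target |

A single global seed fans out to encoder, null-sampling and fixture
sub-seeds by fixed offsets, so one integer reproduces a full run.

## Encoder design

The encoder is written in base R with hand-derived gradients. Design
choices, made where the architecture was genuinely open:

* **Node features.** Default is the 20-dimensional amino-acid composition
  vector (`mean-composition`); a `conv1d` front end is available that
  pools a seeded, *fixed* random 1D-convolution filter bank over the
  27-channel per-residue featurization (20 one-hot + 7 physicochemical
  classes: aliphatic, aromatic, positive, negative, polar-uncharged,
  cysteine, proline — a classic grouping that partitions the alphabet).
  Fixed random filters keep the front end deterministic and cheap; the
  trainable graph layers sit on top. Sequences are truncated from the
  C-terminus (the N-terminal prefix is kept).
* **Graph layers.** GIN-style sum aggregation $S = A + I$, two layers by
  default, ReLU between layers, linear output. Message passing during
  training uses train edges only, so held-out edges stay unseen;
  inference aggregates over the full edge set.
* **Objective.** Binary cross-entropy of logistic inner-product edge
  scores (logit scaled by $1/\sqrt{d}$ to avoid sigmoid saturation)
  against non-edges resampled each epoch at a 1:1 ratio. Interaction
  types are collapsed to a single "interacts" relation — downstream
  scoring consumes only embeddings, never edge labels. Mild L2
  regularization (1e-3) and selection of the best-validation-AUC epoch
  checkpoint counter the rapid memorization small graphs invite.
* **Model selection.** The embedding dimension is chosen by grid search
  maximizing validation AUC (ties to the smaller dimension) — a
  deterministic, desk-scale stand-in for black-box hyperparameter
  optimization, using the same selection criterion.
* Embeddings are exported raw: Pearson correlation is location/scale
  invariant, so any post-hoc normalization would be a no-op.

## What the synthetic generators emulate — and what they do not

The generators supply every input format at toy scale: stochastic block
model (SBM) graphs stand in for the community structure of curated PPI
networks; uniform random sequences exercise the featurization; planted
embeddings ($v = \sqrt{\rho}\,g_\text{block} + \sqrt{1-\rho}\,e$, all
coordinates standard normal) give a *controlled* within-block correlation
$\rho$ so scoring and significance can be validated independently of
encoder quality; scenario collections construct the two regimes the
method distinguishes (overlap-rich vs overlap-free-but-network-linked).

Real data differ in ways the fixtures deliberately ignore: scale-free
degree distributions and hub proteins, sequence homology structure,
noisy/incomplete interaction evidence, and identifier-mapping friction
between gene-symbol gene sets and protein-identifier networks (the
package matches identifiers case-sensitively and performs no mapping — a
separate concern). Passing tests therefore demonstrate correctness of the
algorithmics and calibration under the stated generative conditions, not
biological performance.

## Numerical choices and degenerate inputs

* Zero-variance embedding vectors get correlation 0 by convention (they
  could never pass the filter; this avoids 0/0).
* Correlations are computed via standardized row cross-products and
  clamped to $[-1, 1]$ against rounding spill.
* A pathway with no encodable member is emitted with score 0, flagged
  `skipped`, and excluded from the BH family.
* An empty correlation matrix scores 0 with an `empty` flag.
* Results files sort by BH, then p, then descending score, with
  pathway identifier as the final deterministic tie-break.
* Edge lists are canonicalized on load: self-loops removed, symmetric
  duplicates merged keeping the maximum combined score.

The null-calibration check in the acceptance suite uses unstructured
3-dimensional embeddings: with few coordinates the pairwise correlation
distribution is wide, so null scores are continuous and empirical
p-values can actually be uniform. High-dimensional unstructured
embeddings would put nearly all mass at score 0 and p = 1 — uniformity of
empirical p-values presupposes a continuous statistic, which is a
property of the fixture, not of the estimator.

## Problem sizes used in the checks

Validation runs use 120-node, 4-community SBM graphs ($p_\text{in}=0.3$,
$p_\text{out}=0.01$), queries of ~10, pathways of ~10–15 members, 500
permutations (300–1000 where noted), 100-instance oracle sweeps and
20-seed encoder replicates — sizes at which every claim is recomputable
in seconds while the statistics (AUC, KS, detection rates) remain
well-powered.

## Known limitations

* The max–mean reduction ignores how *many* pathway proteins a query
  protein correlates with beyond its best match.
* Null lists are uniform over the universe; degree-stratified or
  annotation-stratified nulls are not implemented.
* The permutation null at the reference 100 000 permutations is
  expensive for large collections (cost ∝ permutations × pathways).
* No identifier mapping: query, gene sets, network and embeddings must
  share one namespace.
* The encoder is desk-scale: full proteome-wide training is out of its
  intended range, and a precomputed embedding table can be supplied
  instead wherever one exists.
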