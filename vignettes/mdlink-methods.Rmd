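---
title: "Predicting miRNA-disease associations from a molecular association network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA-disease associations from a molecular association network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdlink)
```

## The problem

Only a small fraction of miRNA-disease associations has been confirmed
experimentally, so computational ranking of candidate pairs is used to
prioritise laboratory work. mdlink implements a pipeline that scores
miRNA-disease pairs by combining two complementary views of every
molecule:

* **attribute information** — what the molecule *is*: sequence-derived
  features for miRNAs and ontology-derived semantic similarity for
  diseases;
* **behaviour information** — how the molecule *connects*: graph
  embeddings of a heterogeneous molecular association network (MAN) over
  five node types (miRNA, lncRNA, protein, disease, drug) linked by nine
  undirected association types.

A binary classifier over the fused pair descriptor produces the
association score.

## Attribute features

### Chaos game representation of miRNA sequences

Each sequence is mapped into the unit square: starting from
$T_0 = (0.5, 0.5)$, base $i$ with corner $G_i$ (A at (0,0), C at (0,1),
U at (1,0), G at (1,1)) moves the point by

$$T_i = T_{i-1} + c\,(G_i - T_{i-1}), \qquad c = 0.5 .$$

This is the classical midpoint contraction; it keeps every point inside
the unit square, which is what makes the subsequent spatial partition
meaningful (the additive variant $T_{i-1} + c\,(T_{i-1} - G_i)$ diverges
and is therefore not usable with a bounded partition). The square is
divided into an $8 \times 8$ grid of half-open cells $[k/8, (k+1)/8)$
(a coordinate equal to 1 clamps into the last cell; points exactly on a
gridline belong to the higher-index cell). Cell $i$ is summarised by the
triple $(X_i, Y_i, Z_i)$: the sums of the $x$ and $y$ coordinates of its
points and the z-score of its point count across the 64 cells (population
standard deviation; if all counts are equal all $Z_i$ are defined as 0).
The 64 triples are flattened cell-major into a 192-long descriptor, and
miRNA sequence similarity is the Pearson correlation of two descriptors.
Whether the correlation should run over the flattened vector or
per-component is a genuinely open choice; the flattened form is used
because it is the only one that yields a single scalar directly.

### Disease semantic similarity

Each disease carries one or more MeSH tree numbers. Ancestors are
derived by repeatedly stripping the final dot-component — the standard
MeSH convention — giving a small DAG per disease. The disease itself
contributes 1 and an ancestor $T$ contributes
$D(T) = \max_{T' \in \mathrm{children}(T)} \vartheta\, D(T')$ with decay
$\vartheta = 0.5$, so a term reachable at several depths takes its
largest (shortest-path) value. The semantic value $DV$ of a disease is
the sum of its contributions, and the similarity of two diseases is the
sum of both contributions over shared terms divided by $DV(a) + DV(b)$ —
1 for identical DAGs, 0 for disjoint ones. When the input table itself
names an ancestor (its tree number appears as a prefix), that disease id
is used as the term identity so the same heading at two depths is one
term. Diseases without tree numbers receive self-only DAGs (similarity 1
with themselves, 0 elsewhere) with a warning instead of being dropped,
so the labeled pair set never silently shrinks.

## Behaviour features: structural deep network embedding

The MAN is held as a symmetric binary adjacency matrix $S$ with zero
diagonal and deterministic node order (sorted by type then id, so
embeddings are reproducible run to run). A deep autoencoder maps each
adjacency row $x_i$ through sigmoid layers to a 128-long code $y_i$ and
back. Three penalties are combined:

* second-order proximity: $\lVert (\hat X - X) \odot B \rVert_F^2$ with
  $B_{ij} = \beta$ where $x_{ij} > 0$ and 1 elsewhere, so the many zeros
  of a sparse adjacency cannot dominate reconstruction ($\beta = 5$);
* first-order proximity: $\alpha \sum_{i,j} s_{ij}\lVert y_i - y_j
  \rVert^2$ over ordered pairs (each undirected edge counts twice),
  pulling connected nodes together ($\alpha = 0.05$);
* weight decay: $\nu \cdot \tfrac12 \sum_k (\lVert W^{(k)} \rVert_F^2 +
  \lVert \hat W^{(k)} \rVert_F^2)$ over encoder and decoder matrices,
  offsets excluded ($\nu = 10^{-4}$).

Training is mini-batch Adam (batch 64, full batch for smaller networks)
with the first-order term evaluated on within-batch pairs; all
initialisation and shuffling derive from one integer seed. Layer sizes
($N \to 512 \to 128$), the optimiser and the schedule are not dictated
by the method itself; the defaults follow common practice for this
embedding family and are all exposed in `sdne_config()`. Gradients of
the composite loss are analytic and are verified against finite
differences in the test suite.

## Feature fusion

The two similarity matrices are compressed to 64 dimensions per entity
by a stacked autoencoder (input → 256 → 64, sigmoid hidden layers,
linear code and output so negative correlations are representable,
full-batch Adam on the mean squared reconstruction error, 100 epochs).
The fused descriptor of a pair $(i, j)$ is the concatenation

$$FD(i,j) = [\,M_b(i)\ (128),\ M_{sim}(i)\ (64),\ D_b(j)\ (128),\
D_{sim}(j)\ (64)\,]$$

of behaviour and attribute vectors — 384 values with block boundaries at
128 / 192 / 320. Unknown pairs are sampled uniformly without replacement
as negatives at a configurable ratio (default 1:1, the standard choice
for this task family when the true ratio is unknown).

## Classifier

The descriptor is treated as a length-384 one-channel signal passed
through two valid stride-1 convolutions (32 then 64 filters, 3×1
kernels), one 2×1 max-pooling, a flatten, a 64-unit dense layer with
dropout 0.5 and a 2-way softmax. Three numerical choices matter on
inputs of this kind (sigmoid-scaled embedding blocks next to
linear-scale attribute blocks):

* features are standardised per column inside `fit()` using training
  statistics, reapplied at prediction;
* activations are leaky ReLU (slope 0.01) so no unit can die
  irreversibly after an aggressive early optimiser step;
* the output layer is initialised at one tenth of the He scale so the
  initial logits are near zero and the first softmax gradients are
  well-conditioned.

Without these the network can collapse to predicting the class prior on
exactly this input geometry. Max-pooling ties keep the earliest
position, making prediction fully deterministic. A registry of baseline
classifiers (bagged trees, ridge logistic regression, Gaussian naive
Bayes, AdaBoost.M1 over decision stumps, a single-hidden-layer MLP)
implements the same `fit()`/`predict_proba()` contract so the evaluation
harness can swap models freely.

## Evaluation design

Cross validation splits the known positive pairs into five disjoint
near-equal folds. For each fold:

1. the test-fold miRNA-disease edges are removed from the network
   *before* the embedding is computed (other edge types stay intact);
2. attribute compression is fitted on training-fold entities' similarity
   rows and applied to all entities (the matrices themselves are
   label-free);
3. train and test negatives are sampled disjointly from unknown pairs,
   excluding **all** positives;
4. the classifier sees training rows only.

A programmatic audit records, per fold, that no test positive survives
as a network edge or training row. Metrics are the standard confusion
quantities at threshold 0.5 (the threshold is exposed because reported
operating points in this literature rarely state it), MCC (defined as 0
when a confusion margin is empty), AUC via the rank-sum statistic with
midrank tie correction (deterministic and checkable against the
all-pairs definition), and AUPR as average precision over unique score
thresholds. Case-study ranking trains on every known positive and
scores all miRNAs not yet associated with the query disease, ties broken
lexicographically by id.

## Synthetic fixtures and what they show

The generators produce all pipeline inputs with a planted block
structure: nodes of every type are assigned round-robin to 3 blocks;
miRNA-disease edges appear with probability `p_in = 0.3` inside matched
blocks and `p_out = 0.02` across; the other eight association types use
densities 0.15 / 0.02 with the same block correlation; miRNAs of a block
share a planted 6-mer motif inside otherwise random 20-25 nt sequences;
diseases of a block attach to a shared tree-number backbone at random
depths. Default scale is 60 miRNAs, 40 diseases, 50 proteins, 30
lncRNAs, 30 drugs — small enough that a full five-fold run takes a few
minutes on one core. The package's own evaluation runs use
`fixture_pipeline_config()` — 30 SDNE epochs and 20 CNN epochs, all
other defaults unchanged — a schedule sized to this fixture scale.

One property of the generator is worth stating precisely: because
miRNA-disease edges are sampled independently given the blocks, block
membership is the *only* signal that generalises to held-out pairs, and
the best achievable mean CV AUC equals the AUC of a perfect block
oracle, about 0.81 under the default densities with 1:1 uniform
negatives. Observed fused-pipeline AUCs just above 0.80 therefore mean
the classifier is essentially Bayes-optimal on this fixture — not that
the pipeline is weak. Equally, the fixture does not emulate real data's
degree heterogeneity, shared-neighbour correlations, ontology depth or
sequence family structure, so passing these tests shows the machinery is
correct and leakage-free, not that real-data performance matches any
particular figure.

## Numerical and degenerate-input conventions

* Zero-variance CGR descriptors make Pearson similarity undefined: an
  error, never a silent NA.
* Constant subspace counts give all-zero z-scores.
* Gridline coordinates round to the higher-index cell; 1.0 clamps down.
* Every stochastic routine takes a mandatory seed; stage seeds derive
  from one master seed through a deterministic hash, and the caller's
  RNG state is always restored.
* Isolated nodes keep all-zero adjacency rows rather than being dropped,
  so node indexing is stable across folds.
* AUC on single-class inputs raises an error instead of returning 0.5.
* Networks smaller than the batch size train full-batch.

## Known limitations

* Dense adjacency storage targets networks up to a few thousand nodes;
  the real-scale MAN (~6.5k nodes) fits, but much larger graphs would
  need a sparse backend.
* The CNN trains on one core; at the published data scale (tens of
  thousands of pairs) training takes correspondingly longer.
* Identifier mapping across source databases (miRNA naming, disease
  vocabularies) is the user's responsibility; the loaders take
  pre-mapped TSVs.

## A worked run

```{r, eval = FALSE}
fix <- make_fixture(fixture_spec(seed = 11))
cv <- run_cv(fix$network, fix$sequences, fix$mesh, fix$positives,
             fixture_pipeline_config(), seed = 5)
glance(cv)
autoplot(cv)

model <- fit_pipeline(fix$network, fix$sequences, fix$mesh, fix$positives,
                      fixture_pipeline_config(), seed = 5)
rank_candidates(model, fix$positives$disease_id[1], k = 10)
```
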