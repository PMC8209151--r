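# mdlink

Predicting miRNA–disease associations from a heterogeneous molecular
association network.

Experimentally confirmed miRNA–disease associations cover only a small
part of the real association landscape, so computational models are used
to rank candidate pairs for laboratory follow-up. `mdlink` implements a
complete link-prediction pipeline over a molecular association network
(MAN) — an undirected graph over five node types (miRNA, lncRNA,
protein, disease, drug) joined by nine association types — and fuses two
views of every molecule:

* **attribute information** — chaos-game-representation (CGR)
  descriptors of miRNA sequences and MeSH-DAG semantic similarity of
  diseases, each compressed to 64 dimensions by a stacked autoencoder;
* **behaviour information** — 128-dimensional structural deep network
  embeddings (SDNE) of the MAN adjacency, trained with a first-order
  Laplacian penalty `α Σ s_ij ‖y_i − y_j‖²`, a β-weighted adjacency
  reconstruction loss `‖(X̂ − X) ⊙ B‖²_F`, and weight decay.

Each miRNA–disease pair becomes a 384-long descriptor
`FD(i,j) = [M_b(i), M_sim(i), D_b(j), D_sim(j)]` scored by a small 1-D
CNN (two 3×1 convolutions with 32 and 64 filters, 2×1 max-pooling,
dense + softmax). Evaluation is leakage-controlled five-fold cross
validation: test-fold miRNA–disease edges are removed from the network
*before* embeddings are computed, and a per-fold audit verifies it.
Seeded generators produce synthetic inputs with planted block structure
so the entire pipeline is testable without external databases. A
registry of baseline classifiers (bagging, logistic regression, naive
Bayes, AdaBoost, MLP) shares the `fit()`/`predict_proba()` contract.

All neural components (SDNE, the stacked autoencoder, the CNN) are
implemented in base R with BLAS matrix products and Adam optimisation;
gradients are verified against finite differences in the test suite.

## Worked example

```r
library(mdlink)

# synthetic inputs with 3 planted blocks: 60 miRNAs, 40 diseases,
# 50 proteins, 30 lncRNAs, 30 drugs
fix <- make_fixture(fixture_spec(seed = 11))
fix$network
#> <hetero_network> 209 nodes, 1157 undirected edges
#>   nodes: disease=40, drug=29, lncRNA=30, miRNA=60, protein=50
#>   edge types: drug_disease, drug_protein, lncrna_disease, lncrna_protein,
#>   mirna_disease, mirna_lncrna, mirna_protein, protein_disease, protein_protein

cv <- run_cv(fix$network, fix$sequences, fix$mesh, fix$positives,
             fixture_pipeline_config(), seed = 5)
cv
#> <md_cv> 5-fold cross validation (features: fused, classifier: cnn)
#>   acc = 0.7786 ± 0.0293
#>   sen = 0.8290 ± 0.0800
#>   spec = 0.7283 ± 0.0677
#>   prec = 0.7559 ± 0.0378
#>   mcc = 0.5647 ± 0.0622
#>   auc = 0.8069 ± 0.0458
#>   aupr = 0.7742 ± 0.0473
#>   leakage audit: clean on every fold
```

The mean AUC of 0.81 equals the best achievable value on this fixture:
miRNA–disease edges are planted independently given the blocks, so a
perfect block oracle also scores ≈ 0.81 — the classifier is recovering
essentially all of the planted signal. `autoplot(cv)` draws the per-fold
ROC curves, `tidy(cv)` returns the per-fold metric table.

Ranking candidates for one disease (training on all known positives):

```r
model <- fit_pipeline(fix$network, fix$sequences, fix$mesh, fix$positives,
                      fixture_pipeline_config(), seed = 5)
rank_candidates(model, "dis001", k = 5)
#> # A tibble: 5 x 3
#>    rank mirna_id score
#>   <int> <chr>    <dbl>
#> 1     1 mir052   0.796
#> 2     2 mir022   0.778
#> 3     3 mir010   0.760
#> 4     4 mir007   0.748
#> 5     5 mir046   0.743
```

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mdlink.R", package = "mdlink"))')" \
    run --config pipeline.yaml --seed 1 --out report.json
```

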