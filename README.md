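# tgem — interpretable gene-wise self-attention for expression-based phenotype prediction

`tgem` implements **T-GEM** (Transformer for Gene Expression Modeling),
a Transformer-style classifier for bulk RNA-seq and scRNA-seq
expression in which *every gene carries its own scalar Query, Key and
Value weights*. For a sample $x \in \mathbb{R}^G$ of normalized log
expression, each head computes $q_g = w^q_g x_g$, $k_g = w^k_g x_g$,
$v_g = w^v_g x_g$ and attends each Query gene over all other Key genes,

$$a_{gi} = \mathrm{softmax}_{i \ne g}(q_g k_i), \qquad
  z_g = \sum_{i \ne g} a_{gi} v_i,$$

so the attention weights live directly on named gene–gene pairs. Head
outputs are mixed by a learned vector, layer-normalized over the gene
dimension and added to the input via a skip connection; a dense readout
produces $p(y \mid x) = \mathrm{softmax}(W \phi(z^{(L)}) + b)$.

The package is aimed at computational biologists who want phenotype
classifiers (cancer type, immune cell type, any multi-class label) that
can be *interrogated*, not just scored. Beyond training (Adam on the
multi-class negative log-likelihood, with stratified splitting,
log + min-max preprocessing and a hyperparameter grid search), it
provides the interpretation workflow:

* **attention entropy** per Query gene/head/layer (broad vs focused
  attention);
* **integrated-gradients attribution** of the attention weights toward
  a class logit, against a zero baseline;
* **pruning diagnostics** (zero one head's or layer's mixing weight,
  re-measure accuracy) and **linear-SVM probes** of head/layer outputs;
* **regulatory-network extraction**: thresholded attributions become
  directed Key → Query edges, with degree-ranked **hub genes** as
  candidate markers, SIF/GraphML export for Cytoscape;
* **hypergeometric geneset enrichment** (GMT input, BH-corrected) of
  the informative genes, with cross-layer pathway linking;
* a **synthetic-data generator** (planted markers, correlated modules)
  so the whole pipeline is testable with known ground truth;
* evaluation metrics: accuracy, multi-class Matthews correlation,
  macro one-vs-rest AUC.

## Worked example

```r
library(tgem)

# simulate a labeled cohort with planted marker genes and one correlated module
sim <- simulate_expression(n_classes = 3, n_genes = 100, n_samples_per_class = 150,
                           n_markers_per_class = 10, marker_effect = 2,
                           modules = list(list(name = "m1", size = 12, rho = 0.5)),
                           seed = 1)
sim$dataset
#> tgem_dataset: 450 samples x 100 genes, 3 classes
#> class0 class1 class2
#>    150    150    150

# 70/10/20 stratified split, then train a 1-layer 2-head model
split <- stratified_split(sim$dataset, seed = 1)
fit <- tgem_train(sim$dataset, split,
                  tgem_config(n_layers = 1, n_heads = 2, epochs = 30,
                              learning_rate = 1e-3, seed = 1))
fit
#> tgem_fit: best epoch 5 (val acc 1.000) of 30
#> T-GEM model: 100 genes, 3 classes, 1 layer(s) x 2 head(s), activation 'none'
#>   parameters: 1105

ev <- tgem_evaluate(fit, sim$dataset)
round(c(acc = ev$acc, mcc = ev$mcc, auc = ev$auc), 4)
#> acc mcc auc
#>   1   1   1

# class-0 regulatory network from the class-0 test samples
idx <- split$test[sim$dataset$labels[split$test] == 0]
X0 <- log_minmax_normalize(sim$dataset$matrix[idx, , drop = FALSE],
                           stats = fit$stats)$matrix
net <- extract_network(fit$model, X0, 0, rule = list(method = "percentile", q = 0.99))
net
#> regulatory network (class 'class0', layer 1): 99 edges, 41 nodes, 30 informative Query genes

hubs <- find_hubs(net, 10)
head(hubs, 5)
#>    gene degree in_degree out_degree score_sum
#> 1 g0087     27         0         27 0.4173794
#> 2 g0039     21         0         21 0.2461277
#> 3 g0035     16         0         16 0.1763474
#> 4 g0082     11         0         11 0.1166823
#> 5 g0085      7         7          0 0.1104476

length(intersect(hubs$gene, sim$truth$markers$class0))
#> [1] 4
```

The trained model separates the three classes perfectly on the held-out
test split (accuracy, MCC and macro AUC all 1 at this effect size), and
the extracted class-0 network is driven by high out-degree *Key* genes:
4 of the 10 top hubs are planted class-0 markers (hypergeometric
p ≈ 0.008 against the 100-gene universe), illustrating how hub genes
surface candidate markers for the predicted class.

A command-line front end over the same functions lives at
`inst/cli/tgem.R` (subcommands `simulate`, `train`, `interpret`,
`network`); every run writes a manifest with seeds, argument values and
input digests for reproducibility.

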