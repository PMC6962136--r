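# mtgraph

Joint supervised **graph classification and node classification** on
collections of small labeled graphs (molecules, proteins), in R.

Most graph neural networks for molecular property prediction are trained on
the graph label alone, even though benchmark datasets also label every node
(atom types, secondary-structure elements). `mtgraph` implements
hard-parameter-sharing multi-task learning for this setting: a shared GNN
trunk with two softmax heads trained end-to-end on the joint loss

    L = L_G + alpha * L_v

where `L_G` and `L_v` are masked categorical cross-entropies for the graph
and node tasks and `alpha >= 0` weights the auxiliary node task
(`alpha = 0` is exactly the single-task graph classifier). Two trunks are
provided:

* **MT-GIN** — Graph Isomorphism Network layers
  `h_v <- MLP((1 + eps) * h_v + sum of neighbor h_u)` with per-layer sum
  readouts concatenated across layers `0..L` into the graph representation
  `r_G`, and per-layer node vectors concatenated into `r_v`.
* **MT-DIFFPOOL** — two GraphSAGE layers (mean aggregator, l2-normalized)
  shared between tasks, a differentiable pooling step
  (`S = row-softmax(GNN_pool)`, `X' = S'Z`, `A' = S'AS`, 90% node
  reduction) and three post-pool convolutions for the graph branch, with
  the node head tapping the pre-pool layer.

The package also provides a reader/writer for the TU Dortmund benchmark
format, a synthetic labeled-graph generator with a controllable coupling
between node labels and graph labels, the full training protocol (Adam,
step-decayed learning rate, 10-fold stratified cross-validation), and 2-D
embedding visualization via a built-in exact t-SNE. Training runs on a
small reverse-mode autodiff tape implemented in the package; its gradients
are verified against finite differences in the test suite.

## Worked example

```r
library(mtgraph)

# a coupled synthetic dataset: graph label = majority node class
d <- generateDataset(synthConfig(numGraphs = 100, seed = 1))
datasetStats(d)
#> synth: 100 graphs | avg nodes 15.51 | avg edges 35.84 | C_G=2 | C_v=3 | attr dim 3

# multi-task training, 3-fold CV for a quick look
cfg <- trainConfig(alpha = 1, epochs = 30, folds = 3, model = "gin", seed = 1)
rep <- crossValidate(d, cfg)
rep
#> CVReport (gin, alpha=1, 3 folds)
#>   graph accuracy (best epoch): 0.9899 +/- 0.0175
#>   node  accuracy (best epoch): 0.8297 +/- 0.0678
```

Both tasks are learned from one trunk: held-out graph accuracy ~0.99
(against a 0.5 majority baseline) and node accuracy ~0.83 after only 30
epochs (chance 1/3; the 100-epoch benchmark in `multitaskBenchmark()`
reaches ~0.97).
Setting `alpha = 0` trains the same trunk on the graph task alone; its
node head then receives zero gradient and stays at chance — the
single-task behavior the multi-task objective is designed to fix.

TU-format data from disk works the same way:

```r
d <- readTuDataset("path/to/MUTAG", "MUTAG")   # 188 graphs, 2 classes
reportStats(list(d))
```

A thin command-line front end is available after install at
`exec/mtgraph` (`mtgraph synth`, `mtgraph stats`, `mtgraph train`,
`mtgraph embed`).

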