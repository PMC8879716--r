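# smilegnn

Drug–drug interaction (DDI) prediction that fuses two complementary views of
each drug:

* a **structural feature** vector derived from the character composition of
  its SMILES string — a bag-of-characters count vector over a frequency-capped
  vocabulary (cap 251, including a pooled unknown slot), reduced by PCA to a
  configurable dimension (64 by default); and
* a **topological feature** vector learned from a multi-relational biomedical
  knowledge graph by a two-hop neighborhood-sampling graph neural encoder,
  with relation attention conditioned on the partner drug of the pair being
  scored, and interchangeable `sum` / `concat` / `neigh` aggregators.

The two per-drug vectors *A* (topological) and *B* (structural) are fused into
a comprehensive feature by either superposition

&nbsp;&nbsp;&nbsp;&nbsp;`f = tanh((A + B) W + b)`

or concatenation

&nbsp;&nbsp;&nbsp;&nbsp;`f = tanh([A ‖ B] W + b)`,

and a pair (i, j) is scored as the sigmoid of the inner product of its fused
vectors, `ŷᵢⱼ = σ(fᵢ · fⱼ)`, classified as interacting when the score exceeds
0.5. Training minimises the binary cross-entropy

&nbsp;&nbsp;&nbsp;&nbsp;`Loss = Σ_{(i,j) ∈ Y} −[yᵢⱼ log ŷᵢⱼ + (1 − yᵢⱼ) log(1 − ŷᵢⱼ)]`

over known interactions plus uniformly sampled negative pairs, by mini-batch
Adam with decoupled weight decay. Because drugs without a structure record get
an all-zero structural row, topology-only prediction still works for them —
useful in clinical graphs where only ~72% of drugs carry SMILES.

The package is aimed at computational pharmacologists and method developers
who want a self-contained, fully reproducible implementation: it includes
triple parsers (3-column TSV and an n-quads subset), graph density
diagnostics, stratified cross-validated evaluation (accuracy, AUC, F1),
novel-pair ranking, a grid-search helper, and a synthetic-data generator with
a plantable interaction signal so that every step is testable without any
external database.

## Worked example

```r
library(smilegnn)

# a synthetic knowledge graph + SMILES + labeled pairs with a planted signal
cfg <- simulation_config(seed = 7)   # 200 drugs, 400 entities, 72% SMILES
sim <- simulate_dataset(cfg)
sim$kg
#> <knowledge_graph> 600 entities (200 drugs), 6 relations, 2398 edges

ddi_subgraph_density(sim$pairs, sim$kg)
#> <density_report> N = 200, L = 1592, d(G) = 0.08

st <- structural_features(sim$smiles, drug_ids = sim$latent$drugs,
                          d_struct = 16)
st
#> <structural_features> 200 drugs x 16 dims (56 without SMILES)

tc <- train_config(batch_size = 512, learning_rate = 2e-2, weight_decay = 0.3,
                   embed_dim = 32, d_struct = 16, sample_size = 4,
                   epochs = 12, seed = 7)
ev <- evaluate_cv(sim$kg, st, sim$pairs, tc)
ev
#> <eval_metrics> 5 folds: mean ACC 0.7808, AUC 0.9207, F1 0.8114
```

The mean cross-validated AUC of ~0.92 says that on held-out pairs a random
interacting pair outscores a random non-interacting one about 92% of the
time; at the 0.5 threshold ~78% of pairs are classified correctly. Ranking
unseen candidate pairs by score surfaces likely novel interactions:

```r
model <- train(sim$kg, st, sim$pairs, tc)
cand <- subset(expand.grid(drug1 = sim$latent$drugs, drug2 = sim$latent$drugs,
                           stringsAsFactors = FALSE), drug1 < drug2)
rank_novel_pairs(model, cand, subset(sim$pairs, label == 1),
                 threshold = 0.9, top_k = 3)
#>     drug1   drug2     score predicted_label
#> 1 DB00129 DB00135 0.9999999               1
#> 2 DB00079 DB00124 0.9999999               1
#> 3 DB00096 DB00129 0.9999999               1
```

Two density profiles reported for real clinical knowledge graphs reproduce
exactly from their printed node/edge counts:

```r
graph_density(11174, 56983)   # sparse-profile DDI subgraph
#> <density_report> N = 11174, L = 56983, d(G) = 0.0009128
graph_density(1495, 36768)    # dense-profile DDI subgraph
#> <density_report> N = 1495, L = 36768, d(G) = 0.03292
```

A command-line front end (`inst/cli/smilegnn.R`) exposes `density`,
`simulate`, `train`, `evaluate`, `predict` and `rank` subcommands;
`inst/configs/` ships the two published hyperparameter presets.

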