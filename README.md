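# annlens

Network-science, information-theoretic and geometric analysis of a learning
feed-forward classifier.

`annlens` treats a small artificial neural network as a fully measurable
model organism for a question systems neuroscience keeps asking of brains:
**how do edges, modules, information content and population-activity
geometry reorganise as a function of learning?** A four-layer classifier
(input → 100 → 100 → output, sigmoid hidden units, softmax readout, zero
biases, plain SGD) is trained while its weights and test-set activities are
snapshotted on a logarithmically thinned epoch schedule. Each snapshot is
then analysed with the tools a network neuroscientist would use on
connectome or fMRI data:

* **Signed weighted modularity** — the two-term quality function

  `Q = (1/v+) Σ (w+ − γ e+) δ(Mi,Mj) − (1/(v+ + v−)) Σ (w− − γ e−) δ(Mi,Mj)`

  maximised by a Louvain algorithm with flat fine-tuning and multi-restart
  search, plus consensus clustering over runs and a resolution (γ) stability
  sweep.
* **Cartographic profiling** — per-node participation coefficient
  `PC = 1 − Σ_s (κ_is/κ_i)²` (on positive weights) and module-degree z-score
  `MZ = (κ_i − mean κ_module)/sd κ_module`.
* **Information maps** — plug-in mutual information between class labels and
  (i) each pixel, binarized at its MI-maximising threshold (`I_P`), (ii) the
  pixel-on pointwise average (`I_D`), and (iii) each hidden node binarized at
  0.5 (`I_H`).
* **Activity geometry** — PCA of node activities (per epoch and concatenated
  across epochs), top-10 explained-variance trajectories, and category
  *untangling* measured as between- vs within-class distances in the top-3
  space.
* **Inference** — permutation tests for correlations, Steiger's test for
  dependent correlations, and changepoint segmentation of the modularity
  trajectory into early / middle / late training periods.

Everything runs against a synthetic **glyph** dataset whose class-informative
pixels are known by construction (so every analysis is checkable as
parameter recovery), and against any MNIST-format IDX image/label files via
`read_idx()` / `write_idx()`.

## Worked example

Generate a glyph task, train the classifier for 30 epochs, and ask whether
the edges that change most during early training point at the most
class-informative pixels:

```r
library(annlens)

spec      <- glyph_spec(seed = 7)                    # 14x14, 5 classes
train_set <- make_glyph_dataset(spec, 1000, "train")
test_set  <- make_glyph_dataset(spec, 300, "test")

net   <- init_network(c(196, 100, 100, 5), seed = 1)
trace <- train(net, train_set, test_set, lr = 0.5, max_epoch = 30, seed = 2)
trace
#> <training_trace: 30 snapshots over 30 epochs, final accuracy 0.960>

part <- louvain(symmetrize(assemble_adjacency(trace$weights[[30]])), seed = 3)
part
#> <partition: 7 modules over 401 nodes, Q = 0.1200 (gamma = 1)>

info <- pixel_info_map(train_set)
info
#> <pixel_info_map: 14x14, I_P in [0.004, 0.236] bits>
gt <- ground_truth_pixel_info(spec)          # analytic map from the generator
cor(as.vector(info$i_p), as.vector(gt))
#> [1] 0.9860318

ecm <- edge_change_map(trace, range(trace$schedule))
perm_corr(as.vector(ecm), as.vector(gt), n_perm = 10000, seed = 4)
#> <perm_corr: r = 0.9009, p_perm = 9.999e-05 (two.sided, n = 196, 10000 perms)>
```

Reading the output: the trained network classifies 96% of held-out glyphs;
its final graph splits into 7 signed modules at Q = 0.12; the estimated
per-pixel information map recovers the generator's analytic map at r = 0.99;
and the input edges that moved most during training correlate at r = 0.90
(permutation p < 1e-4) with the analytically most informative pixels — the
early "edge realignment toward informative inputs" effect.

The full pipeline — training, per-epoch modularity, consensus, cartography,
information maps, PCA/untangling, segmentation and period statistics, with
all tables exported as CSV/JSON — is one call:

```r
res <- run_all(run_config(seed = 1), "my_run")   # ~5-7 minutes, one CPU
report("my_run")                                  # summary.md + figures
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --config run.yaml --out my_run`).

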