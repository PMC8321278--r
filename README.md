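# bunet — Bayesian U-Net with active learning for semantic segmentation

Pixel-wise labels are the expensive ingredient of biomedical image
segmentation: a single ground-truth mask can take an expert many minutes
to draw. `bunet` trains a U-Net segmenter from a *minimal* number of
labelled images by letting the model's own uncertainty pick which images
from an unlabelled pool are worth annotating. It is aimed at method-level
experiments on a desktop CPU: everything from the network forward/backward
passes to the active-learning loop is implemented in the package (R with
RcppArmadillo kernels), and a synthetic multi-class shape generator makes
the whole pipeline runnable and testable without any external data.

## The method

**Model.** A U-shaped encoder–decoder: two-convolution blocks (3×3, same
padding, batch normalization + rectifier) separated by 2×2 max pooling,
channel width doubling per level; transposed-convolution upsampling with
skip connections; per-pixel softmax over *c* classes; categorical
cross-entropy trained with Adam (lr 0.001).

**Uncertainty.** Monte-Carlo dropout: dropout sites stay active at
prediction time and the posterior predictive is approximated by averaging
*T* stochastic forward passes,

```
p(Y* | X*, D) ≈ (1/T) Σₜ p(Y* | X*, Wₜ),   Wₜ = W ⊗ αₜ,  αₜ ~ Bernoulli(p).
```

The default placement is dropout immediately after each max pool
(`maxpool_dropout`); `plain`, `standard_dropout` and `both` are available
for benchmarking (`runVariantBenchmark()`).

**Acquisition.** The informativeness *I(X)* of a pool image is a sum of
per-pixel information quantities (nats):

| function        | per-pixel quantity                                   |
|-----------------|------------------------------------------------------|
| `entropy`       | H of the MC mean prediction                          |
| `bald`          | H(MC mean) − mean per-pass H (mutual information)    |
| `committee_kl`  | KL(standard prediction ‖ MC mean)                    |
| `committee_jsd` | Jensen–Shannon divergence of the same pair           |
| `random`        | control baseline                                     |

**Loop.** Label a random initial set (default 2), train; then repeatedly
score the pool, query a simulated oracle for the top-*k* images (default
2), and warm-start retrain with early stopping on validation dice —
macro-averaged one-vs-rest Sørensen–Dice over the classes present in the
ground truth.

## Worked example

Five-class 64×64 synthetic shapes; 12-image pool, 4 validation images;
three acquisition rounds of the committee-JSD strategy:

```r
library(bunet)
ds  <- generateDataset(syntheticSpec(nImages = 16L, seed = 42L))
ids <- datasetIds(ds)
pool <- subsetDataset(ds, ids[1:12])
val  <- subsetDataset(ds, ids[13:16])

cfg <- modelConfig(depth = 2L, baseFilters = 8L, nClasses = 5L,
                   variant = "maxpool_dropout")
oracle <- makeOracle(pool)
state <- runActiveLearning(cfg, pool, oracle, val,
                           acquisition = "committee_jsd", k = 2L,
                           iterations = 3L, initialSize = 2L, T = 10L,
                           seed = 1L, maxEpochs = 12L, patience = 3L)
state
#> ALState: iteration 3, 8 labelled, 4 in pool, 8 labels queried
#>   final MC validation dice: 0.6325
alHistory(state)
#>   iteration n_labeled   acquisition val_dice_mean val_dice_sd epochs_run
#> 1         1         4 committee_jsd     0.3763210  0.09764963         12
#> 2         2         6 committee_jsd     0.4791254  0.09738247         12
#> 3         3         8 committee_jsd     0.6324627  0.09863533         12
```

Reading the history: with 4 labelled images the Monte-Carlo validation
dice (argmax of the averaged prediction vs ground truth, mean ± sd over
the validation images) is 0.38; after two more rounds — 8 of 12 pool
images labelled, each queried from the oracle only when the model asked
for it — it reaches 0.63. `oracle` confirms the label budget: 8 labels
released, never more than requested.

The same pipeline is scriptable from a shell via the installed CLI
(`system.file("scripts", "bunet", package = "bunet")`):

```sh
bunet simulate --n 40 --classes 5 --seed 7 --out data/
bunet active-learn --data data/ --acquisition committee_jsd \
      --k 2 --iterations 15 --initial 2 --seed 7 --out runs/jsd/
bunet score --data data/ --checkpoint runs/jsd/checkpoint.rds \
      --acquisition entropy --out runs/jsd/scores/
```

Subcommands: `simulate`, `train`, `active-learn`, `benchmark-variants`,
`score`, `evaluate`; all outputs (history CSV, resolved YAML config,
checkpoint) land under `--out` and are reproducible byte-for-byte under a
fixed `--seed`.

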