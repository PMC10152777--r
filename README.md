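# scea

Cell-type clustering for single-cell RNA-seq count matrices.

Single-cell expression data is sparse (technical dropout), over-dispersed
and very high-dimensional, which makes cell-type discovery by clustering
fragile. `scea` addresses this with a pipeline built around *non-linear*
dimension reduction over a *denoised cell graph*:

1. **Quality control** — genes must be expressed (count > 0) in ≥ 3 cells;
   cells with outlying library size or detected-gene count are removed by
   Tukey quartile fences; genes whose total expression exceeds the 75th
   percentile (housekeeping-like) are dropped; counts are library-
   normalized and log-transformed.
2. **Cell graph** — Pearson correlation between cells, denoised by Network
   Enhancement (a diffusion on the doubly stochastic scaling of the
   locally restricted similarity matrix, which widens the spectral
   eigengap: `W ← α·T²·W + (1−α)·T`), then KNN-sparsified.
3. **Two-stage reduction** — a three-layer tanh MLP encoder
   (4096 → 2048 → 1024), pretrained as a mirrored autoencoder under mean
   absolute error (MAE), optionally standardized; then a multi-head graph
   attention autoencoder (two attention layers each way, 8 heads,
   `e_ij = LeakyReLU(a_src·Wh_i + a_dst·Wh_j)` softmaxed over graph
   neighborhoods) trained with MAE over the cell graph.
4. **Self-optimizing clustering** — k-means centers in the latent space,
   Student-t soft assignments `q_ij ∝ (1+‖z_i−μ_j‖²)⁻¹`, sharpened target
   `p_ij ∝ q_ij²/f_j`, and joint refinement of network and centers under
   `MAE + λ·KL(P‖Q)`.
5. **Evaluation** — adjusted Rand index and normalized mutual information
   against reference labels.

All neural components, including backpropagation through the masked
multi-head attention, are implemented natively in R and verified against
numerical gradients in the test suite. A negative-binomial synthetic-data
generator with dropout makes the whole pipeline testable offline.

## Worked example

Simulate a 4-cluster dataset with 30% dropout, cluster it, and score the
result (reduced layer widths keep the example fast):

```r
library(scea)

sim <- generate_counts(synthetic_spec(n_cells = 300, n_genes = 500,
                                      n_clusters = 4, de_fraction = 0.3,
                                      log_fold_change = 2.5,
                                      dropout_rate = 0.3, seed = 7))

cfg <- scea_config(K = 4, seed = 1,
                   encoder = list(layer_dims = c(256, 128, 64), epochs = 15),
                   gat = list(hidden_dim = 64, latent_dim = 16,
                              n_heads = 8, epochs = 40),
                   cluster = list(max_epochs = 40, update_interval = 10))

fit <- run_scea(sim$counts, cfg, labels_true = sim$labels)
fit$manifest$dimensions
#> $input
#> [1] 300 500
#> $preprocessed
#> [1] 293 375
#> $embedding
#> [1] 293  64
#> $latent
#> [1] 293  16

sprintf("ARI: %.3f  NMI: %.3f",
        fit$manifest$metrics$ari, fit$manifest$metrics$nmi)
#> [1] "ARI: 1.000  NMI: 1.000"

table(fit$labels)
#>  1  2  3  4
#> 74 74 71 74
```

QC removed 7 outlier cells and 125 high-aggregate genes (300 × 500 →
293 × 375); the encoder compressed the QC-passed matrix to 64 dimensions
and the attention autoencoder to 16; refinement recovered the planted
partition exactly (ARI = NMI = 1). The manifest also carries the filter
report, per-stage loss traces and timings, and is written as JSON when an
output directory is given.

Real data enters the same way: `run_scea("counts.csv", ...)` for a dense
matrix with cell-id rows and gene-id header, or
`run_scea("10x_dir/", ...)` for a Matrix Market triplet directory
(`matrix.mtx` + `barcodes.tsv` + `features.tsv`). A thin command-line
wrapper with `run` / `simulate` / `evaluate` / `graph` subcommands is
installed at `inst/cli/scea.R`.

## Scope

`scea` ends at cluster labels and agreement metrics. It does not select
the number of clusters, correct batch effects, impute dropouts, or draw
embeddings; dense per-head attention targets datasets up to a few
thousand cells. See the methods vignette (`vignettes/scea-methods.Rmd`)
for the models, defaults, and design rationale.
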