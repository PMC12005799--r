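# spotweave

Joint analysis of multi-slice spatial transcriptomics (SRT) with an annotated
scRNA-seq reference: one shared embedding space for all slices, per-spot
cell-type proportions, batch-effect-corrected alignment, spatial-domain
calling, and denoised expression.

## Who this is for

Sequencing-based SRT (10x Visium-class) measures expression at spots that mix
several cells, and real studies produce multiple slices whose expression is
shifted by batch effects. spotweave is for analysts who want, from raw spot
counts + coordinates + a labeled single-cell reference:

* **aligned spot embeddings** across slices,
* **cell-type proportions** per spot (deconvolution),
* **spatial domains** comparable across slices (unsupervised, or transferred
  from one annotated slice),
* **denoised expression** per slice.

## The model in brief

Each slice gets a spatial graph (Delaunay 1-skeleton filtered at radius r =
mean k-NN distance, k = 6) with normalized adjacency
Â = D^(−1/2)(A + I)D^(−1/2). A two-layer GCN encoder shared across slices is
trained full-batch with

L = L_recon + α·L_contrastive + β·L_spatial,

where L_contrastive is a corrupted-graph objective — a bilinear discriminator
σ(zᵀΘg) separates each spot's embedding paired with its local context g
(sigmoid of neighbors' mean embedding) from the corrupted graph's counterpart
— and L_spatial = Σᵢⱼ d^c_ij(1 − d^Z_ij)/N² couples embedding distances to
coordinate distances. A GCN decoder reconstructs expression (the denoised
output). The frozen encoder embeds the reference over its SNN graph; a softmax
MLP classifier trained with

L_sc + λ·Σ_t ‖X_t − P_t B‖²_F / N_t + γ·C_spatial

yields the row-stochastic proportion matrix P_t (B = per-type mean expression
signatures). Mutual-nearest-neighbor anchors in proportion space and a
multi-kernel Gaussian MMD loss on anchor embeddings remove batch effects while
the encoder is fine-tuned; a full-covariance Gaussian mixture on the pooled
proportions calls spatial domains. With one annotated slice, a 512-512 MLP
transfers its domain labels to the rest. Details and all numerical choices:
`vignette("spotweave-methods")`.

## Worked example

The built-in generator reproduces the package's standard benchmark: three
15×15-spot slices with three vertical-band domains, K = 5 cell types, S1 and
S2 sharing domain compositions, S3 diverging in one domain, and a mild
gene-wise batch effect.

```r
library(spotweave)

sim <- simulate_benchmark(seed = 1)
bundle <- run_pipeline(sim$slices, sim$ref,
                       config = list(seed = 1, deconv = list(n_domains = 4)))
ev <- evaluate_bundle(bundle, sim$truth_domains, sim$truth_proportions)

round(ev$ari_per_slice, 3)
#    S1    S2    S3
# 0.987 0.974 0.947
sapply(ev$proportions, function(m) round(m$median_pcc, 3))
#    S1    S2    S3
# 0.933 0.937 0.932
```

Per slice this prints the adjusted Rand index between the called and true
domains (1.0 = perfect recovery of the three bands) and the median across
spots of the Pearson correlation between each spot's estimated and true
5-type proportion vector. For calibration, refitting the true signature
matrix to each spot by non-negative least squares — the information ceiling
for signature-based deconvolution on this data — reaches median PCC ≈ 0.95,
so the pipeline recovers nearly all of the per-spot compositional signal;
domain-level composition errors (median per-spot MSE ≈ 0.01) are dominated
by the 10-cell sampling noise in the ground truth itself.

A thin command-line front-end is installed with the package
(`system.file("cli", "spotweave", package = "spotweave")`) with subcommands
`simulate`, `run` and `evaluate` over the same functions.

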