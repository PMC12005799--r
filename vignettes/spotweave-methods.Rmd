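---
title: "spotweave: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotweave: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sequencing-based spatial transcriptomics (SRT) measures expression at capture
spots that each pool mRNA from one to dozens of cells, and a study typically
produces several slices that differ by section, donor or platform. Three
questions recur: which *spatial domains* (coherent tissue regions) does each
slice contain; what *cell-type composition* does each spot carry; and how can
slices be analyzed *jointly* when batch effects shift their expression?
spotweave answers all three at once by learning one embedding space for all
slices and an annotated scRNA-seq reference.

## Model overview

For slice $t$ with spot expression $X_t \in \mathbb{R}^{N_t \times D}$
(library-size normalized, $\log(1 + 10^4\,v/T)$) and coordinates $C_t$:

1. **Spatial graph.** Spots are connected by the 1-skeleton of their Delaunay
   triangulation, filtered to edges no longer than $r$, the mean over spots of
   the mean distance to their $k = 6$ nearest neighbors (an alpha-complex at
   scale $r$). The adjacency is normalized as
   $\hat A = D^{-1/2}(A + I)D^{-1/2}$.
2. **Encoder.** A two-layer GCN with PReLU activations, shared across all
   slices, maps $X_t$ to embeddings $Z_t \in \mathbb{R}^{N_t \times 50}$.
3. **Contrastive objective.** A corrupted view $\tilde X_t$ permutes spot
   profiles over the fixed graph. Each spot's local context $g_i$ is the
   sigmoid of its neighbors' mean embedding; a bilinear discriminator
   $D(z, g) = \sigma(z^\top \Theta g)$ should score $(z_i, g_i)$ high and
   $(\tilde z_i, g_i)$ low:
   $$\mathcal{L}_{\text{local}} = -\tfrac{1}{2N_t}\sum_i
     \big[\log D(z_i, g_i) + \log(1 - D(\tilde z_i, g_i))\big].$$
4. **Spatial consistency.** With $d^c$ and $d^Z$ the min-max normalized
   pairwise coordinate and embedding distances,
   $\mathcal{L}_R = \sum_{ij} d^c_{ij}(1 - d^Z_{ij}) / N_t^2$.
5. **Decoder / denoising.** Two further GCN layers map $Z_t$ back to the gene
   space; $\mathcal{L}_{\text{recon}} = \sum_i \lVert x_i - h_i \rVert^2$
   (optimized as the per-spot mean). The reconstruction $H_t$ is the denoised
   expression.

The encoder minimizes
$\mathcal{L}_{\text{recon}} + \alpha \mathcal{L}_{\text{local}} + \beta \mathcal{L}_R$
summed over slices (defaults $\alpha = 1$, $\beta = 0.1$), full batch, Adam
(learning rate $10^{-3}$, 400 epochs), with the corrupted view re-drawn every
epoch. All gradients are analytic and are verified against finite differences
in the test suite.

## Deconvolution

The trained encoder is applied, frozen, to the reference over its
shared-nearest-neighbor graph (PCA to 40 PCs, $k = 20$, weights = shared
neighbor fraction, max-symmetrized). A softmax MLP classifier
($50 \to 128 \to K$) is then trained with

$$\mathcal{L} = \mathcal{L}_{sc}
  + \lambda \sum_t \tfrac{1}{N_t}\lVert X_t - P_t B\rVert_F^2
  + \gamma\, C_{\text{spatial}},$$

where $\mathcal{L}_{sc}$ is cross-entropy on the labeled cells, $B$ is the
$K \times D$ matrix of per-type mean normalized expression, $P_t$ the
classifier's row-stochastic output on spot embeddings, and $C_{\text{spatial}}$
couples proportion distances to embedding distances
($\sum_{ij} d^P_{ij}(1 - d^Z_{ij})/N_t^2$, plus the same form restricted to
anchor pairs once anchors exist).

Two scale choices matter and were set after measuring their effect:

* The reconstruction term is normalized **per spot only** (not per gene).
  Normalizing by $N_t D$ makes the term two orders of magnitude smaller than
  the cross-entropy, the optimizer leaves it flat, and the proportion matrix
  collapses; the printed objective this package implements uses the raw
  Frobenius norm, whose dominance is exactly what makes $P$ track per-spot
  composition. Per-spot normalization keeps that dominance while being
  independent of slice size.
* The consistency terms use min-max normalized distances; their normalization
  constants are functions of the embedding, and their (almost-everywhere)
  gradients through the argmin/argmax pairs are included — the detached
  approximation measurably biases the gradient.

Spatial domains come from a full-covariance Gaussian mixture fitted to the
proportions pooled across slices (EM, k-means initialization with 10
restarts, $10^{-6}$ covariance ridge — the ridge matters because
row-stochastic $P$ is rank-deficient), each spot labeled by maximum
responsibility.

## Alignment

Anchors between slice pairs are mutual nearest neighbors (default $k = 5$)
in proportion space (embedding space is available via
`align$space = "embedding"`). Between anchor embedding sets the package
minimizes a multi-kernel Gaussian MMD$^2$ (biased V-statistic; bandwidths =
median heuristic $\times\, \{0.5, 1, 2\}$), **summed over anchors** so that
$\delta = 1$ puts the term on the same per-observation scale as the per-spot
reconstruction loss. Each alignment epoch fine-tunes the encoder on its full
objective plus $\delta \cdot n_{\text{anchors}} \cdot \text{MMD}^2$, with
anchors refreshed every 50 epochs; afterwards the cell-type classifier is
re-fitted **warm-started** from its pre-alignment weights with the
anchor-restricted consistency term active, and $P_t$ is recomputed from the
aligned embeddings. (A cold-restarted refit measurably degraded both the
proportions and the domain calls; alternating encoder/classifier updates was
chosen over joint backpropagation through both networks for robustness and
simplicity, and the `freeze_encoder` switch turns the encoder updates off.)

The alignment phase uses a deliberately gentle learning rate ($10^{-4}$,
vs $10^{-3}$ for initial training): restarting Adam at the full rate
perturbs slice pairs that are already aligned and measurably degrades
cross-slice label transfer on batch-effect-free pairs, while at $10^{-4}$
the anchor MMD still drops severalfold within the default 100 epochs when
a real batch effect exists (the test suite checks both properties). The
post-alignment classifier refit keeps the full rate (`refit_lr`).

## Semi-supervised domain transfer

When one slice carries domain annotations, a three-layer perceptron
($50 \to 512 \to 512 \to M$, ReLU) is trained with mean cross-entropy on the
labeled spots' aligned embeddings
($\mathcal{L}_{\text{semi}} = -\tfrac1m \sum_k y_k \log \hat y_k$) and
predicts domains for every other slice by argmax.

## The synthetic benchmark

`simulate_benchmark()` generates the package's standard study conditions:
a reference of $K = 5$ types (500 cells each, 2000 genes, 40 marker genes
per type at 5-fold change over a gamma-distributed baseline,
negative-binomial counts with dispersion 0.5), and three $15 \times 15$
slices of three vertical-band domains. Spots draw 10 reference cells with
type probabilities set by their domain's mixing row; slices S1 and S2 share
mixing (dominant type 0.6, rest 0.1), S3 diverges in exactly one domain row
(0.05/0.05/0.05/0.60/0.25); slices beyond the first receive a gene-wise
log-normal batch factor (sdlog 0.2). Ground-truth proportions are the
*realized* draws, so deconvolution is scored against what is actually in
each spot. Domain-wise mixing values, cells per spot and dispersion were
chosen once as typical of sequencing-based SRT at 50-μm-class resolution;
the generator writes the exact input formats the loaders read.

What the generator does *not* emulate: platform-specific spot geometry,
segmentation error, spatially smooth gradients within domains, zero-inflation
beyond NB noise, or reference/SRT technology gaps other than a multiplicative
gene-wise factor. Passing the benchmark therefore demonstrates correctness of
the machinery and sensible behavior under idealized mixing, not performance
on any particular tissue.

## Numerical choices and degenerate inputs

* PReLU slopes are learnable, initialized at 0.25, one per layer.
* Discriminator outputs are clamped to $[10^{-7}, 1 - 10^{-7}]$ inside the
  loss; softmax rows are max-shifted.
* kNN and MNN ties break by index; the corrupted permutation, Adam
  initialization and k-means restarts are all driven by the run seed, so a
  fixed seed reproduces runs bit-for-bit.
* Constant embeddings make $d^Z$ degenerate; the regularizer then treats
  $d^Z \equiv 0$. Spots with zero total count stay all-zero after
  normalization (with a warning). Isolated graph nodes use themselves as
  their local context. Collinear coordinates (no triangulation) fall back to
  a kNN graph.
* The contrastive loss pairs $z_i$ with the *local* context $g_i$; the global
  summary $s$ (column mean of $Z$) is computed and exposed, and a future
  `contrastive.context` switch could substitute it — local context was chosen
  because per-spot discrimination against a graph-wide summary is
  uninformative when the corrupted view shares that summary.

## Default problem sizes

The package's own test suite and the acceptance script run the three-slice
benchmark at its native size (675 spots, ~1500 retained genes, 2500 reference
cells) with the default training lengths (encoder 400 epochs, classifier 300,
alignment 100 + 150-epoch warm-started refit); one full pipeline run takes a
few minutes on a laptop-class CPU core.

## Known limitations

* Deconvolution operates in log-normalized space, where mixing is only
  approximately linear; systematic Jensen-gap bias is absorbed by the
  classifier but not modeled.
* Alignment matches embedding distributions of anchors; it does not register
  coordinates, and a domain private to one slice can only be protected by the
  mutuality of the anchor filter.
* The GMM assumes roughly Gaussian proportion clusters; heavily overlapping
  compositions merge.
* Proportions are relative; absolute per-spot cell counts are out of scope.
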