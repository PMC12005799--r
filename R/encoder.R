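# Graph-contrastive autoencoder. A two-layer GCN encoder shared across all
# slices maps normalized expression to d-dimensional spot embeddings; a
# bilinear discriminator contrasts each spot's embedding with its local
# context against the corrupted-graph counterpart; a spatial-consistency
# regularizer couples embedding distances to coordinate distances; a
# two-layer GCN decoder reconstructs (denoises) expression. Training is
# full-batch gradient descent with Adam; all gradients are analytic.

#' Initialize encoder/decoder/discriminator parameters
#'
#' Glorot-uniform weights, zero biases, PReLU slopes at 0.25 (one learnable
#' slope per layer).
#'
#' @param n_genes input feature dimension.
#' @param hidden hidden layer width (default 256).
#' @param latent_dim embedding dimension d (default 50).
#' @param seed integer seed.
#' @return Named list of parameter arrays (class `encoder_params`).
#' @export
init_encoder_params <- function(n_genes, hidden = 256L, latent_dim = 50L,
                                seed = 0L) {
  p <- with_seed(seed, list(
    W1 = glorot(n_genes, hidden), b1 = numeric(hidden), a1 = 0.25,
    W2 = glorot(hidden, latent_dim), b2 = numeric(latent_dim), a2 = 0.25,
    Theta = glorot(latent_dim, latent_dim),
    V1 = glorot(latent_dim, hidden), c1 = numeric(hidden), a3 = 0.25,
    V2 = glorot(hidden, n_genes), c2 = numeric(n_genes), a4 = 0.25
  ))
  structure(p, class = "encoder_params")
}

#' One graph-convolution layer
#'
#' Computes `PReLU(A_hat %*% X %*% W + b)`; features are aggregated over each
#' node's normalized neighborhood before the linear map and activation.
#'
#' @param X node x p input matrix.
#' @param A_hat normalized adjacency from [normalize_adjacency()].
#' @param W p x q weight matrix.
#' @param b length-q bias (default zeros).
#' @param slope PReLU negative slope (default 0.25).
#' @return node x q output matrix.
#' @export
gcn_layer <- function(X, A_hat, W, b = NULL, slope = 0.25) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(W)) {
    stopf("feature dimension %d does not match weight rows %d", ncol(X), nrow(W))
  }
  if (nrow(X) != nrow(A_hat)) {
    stopf("node count %d does not match adjacency size %d", nrow(X), nrow(A_hat))
  }
  pre <- as.matrix(A_hat %*% (X %*% W))
  if (!is.null(b)) pre <- sweep(pre, 2L, b, "+")
  prelu(pre, slope)
}

# Forward pass through the 2-layer encoder, keeping caches for backprop.
enc_forward <- function(X, A_hat, params) {
  pre1 <- as.matrix(A_hat %*% (X %*% params$W1))
  pre1 <- sweep(pre1, 2L, params$b1, "+")
  H1 <- prelu(pre1, params$a1)
  pre2 <- as.matrix(A_hat %*% (H1 %*% params$W2))
  pre2 <- sweep(pre2, 2L, params$b2, "+")
  Z <- prelu(pre2, params$a2)
  list(X = X, pre1 = pre1, H1 = H1, pre2 = pre2, Z = Z)
}

# Backward pass matching enc_forward; returns parameter grads (suffixed by
# `tag` so clean/corrupted passes can be accumulated) given dLoss/dZ.
enc_backward <- function(gZ, fwd, A_hat, params) {
  p2 <- prelu_backward(gZ, fwd$pre2, params$a2)
  Ag2 <- as.matrix(A_hat %*% p2$grad_pre)          # A_hat symmetric
  gW2 <- crossprod(fwd$H1, Ag2)
  gb2 <- colSums(p2$grad_pre)
  gH1 <- Ag2 %*% t(params$W2)
  p1 <- prelu_backward(gH1, fwd$pre1, params$a1)
  Ag1 <- as.matrix(A_hat %*% p1$grad_pre)
  gW1 <- crossprod(fwd$X, Ag1)
  gb1 <- colSums(p1$grad_pre)
  list(W1 = gW1, b1 = gb1, a1 = p1$grad_slope,
       W2 = gW2, b2 = gb2, a2 = p2$grad_slope)
}

# Decoder forward/backward (2 GCN layers, d -> hidden -> genes).
dec_forward <- function(Z, A_hat, params) {
  pre1 <- as.matrix(A_hat %*% (Z %*% params$V1))
  pre1 <- sweep(pre1, 2L, params$c1, "+")
  D1 <- prelu(pre1, params$a3)
  pre2 <- as.matrix(A_hat %*% (D1 %*% params$V2))
  pre2 <- sweep(pre2, 2L, params$c2, "+")
  H <- prelu(pre2, params$a4)
  list(Z = Z, pre1 = pre1, D1 = D1, pre2 = pre2, H = H)
}

dec_backward <- function(gH, fwd, A_hat, params) {
  p2 <- prelu_backward(gH, fwd$pre2, params$a4)
  Ag2 <- as.matrix(A_hat %*% p2$grad_pre)
  gV2 <- crossprod(fwd$D1, Ag2)
  gc2 <- colSums(p2$grad_pre)
  gD1 <- Ag2 %*% t(params$V2)
  p1 <- prelu_backward(gD1, fwd$pre1, params$a3)
  Ag1 <- as.matrix(A_hat %*% p1$grad_pre)
  gV1 <- crossprod(fwd$Z, Ag1)
  gc1 <- colSums(p1$grad_pre)
  gZ <- Ag1 %*% t(params$V1)
  list(V1 = gV1, c1 = gc1, a3 = p1$grad_slope,
       V2 = gV2, c2 = gc2, a4 = p2$grad_slope, gZ = gZ)
}

#' Encode one graph into spot embeddings
#'
#' Applies the two-layer GCN encoder and derives the global summary vector
#' `s` (column mean of Z) and each node's local context `g_i`, the sigmoid of
#' the mean embedding of its graph neighbors (an isolated node uses itself).
#'
#' @param X node x gene normalized matrix.
#' @param graph a `spatial_graph`.
#' @param params [init_encoder_params()] output (typically trained).
#' @return List of class `spot_embedding` with `Z`, `s`, `g`.
#' @export
encode_graph <- function(X, graph, params) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(params$W1)) {
    stopf("input has %d genes but encoder expects %d", ncol(X), nrow(params$W1))
  }
  fwd <- enc_forward(X, graph$A_hat, params)
  M <- neighbor_mean_operator(graph$A)
  g <- sigmoid(as.matrix(M %*% fwd$Z))
  structure(list(Z = fwd$Z, s = colMeans(fwd$Z), g = g),
            class = "spot_embedding")
}

#' Bilinear discriminator score
#'
#' `sigmoid(z' Theta g)` — the probability that embedding `z` and context `g`
#' come from the observed (uncorrupted) graph. Row-wise when matrices are
#' given.
#'
#' @param z d-vector or n x d matrix of embeddings.
#' @param g d-vector or n x d matrix of contexts (paired by row).
#' @param Theta d x d bilinear weight.
#' @return Probability (vector) in (0, 1).
#' @export
discriminate <- function(z, g, Theta) {
  z <- rbind(z); g <- rbind(g)
  unname(sigmoid(rowSums((z %*% Theta) * g)))
}

#' Local contrastive loss for one slice
#'
#' Minimized negative of the mutual-information objective:
#' `-(1/2N) sum_i [log D(z_i, g_i) + log(1 - D(z~_i, g_i))]` with
#' discriminator outputs clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param Z,Z_tilde n x d embeddings of the observed and corrupted graphs.
#' @param g n x d local contexts.
#' @param Theta discriminator weight.
#' @return Non-negative scalar loss.
#' @export
contrastive_loss <- function(Z, Z_tilde, g, Theta) {
  eps <- 1e-7
  pos <- pmin(pmax(discriminate(Z, g, Theta), eps), 1 - eps)
  neg <- pmin(pmax(discriminate(Z_tilde, g, Theta), eps), 1 - eps)
  -(sum(log(pos)) + sum(log(1 - neg))) / (2 * nrow(Z))
}

# Contrastive loss + gradients wrt Z, Z_tilde, G (through the sigmoid-of-
# neighbor-mean), and Theta for one slice. M is the neighbor-mean operator.
contrastive_grads <- function(Z, Zt, G, M, Theta) {
  n <- nrow(Z)
  sp <- rowSums((Z %*% Theta) * G)
  sn <- rowSums((Zt %*% Theta) * G)
  p <- sigmoid(sp)
  q <- sigmoid(sn)
  eps <- 1e-7
  loss <- -(sum(log(pmax(p, eps))) + sum(log(pmax(1 - q, eps)))) / (2 * n)
  dsp <- -(1 - p) / (2 * n)      # dL/d(score_pos)
  dsn <- q / (2 * n)             # dL/d(score_neg)
  gZ <- (dsp * G) %*% t(Theta)
  gZt <- (dsn * G) %*% t(Theta)
  gG <- dsp * (Z %*% Theta) + dsn * (Zt %*% Theta)
  gTheta <- crossprod(Z, dsp * G) + crossprod(Zt, dsn * G)
  # G = sigmoid(M Z): route the context gradient back into Z
  gMZ <- gG * G * (1 - G)
  gZ <- gZ + as.matrix(Matrix::t(M) %*% gMZ)
  list(loss = loss, gZ = gZ, gZt = gZt, gTheta = gTheta)
}

#' Spatial-consistency regularizer
#'
#' `sum_{i,j} d_c[i,j] * (1 - d_Z[i,j]) / N^2` where `d_c` are pairwise
#' coordinate distances and `d_Z` pairwise embedding distances, each min-max
#' normalized to `[0, 1]` over off-diagonal pairs. A constant embedding makes
#' `d_Z` degenerate; it is then treated as identically zero.
#'
#' @param Z n x d embedding matrix.
#' @param coords n x 2 coordinates.
#' @param d_c,d_Z optional pre-normalized pairwise distance matrices; when
#'   given they override the matrices derived from `coords`/`Z` (useful for
#'   composing the loss from externally normalized distances).
#' @return Scalar in `[0, 1]`.
#' @export
spatial_regularizer <- function(Z, coords, d_c = NULL, d_Z = NULL) {
  n <- if (!is.null(d_c)) nrow(d_c) else nrow(as.matrix(Z))
  if (n < 2L) return(0)
  if (is.null(d_c)) d_c <- minmax_offdiag(pairwise_dist(coords))$scaled
  if (is.null(d_Z)) d_Z <- minmax_offdiag(pairwise_dist(Z))$scaled
  sum(d_c * (1 - d_Z)) / (n * n)
}

# Spatial regularizer with gradient wrt Z. Pre-normalized coordinate
# distances d_c are passed in (constant across epochs); the embedding
# min-max constants are treated as fixed.
spatial_reg_grads <- function(Z, d_c) {
  n <- nrow(Z)
  if (n < 2L) return(list(loss = 0, gZ = Z * 0))
  E <- pairwise_dist(Z)
  off <- E[row(E) != col(E)]
  if (max(off) - min(off) <= 1e-12) {      # constant embedding: d_Z == 0
    return(list(loss = sum(d_c) / (n * n), gZ = Z * 0))
  }
  mm <- minmax_offdiag(E)
  loss <- sum(d_c * (1 - mm$scaled)) / (n * n)
  # dL/du_ij with u the min-max normalized distance; the normalization
  # constants lo (min) and hi (max) are themselves functions of E, so their
  # first-order effect is routed back to the argmin/argmax pairs.
  C <- -d_c / (n * n)
  W <- dmat_through_minmax(C, E, mm)
  S <- W / pmax(E, 1e-12)                  # chain through dE/dZ
  S[E < 1e-9] <- 0                         # coincident embeddings: zero limit
  diag(S) <- 0
  S2 <- 2 * S
  gZ <- rowSums(S2) * Z - S2 %*% Z
  list(loss = loss, gZ = gZ)
}

#' Decode embeddings back to expression space
#'
#' Two GCN layers map the d-dimensional embedding through the hidden layer
#' back to the gene dimension; the output `H` is the denoised expression.
#'
#' @param Z n x d embedding.
#' @param graph a `spatial_graph` (its `A_hat` is used).
#' @param params encoder parameter list (decoder weights `V1`, `V2`).
#' @return n x genes denoised matrix.
#' @export
decode_graph <- function(Z, graph, params) {
  if (ncol(Z) != nrow(params$V1)) {
    stopf("embedding dim %d does not match decoder input %d",
          ncol(Z), nrow(params$V1))
  }
  dec_forward(as.matrix(Z), graph$A_hat, params)$H
}

#' Reconstruction loss
#'
#' Squared Frobenius distance `sum_i ||x_i - h_i||^2` between observed and
#' reconstructed expression; the per-spot mean is attached as attribute
#' `"mean"` (the scale used during optimization).
#'
#' @param X,H matrices of identical shape.
#' @return Scalar raw sum of squares with attribute `mean`.
#' @export
reconstruction_loss <- function(X, H) {
  if (!all(dim(X) == dim(H))) stopf("X and H must have identical shape")
  raw <- sum((X - H)^2)
  structure(raw, mean = raw / nrow(X))
}

default_encoder_config <- function() {
  list(latent_dim = 50L, hidden = 256L, alpha = 1.0, beta = 0.1,
       epochs = 400L, lr = 1e-3, seed = 0L)
}

# Forward + all losses + all gradients for one slice. extra_gZ lets callers
# (alignment) inject additional dLoss/dZ before backprop.
slice_step <- function(sd, params, alpha, beta, corrupt_seed,
                       extra_gZ = NULL, extra_loss = 0) {
  fc <- enc_forward(sd$X, sd$A_hat, params)
  Xt <- corrupt_features(sd$X, corrupt_seed)
  ft <- enc_forward(Xt, sd$A_hat, params)
  G <- sigmoid(as.matrix(sd$M %*% fc$Z))

  cg <- contrastive_grads(fc$Z, ft$Z, G, sd$M, params$Theta)
  sg <- spatial_reg_grads(fc$Z, sd$d_c)
  df <- dec_forward(fc$Z, sd$A_hat, params)
  n <- nrow(sd$X)
  recon <- sum((sd$X - df$H)^2) / n
  gH <- 2 * (df$H - sd$X) / n
  db <- dec_backward(gH, df, sd$A_hat, params)

  gZ <- db$gZ + alpha * cg$gZ + beta * sg$gZ
  if (!is.null(extra_gZ)) gZ <- gZ + extra_gZ
  eb_clean <- enc_backward(gZ, fc, sd$A_hat, params)
  eb_corr <- enc_backward(alpha * cg$gZt, ft, sd$A_hat, params)

  grads <- list(
    W1 = eb_clean$W1 + eb_corr$W1, b1 = eb_clean$b1 + eb_corr$b1,
    a1 = eb_clean$a1 + eb_corr$a1,
    W2 = eb_clean$W2 + eb_corr$W2, b2 = eb_clean$b2 + eb_corr$b2,
    a2 = eb_clean$a2 + eb_corr$a2,
    Theta = alpha * cg$gTheta,
    V1 = db$V1, c1 = db$c1, a3 = db$a3,
    V2 = db$V2, c2 = db$c2, a4 = db$a4
  )
  list(loss = recon + alpha * cg$loss + beta * sg$loss + extra_loss,
       recon = recon, contrastive = cg$loss, spatial = sg$loss,
       grads = grads, Z = fc$Z, G = G, H = df$H)
}

prepare_slice_data <- function(slices, graphs) {
  mapply(function(s, g) {
    list(X = s$X, A_hat = g$A_hat,
         M = neighbor_mean_operator(g$A, warn_isolated = FALSE),
         d_c = minmax_offdiag(pairwise_dist(s$coords))$scaled,
         coords = s$coords)
  }, slices, graphs, SIMPLIFY = FALSE)
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

#' Train the shared graph-contrastive autoencoder
#'
#' Minimizes `recon + alpha * contrastive + beta * spatial` jointly over all
#' slices with shared weights (full batch, Adam). The corrupted view is
#' re-drawn every epoch from the run seed.
#'
#' @param slices list of normalized [spatial_slice()] objects.
#' @param graphs list of matching `spatial_graph`s.
#' @param config named list overriding defaults: `latent_dim` (50), `hidden`
#'   (256), `alpha` (1), `beta` (0.1), `epochs` (400), `lr` (1e-3),
#'   `seed` (0).
#' @return List with `params` (trained), `embeddings` (per-slice
#'   [encode_graph()] outputs), and `history` (per-epoch loss data frame).
#' @export
train_encoder <- function(slices, graphs, config = list()) {
  cfg <- utils::modifyList(default_encoder_config(), config)
  if (length(slices) != length(graphs)) stopf("one graph per slice required")
  if (!all(vapply(slices, `[[`, logical(1), "normalized"))) {
    stopf("slices must be normalized before training")
  }
  n_genes <- ncol(slices[[1L]]$X)
  params <- init_encoder_params(n_genes, cfg$hidden, cfg$latent_dim, cfg$seed)
  sdat <- prepare_slice_data(slices, graphs)
  opt <- adam_init(params)
  hist <- matrix(NA_real_, nrow = cfg$epochs, ncol = 4L,
                 dimnames = list(NULL, c("recon", "contrastive", "spatial", "total")))
  corrupt_seeds <- with_seed(cfg$seed,
    matrix(sample.int(.Machine$integer.max, max(cfg$epochs, 1L) * length(slices)),
           ncol = length(slices)))
  if (cfg$epochs > 0L) {
    for (ep in seq_len(cfg$epochs)) {
      grads <- NULL
      tot <- c(0, 0, 0, 0)
      for (t in seq_along(sdat)) {
        st <- slice_step(sdat[[t]], params, cfg$alpha, cfg$beta,
                         corrupt_seeds[ep, t])
        grads <- accumulate_grads(grads, st$grads)
        tot <- tot + c(st$recon, st$contrastive, st$spatial, st$loss)
      }
      if (!all(is.finite(tot))) {
        stopf("non-finite loss at epoch %d (recon=%.3g contrastive=%.3g spatial=%.3g)",
              ep, tot[1], tot[2], tot[3])
      }
      hist[ep, ] <- tot
      upd <- adam_step(params, grads, opt, lr = cfg$lr)
      params <- upd$params
      opt <- upd$state
      class(params) <- "encoder_params"
    }
  }
  embeddings <- mapply(function(s, g) encode_graph(s$X, g, params),
                       slices, graphs, SIMPLIFY = FALSE)
  names(embeddings) <- vapply(slices, `[[`, character(1), "slice_id")
  list(params = params, embeddings = embeddings,
       history = as.data.frame(cbind(epoch = seq_len(nrow(hist)), hist)))
}
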