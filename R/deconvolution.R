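# Cell-type deconvolution: the trained encoder is transferred to the
# scRNA-seq reference, a softmax MLP classifier is trained with a composite
# loss (cross-entropy on labeled cells + signature reconstruction of spot
# expression + proportion/embedding spatial consistency) and yields the
# row-stochastic spot x cell-type proportion matrix P. Gaussian mixture
# clustering of P gives spatial domains.

#' Embed the single-cell reference with frozen encoder weights
#'
#' Applies the SRT-trained encoder to the reference over its SNN graph; the
#' parameter-sharing contract means no weights are updated here.
#'
#' @param ref normalized [sc_reference()].
#' @param snn `spatial_graph` from [build_snn_graph()].
#' @param params trained [init_encoder_params()].
#' @return A `spot_embedding` for the cells.
#' @export
embed_reference <- function(ref, snn, params) {
  if (ncol(ref$X_sc) != nrow(params$W1)) {
    stopf("reference has %d genes but encoder expects %d; harmonize first",
          ncol(ref$X_sc), nrow(params$W1))
  }
  encode_graph(ref$X_sc, snn, params)
}

#' Per-cell-type mean expression signatures
#'
#' Row k of `B` is the mean normalized expression over reference cells of
#' type k.
#'
#' @param ref normalized [sc_reference()].
#' @param cell_types optional type ordering; every named type must have at
#'   least one cell.
#' @return List of class `signature_matrix` with `B` (K x D),
#'   `cell_type_names`, `gene_ids`.
#' @export
compute_signatures <- function(ref, cell_types = NULL) {
  if (is.null(cell_types)) cell_types <- sort(unique(ref$cell_type_labels))
  counts <- table(factor(ref$cell_type_labels, levels = cell_types))
  if (any(counts == 0)) {
    stopf("cell type(s) with zero cells: %s",
          paste(names(counts)[counts == 0], collapse = ", "))
  }
  B <- rowsum(ref$X_sc, group = factor(ref$cell_type_labels, levels = cell_types)) /
    as.numeric(counts)
  structure(list(B = as.matrix(B), cell_type_names = cell_types,
                 gene_ids = ref$gene_ids),
            class = "signature_matrix")
}

#' Initialize the cell-type classifier
#'
#' A one-hidden-layer perceptron (d -> hidden -> K) with ReLU and softmax
#' output.
#'
#' @param d input (embedding) dimension.
#' @param K number of cell types.
#' @param hidden hidden width (default 128).
#' @param seed integer seed.
#' @return Named parameter list of class `classifier_params`.
#' @export
init_classifier_params <- function(d, K, hidden = 128L, seed = 0L) {
  p <- with_seed(seed, list(
    Wc1 = glorot(d, hidden), bc1 = numeric(hidden),
    Wc2 = glorot(hidden, K), bc2 = numeric(K)
  ))
  attr(p, "K") <- K
  class(p) <- "classifier_params"
  p
}

clf_forward_cache <- function(Z, clf) {
  pre <- sweep(Z %*% clf$Wc1, 2L, clf$bc1, "+")
  A1 <- pmax(pre, 0)
  logits <- sweep(A1 %*% clf$Wc2, 2L, clf$bc2, "+")
  list(pre = pre, A1 = A1, logits = logits, P = softmax_rows(logits))
}

#' Classifier forward pass
#'
#' Rows of the output are probability vectors over the K cell types: applied
#' to spot embeddings this is the proportion matrix `P_t`; applied to cell
#' embeddings it gives per-cell type probabilities.
#'
#' @param Z n x d embedding matrix (or `spot_embedding`).
#' @param clf [init_classifier_params()] output.
#' @return n x K row-stochastic matrix.
#' @export
classifier_forward <- function(Z, clf) {
  if (inherits(Z, "spot_embedding")) Z <- Z$Z
  clf_forward_cache(as.matrix(Z), clf)$P
}

# Backprop dL/dlogits through the MLP given the forward cache; returns
# parameter grads.
clf_backward <- function(dlogits, Z, cache, clf) {
  gWc2 <- crossprod(cache$A1, dlogits)
  gbc2 <- colSums(dlogits)
  dA1 <- dlogits %*% t(clf$Wc2)
  dA1[cache$pre <= 0] <- 0
  gWc1 <- crossprod(Z, dA1)
  gbc1 <- colSums(dA1)
  list(Wc1 = gWc1, bc1 = gbc1, Wc2 = gWc2, bc2 = gbc2)
}

softmax_vjp <- function(P, dLdP) {
  P * (dLdP - rowSums(dLdP * P))
}

# Consistency term sum_{i,j} d_P[i,j] (1 - d_Z[i,j]) / N^2 with min-max
# normalized distances; returns loss and dL/dP (d_Z fixed, scale detached).
prop_consistency_grads <- function(P, d_Z_scaled) {
  n <- nrow(P)
  if (n < 2L) return(list(loss = 0, gP = P * 0))
  Ep <- pairwise_dist(P)
  offr <- range(Ep[row(Ep) != col(Ep)])
  if (diff(offr) <= 1e-12) {
    return(list(loss = 0, gP = P * 0))
  }
  mm <- minmax_offdiag(Ep)
  loss <- sum(mm$scaled * (1 - d_Z_scaled)) / (n * n)
  C <- (1 - d_Z_scaled) / (n * n)
  diag(C) <- 0
  W <- dmat_through_minmax(C, Ep, mm)
  S <- W / pmax(Ep, 1e-12)
  S[Ep < 1e-9] <- 0
  diag(S) <- 0
  S2 <- 2 * S
  gP <- rowSums(S2) * P - S2 %*% P
  list(loss = loss, gP = gP)
}

# Anchor-restricted consistency: over matched anchor rows across two slices,
# mean of d_P (1 - d_Z) with per-pair distances min-max normalized.
anchor_consistency_grads <- function(Pa, Pb, Za, Zb) {
  n <- nrow(Pa)
  if (n < 2L) return(list(loss = 0, gPa = Pa * 0, gPb = Pb * 0))
  dp <- sqrt(rowSums((Pa - Pb)^2))
  dz <- sqrt(rowSums((Za - Zb)^2))
  nz <- function(v) {
    r <- range(v)
    if (diff(r) <= 1e-12) list(s = v * 0, span = 1)
    else list(s = (v - r[1]) / diff(r), span = diff(r))
  }
  np <- nz(dp); nzd <- nz(dz)
  loss <- mean(np$s * (1 - nzd$s))
  # dL/ddp including the min-max constants (attained at single anchors)
  cvec <- (1 - nzd$s) / n
  w <- cvec / np$span
  if (diff(range(dp)) > 1e-12) {
    lo <- min(dp); hi <- max(dp)
    g_hi <- -sum(cvec * (dp - lo)) / np$span^2
    g_lo <- sum(cvec * (dp - hi)) / np$span^2
    w[which.max(dp)] <- w[which.max(dp)] + g_hi
    w[which.min(dp)] <- w[which.min(dp)] + g_lo
  } else {
    w <- w * 0
  }
  coef <- w / pmax(dp, 1e-12)
  coef[dp < 1e-9] <- 0
  gPa <- coef * (Pa - Pb)
  list(loss = loss, gPa = gPa, gPb = -gPa)
}

#' Composite classifier loss
#'
#' `L_sc + lambda * sum_t ||X_t - P_t B||_F^2 / N_t + gamma * C_spatial`
#' where `L_sc` is cross-entropy on the labeled reference cells, the middle
#' term asks the proportion-weighted signatures to reconstruct spot
#' expression, and `C_spatial` couples proportion distances to embedding
#' distances over all spot pairs of each slice (plus the same form restricted
#' to anchor pairs when anchors are supplied).
#'
#' @param clf classifier parameters.
#' @param Z_sc cell embeddings (matrix or `spot_embedding`).
#' @param labels per-cell type labels.
#' @param Z_list list of per-slice spot embedding matrices.
#' @param X_list list of per-slice normalized expression matrices.
#' @param B a `signature_matrix` (or plain K x D matrix in the type order of
#'   the classifier).
#' @param lambda,gamma loss weights (default 1, 1).
#' @param cell_types type ordering mapping labels to classifier outputs.
#' @param anchors optional list of anchor sets (see [find_mnn_anchors()])
#'   with elements `a`, `b` (slice indices) and `pairs`.
#' @return Scalar loss with attribute `"parts"`.
#' @export
classifier_loss <- function(clf, Z_sc, labels, Z_list, X_list, B,
                            lambda = 1, gamma = 1, cell_types = NULL,
                            anchors = NULL) {
  lg <- classifier_loss_grads(clf, Z_sc, labels, Z_list, X_list, B,
                              lambda, gamma, cell_types, anchors)
  structure(lg$loss, parts = lg$parts)
}

classifier_loss_grads <- function(clf, Z_sc, labels, Z_list, X_list, B,
                                  lambda = 1, gamma = 1, cell_types = NULL,
                                  anchors = NULL, d_Z_scaled = NULL) {
  if (inherits(Z_sc, "spot_embedding")) Z_sc <- Z_sc$Z
  if (inherits(B, "signature_matrix")) {
    if (is.null(cell_types)) cell_types <- B$cell_type_names
    B <- B$B
  }
  if (is.null(cell_types)) cell_types <- sort(unique(labels))
  K <- length(cell_types)
  nc <- nrow(Z_sc)
  y <- match(labels, cell_types)
  if (anyNA(y)) stopf("labels contain types unknown to the classifier")
  if (ncol(B) != ncol(X_list[[1L]])) {
    stopf("signature matrix has %d genes but slices have %d",
          ncol(B), ncol(X_list[[1L]]))
  }

  # -- cross-entropy on the reference
  csc <- clf_forward_cache(Z_sc, clf)
  eps <- 1e-12
  L_sc <- -mean(log(pmax(csc$P[cbind(seq_len(nc), y)], eps)))
  Y <- matrix(0, nc, K)
  Y[cbind(seq_len(nc), y)] <- 1
  dlog_sc <- (csc$P - Y) / nc
  grads <- clf_backward(dlog_sc, Z_sc, csc, clf)

  # -- per-slice terms
  if (is.null(d_Z_scaled)) {
    d_Z_scaled <- lapply(Z_list, function(z) minmax_offdiag(pairwise_dist(z))$scaled)
  }
  caches <- lapply(Z_list, function(z) clf_forward_cache(as.matrix(z), clf))
  L_rec <- 0; L_spa <- 0
  dLdP <- vector("list", length(Z_list))
  for (t in seq_along(Z_list)) {
    P <- caches[[t]]$P
    Nt <- nrow(P); D <- ncol(B)
    R <- P %*% B - X_list[[t]]
    # per-spot mean of the squared residual, genes summed: keeps the term on
    # the scale of the printed objective (raw Frobenius) per spot, so it is
    # not drowned out by the reference cross-entropy
    L_rec <- L_rec + sum(R^2) / Nt
    dP <- 2 * tcrossprod(R, B) / Nt * lambda
    pc <- prop_consistency_grads(P, d_Z_scaled[[t]])
    L_spa <- L_spa + pc$loss
    dLdP[[t]] <- dP + gamma * pc$gP
  }

  # -- anchor-restricted consistency
  L_anchor <- 0
  if (!is.null(anchors)) {
    for (an in anchors) {
      if (is.null(an$pairs) || nrow(an$pairs) < 2L) next
      ia <- an$pairs[, 1L]; ib <- an$pairs[, 2L]
      Pa <- caches[[an$a]]$P[ia, , drop = FALSE]
      Pb <- caches[[an$b]]$P[ib, , drop = FALSE]
      Za <- as.matrix(Z_list[[an$a]])[ia, , drop = FALSE]
      Zb <- as.matrix(Z_list[[an$b]])[ib, , drop = FALSE]
      ac <- anchor_consistency_grads(Pa, Pb, Za, Zb)
      L_anchor <- L_anchor + ac$loss
      ga <- matrix(0, nrow(caches[[an$a]]$P), ncol(Pa))
      gb <- matrix(0, nrow(caches[[an$b]]$P), ncol(Pb))
      for (m in seq_along(ia)) {            # anchors may repeat a spot
        ga[ia[m], ] <- ga[ia[m], ] + ac$gPa[m, ]
        gb[ib[m], ] <- gb[ib[m], ] + ac$gPb[m, ]
      }
      dLdP[[an$a]] <- dLdP[[an$a]] + gamma * ga
      dLdP[[an$b]] <- dLdP[[an$b]] + gamma * gb
    }
  }

  for (t in seq_along(Z_list)) {
    dlog <- softmax_vjp(caches[[t]]$P, dLdP[[t]])
    grads <- accumulate_grads(grads, clf_backward(dlog, as.matrix(Z_list[[t]]),
                                                  caches[[t]], clf))
  }
  loss <- L_sc + lambda * L_rec + gamma * (L_spa + L_anchor)
  list(loss = loss, grads = grads,
       parts = c(L_sc = L_sc, recon = L_rec, spatial = L_spa, anchor = L_anchor),
       P_list = lapply(caches, `[[`, "P"))
}

new_ctr <- function(P, cell_types, slice_id) {
  stopifnot(all(abs(rowSums(P) - 1) < 1e-6))
  colnames(P) <- cell_types
  structure(list(P = P, cell_type_names = cell_types, slice_id = slice_id),
            class = "cell_type_representation")
}

#' @export
print.cell_type_representation <- function(x, ...) {
  cat(sprintf("cell_type_representation '%s': %d spots x %d types\n",
              x$slice_id, nrow(x$P), length(x$cell_type_names)))
  invisible(x)
}

default_deconv_config <- function() {
  list(lambda = 1, gamma = 1, epochs = 300L, lr = 1e-3, hidden = 128L,
       seed = 0L)
}

#' Deconvolve spots into cell-type proportions
#'
#' Trains the cell-type classifier on the frozen embeddings (reference cells
#' and spots jointly) by minimizing [classifier_loss()] with Adam, then reads
#' off `P_t = classifier_forward(Z_t)` per slice.
#'
#' @param slices list of normalized [spatial_slice()] objects (harmonized
#'   genes).
#' @param graphs matching `spatial_graph`s.
#' @param ref normalized [sc_reference()] (harmonized genes).
#' @param snn SNN graph of the reference.
#' @param params trained encoder parameters.
#' @param config overrides: `lambda` (1), `gamma` (1), `epochs` (300),
#'   `lr` (1e-3), `hidden` (128), `seed` (0).
#' @param anchors optional anchor sets forwarded to the loss.
#' @param clf_init optional classifier to warm-start from (used when
#'   re-fitting after alignment); defaults to a fresh initialization.
#' @return List with `proportions` (per-slice `cell_type_representation`),
#'   `clf`, `signatures`, `Z_sc`, `embeddings`, `history`.
#' @export
deconvolve <- function(slices, graphs, ref, snn, params, config = list(),
                       anchors = NULL, clf_init = NULL) {
  cfg <- utils::modifyList(default_deconv_config(), config)
  if (!ref$normalized) stopf("reference must be normalized")
  sig <- compute_signatures(ref)
  cell_types <- sig$cell_type_names
  K <- length(cell_types)
  emb_sc <- embed_reference(ref, snn, params)
  embeddings <- mapply(function(s, g) encode_graph(s$X, g, params),
                       slices, graphs, SIMPLIFY = FALSE)
  Z_list <- lapply(embeddings, `[[`, "Z")
  X_list <- lapply(slices, `[[`, "X")
  d_Z_scaled <- lapply(Z_list, function(z) minmax_offdiag(pairwise_dist(z))$scaled)

  clf <- clf_init %||%
    init_classifier_params(ncol(emb_sc$Z), K, cfg$hidden, cfg$seed)
  opt <- adam_init(clf)
  hist <- matrix(NA_real_, cfg$epochs, 4L,
                 dimnames = list(NULL, c("L_sc", "recon", "spatial", "total")))
  for (ep in seq_len(cfg$epochs)) {
    lg <- classifier_loss_grads(clf, emb_sc$Z, ref$cell_type_labels,
                                Z_list, X_list, sig$B,
                                lambda = cfg$lambda, gamma = cfg$gamma,
                                cell_types = cell_types, anchors = anchors,
                                d_Z_scaled = d_Z_scaled)
    if (!is.finite(lg$loss)) stopf("non-finite classifier loss at epoch %d", ep)
    hist[ep, ] <- c(lg$parts[["L_sc"]], lg$parts[["recon"]],
                    lg$parts[["spatial"]], lg$loss)
    upd <- adam_step(clf, lg$grads, opt, lr = cfg$lr)
    clf <- upd$params
    opt <- upd$state
    class(clf) <- "classifier_params"
    attr(clf, "K") <- K
  }
  proportions <- mapply(function(z, s) {
    new_ctr(classifier_forward(z, clf), cell_types, s$slice_id)
  }, Z_list, slices, SIMPLIFY = FALSE)
  names(proportions) <- vapply(slices, `[[`, character(1), "slice_id")
  list(proportions = proportions, clf = clf, signatures = sig,
       Z_sc = emb_sc$Z, embeddings = embeddings,
       history = as.data.frame(cbind(epoch = seq_len(nrow(hist)), hist)))
}

# ---- Gaussian mixture clustering of the proportion matrix ----

gmm_em <- function(X, G, seed = 0L, max_iter = 200L, tol = 1e-8,
                   ridge = 1e-6, n_start = 10L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (G > n) stopf("n_domains (%d) exceeds number of observations (%d)", G, n)
  if (G == 1L) return(list(labels = rep(1L, n), loglik = NA_real_))
  km <- with_seed(seed, stats::kmeans(X, centers = G, nstart = n_start,
                                      iter.max = 50L))
  resp <- matrix(0, n, G)
  resp[cbind(seq_len(n), km$cluster)] <- 1

  log_dens <- function(mu, Sigma, w) {
    out <- matrix(0, n, G)
    for (g in seq_len(G)) {
      ch <- chol(Sigma[[g]])
      xc <- sweep(X, 2L, mu[[g]])
      q <- backsolve(ch, t(xc), transpose = TRUE)
      out[, g] <- log(w[g]) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi) -
        0.5 * colSums(q^2)
    }
    out
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # M step
    nk <- colSums(resp) + 1e-12
    w <- nk / n
    mu <- lapply(seq_len(G), function(g) colSums(resp[, g] * X) / nk[g])
    Sigma <- lapply(seq_len(G), function(g) {
      xc <- sweep(X, 2L, mu[[g]])
      S <- crossprod(xc * resp[, g], xc) / nk[g]
      S + diag(ridge, p)
    })
    # E step
    ld <- log_dens(mu, Sigma, w)
    m <- apply(ld, 1L, max)
    lse <- m + log(rowSums(exp(ld - m)))
    resp <- exp(ld - lse)
    ll <- sum(lse)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(labels = max.col(resp, ties.method = "first"), loglik = ll_old,
       resp = resp)
}

#' Cluster spots into spatial domains
#'
#' Fits a full-covariance Gaussian mixture (EM, k-means initialization with
#' 10 restarts, 1e-6 covariance ridge) to the cell-type representation and
#' labels each spot with its maximum-responsibility component. Pass the
#' proportions of several slices together so domain labels are comparable
#' across slices.
#'
#' @param P a `cell_type_representation`, a list of them, or a plain matrix.
#' @param n_domains number of mixture components.
#' @param seed integer seed.
#' @return Object of class `domain_labels`: integer `labels` (concatenated
#'   over input slices), `slice` (factor of slice ids), `source = "gmm"`.
#' @export
cluster_domains <- function(P, n_domains, seed = 0L) {
  if (inherits(P, "cell_type_representation")) P <- list(P)
  if (is.list(P) && !is.data.frame(P)) {
    slice_ids <- rep(vapply(P, `[[`, character(1), "slice_id"),
                     vapply(P, function(x) nrow(x$P), integer(1)))
    M <- do.call(rbind, lapply(P, `[[`, "P"))
  } else {
    M <- as.matrix(P)
    slice_ids <- rep("slice", nrow(M))
  }
  if (n_domains < 1L) stopf("n_domains must be >= 1")
  fit <- gmm_em(M, n_domains, seed = seed)
  structure(list(labels = fit$labels, slice = factor(slice_ids),
                 source = "gmm", loglik = fit$loglik),
            class = "domain_labels")
}

#' @export
print.domain_labels <- function(x, ...) {
  cat(sprintf("domain_labels (%s): %d spots, %d domains\n",
              x$source, length(x$labels), length(unique(x$labels))))
  invisible(x)
}
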