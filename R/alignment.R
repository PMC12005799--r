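# Cross-slice alignment: mutual-nearest-neighbor anchors detected on
# proportion vectors (or embeddings), a multi-kernel Gaussian MMD loss that
# pulls anchor embedding distributions together while the encoder is
# fine-tuned, and the semi-supervised domain classifier that propagates one
# slice's annotation to the others.

#' Find mutual-nearest-neighbor anchors between two representations
#'
#' Pair (i, j) is an anchor iff j is among the k nearest rows of `R_b` to
#' `R_a[i, ]` and i is among the k nearest rows of `R_a` to `R_b[j, ]`
#' (Euclidean distance, ties broken by index).
#'
#' @param R_a,R_b matrices with a common column dimension.
#' @param k neighborhood size (default 5); must be smaller than both row
#'   counts.
#' @param space label recorded on the result (`"embedding"` or
#'   `"proportions"`).
#' @return List of class `anchor_set` with `pairs` (n x 2 index matrix),
#'   `n`, `space`.
#' @export
find_mnn_anchors <- function(R_a, R_b, k = 5L, space = "embedding") {
  R_a <- as.matrix(R_a); R_b <- as.matrix(R_b)
  if (ncol(R_a) != ncol(R_b)) stopf("feature dimensions differ")
  na <- nrow(R_a); nb <- nrow(R_b)
  if (k >= min(na, nb)) {
    stopf("k (%d) must be smaller than both set sizes (%d, %d)", k, na, nb)
  }
  ab <- cross_knn(R_a, R_b, k)   # na x k indices into R_b
  ba <- cross_knn(R_b, R_a, k)   # nb x k indices into R_a
  Nab <- Matrix::sparseMatrix(i = rep(seq_len(na), each = k),
                              j = as.vector(t(ab)), x = 1, dims = c(na, nb))
  Nba <- Matrix::sparseMatrix(i = as.vector(t(ba)),
                              j = rep(seq_len(nb), each = k), x = 1,
                              dims = c(na, nb))
  both <- Matrix::which(Nab * Nba > 0, arr.ind = TRUE)
  pairs <- both[order(both[, 1L], both[, 2L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("a", "b"))
  structure(list(pairs = pairs, n = nrow(pairs), space = space),
            class = "anchor_set")
}

cross_knn <- function(query, data, k) {
  nn <- RANN::nn2(data, query, k = min(k + 2L, nrow(data)))
  t(vapply(seq_len(nrow(query)), function(i) {
    o <- order(nn$nn.dists[i, ], nn$nn.idx[i, ])
    nn$nn.idx[i, o][seq_len(k)]
  }, integer(k)))
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("anchor_set: %d mutual pairs (%s space)\n", x$n, x$space))
  invisible(x)
}

gauss_kernel_sums <- function(A, B, bw) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  Reduce(`+`, lapply(bw, function(s) exp(-d2 / (2 * s^2))))
}

median_heuristic_bw <- function(A, B) {
  pooled <- rbind(A, B)
  n <- nrow(pooled)
  if (n > 200L) pooled <- pooled[with_seed(0L, sample.int(n, 200L)), , drop = FALSE]
  d <- pairwise_dist(pooled)
  med <- stats::median(d[row(d) != col(d)])
  if (!is.finite(med) || med <= 0) med <- 1
  med * c(0.5, 1, 2)
}

#' Multi-kernel Gaussian MMD^2 between two samples
#'
#' Biased V-statistic
#' `mean k(A,A) + mean k(B,B) - 2 mean k(A,B)` with Gaussian kernels
#' `k(x, y) = exp(-||x - y||^2 / (2 s^2))`, summed over the bandwidth list
#' (default: median heuristic of the pooled pairwise distances times
#' 0.5, 1, 2). Always non-negative.
#'
#' @param Za,Zb n x d and m x d sample matrices.
#' @param bandwidths numeric vector of kernel bandwidths s.
#' @return Scalar MMD^2 (0 with a warning for an empty sample).
#' @export
mmd_loss <- function(Za, Zb, bandwidths = NULL) {
  Za <- rbind(Za); Zb <- rbind(Zb)
  if (nrow(Za) == 0L || nrow(Zb) == 0L) {
    warnf("empty sample: MMD set to 0")
    return(0)
  }
  if (is.null(bandwidths)) bandwidths <- median_heuristic_bw(Za, Zb)
  mean(gauss_kernel_sums(Za, Za, bandwidths)) +
    mean(gauss_kernel_sums(Zb, Zb, bandwidths)) -
    2 * mean(gauss_kernel_sums(Za, Zb, bandwidths))
}

# MMD^2 with gradients wrt both samples.
mmd_grads <- function(Za, Zb, bandwidths) {
  n <- nrow(Za); m <- nrow(Zb)
  loss <- 0
  gA <- Za * 0; gB <- Zb * 0
  for (s in bandwidths) {
    Kaa <- gauss_kernel_sums(Za, Za, s)
    Kbb <- gauss_kernel_sums(Zb, Zb, s)
    Kab <- gauss_kernel_sums(Za, Zb, s)
    loss <- loss + mean(Kaa) + mean(Kbb) - 2 * mean(Kab)
    s2 <- s^2
    # within-A: dL/da_i = -(2/(n^2 s^2)) sum_j Kaa_ij (a_i - a_j)
    wa <- Kaa / (n * n * s2)
    gA <- gA - 2 * (rowSums(wa) * Za - wa %*% Za)
    wb <- Kbb / (m * m * s2)
    gB <- gB - 2 * (rowSums(wb) * Zb - wb %*% Zb)
    # cross term: +(2/(n m s^2)) sum_j Kab_ij (a_i - b_j)
    wc <- 2 * Kab / (n * m * s2)
    gA <- gA + (rowSums(wc) * Za - wc %*% Zb)
    gB <- gB + (colSums(wc) * Zb - t(wc) %*% Za)
  }
  list(loss = loss, gA = gA, gB = gB)
}

default_align_config <- function() {
  list(delta = 1.0, k_anchor = 5L, space = "proportions", epochs = 100L,
       anchor_refresh = 50L, lr = 1e-4, freeze_encoder = FALSE,
       refit_epochs = 150L, refit_lr = 1e-3, alpha = 1.0, beta = 0.1,
       seed = 0L, lambda = 1, gamma = 1)
}

#' Align slices by minimizing anchor MMD while fine-tuning the encoder
#'
#' Anchors between every slice pair are detected in the configured space
#' (proportion vectors by default) and refreshed every
#' `config$anchor_refresh` epochs; each epoch the encoder takes a gradient
#' step on its reconstruction + contrastive + spatial objectives plus
#' `delta` times the summed anchor MMD^2. Afterwards the cell-type
#' classifier is re-fitted on the aligned embeddings with the
#' anchor-restricted consistency term active, and P is recomputed.
#'
#' @param slices normalized, gene-harmonized slices (>= 2).
#' @param graphs matching `spatial_graph`s.
#' @param ref normalized reference.
#' @param snn reference SNN graph.
#' @param params trained encoder parameters.
#' @param clf trained classifier (anchor space "proportions" uses it).
#' @param config overrides of `delta` (1), `k_anchor` (5), `space`
#'   ("proportions"), `epochs` (100), `anchor_refresh` (50), `lr` (1e-4,
#'   a gentle fine-tuning rate that preserves already-aligned structure),
#'   `freeze_encoder` (FALSE), `refit_epochs` (150), `refit_lr` (1e-3),
#'   plus the encoder
#'   weights `alpha`, `beta` and loss weights `lambda`, `gamma`.
#' @return List: `params`, `embeddings`, `proportions`, `clf`, `anchors`,
#'   `mmd_history` (per-epoch summed anchor MMD^2), `signatures`.
#' @export
align_slices <- function(slices, graphs, ref, snn, params, clf,
                         config = list()) {
  cfg <- utils::modifyList(default_align_config(), config)
  Tn <- length(slices)
  if (Tn < 2L) stopf("alignment needs at least 2 slices")
  sdat <- prepare_slice_data(slices, graphs)
  pairs_all <- utils::combn(Tn, 2L, simplify = FALSE)
  opt <- adam_init(params)
  mmd_hist <- numeric(0)
  anchors <- NULL
  bw <- NULL

  current_Z <- function() {
    lapply(sdat, function(sd) enc_forward(sd$X, sd$A_hat, params)$Z)
  }
  refresh_anchors <- function(Z_list) {
    reps <- if (cfg$space == "proportions") {
      lapply(Z_list, classifier_forward, clf = clf)
    } else Z_list
    out <- list()
    for (pr in pairs_all) {
      an <- find_mnn_anchors(reps[[pr[1L]]], reps[[pr[2L]]], cfg$k_anchor,
                             space = cfg$space)
      if (an$n == 0L) {
        warnf("no anchors between slices %d and %d; pair skipped",
              pr[1L], pr[2L])
        next
      }
      out[[length(out) + 1L]] <- list(a = pr[1L], b = pr[2L],
                                      pairs = an$pairs, n = an$n)
    }
    out
  }

  corrupt_seeds <- with_seed(cfg$seed,
    matrix(sample.int(.Machine$integer.max, max(cfg$epochs, 1L) * Tn), ncol = Tn))

  for (ep in seq_len(cfg$epochs)) {
    if (is.null(anchors) || (ep - 1L) %% cfg$anchor_refresh == 0L) {
      anchors <- refresh_anchors(current_Z())
    }
    Z_list <- current_Z()
    if (is.null(bw)) {
      pooled <- do.call(rbind, Z_list)
      bw <- median_heuristic_bw(pooled, pooled)
    }
    extra_gZ <- lapply(Z_list, function(z) z * 0)
    mmd_total <- 0
    for (an in anchors) {
      Za <- Z_list[[an$a]][an$pairs[, 1L], , drop = FALSE]
      Zb <- Z_list[[an$b]][an$pairs[, 2L], , drop = FALSE]
      mg <- mmd_grads(Za, Zb, bw)
      mmd_total <- mmd_total + mg$loss
      # the MMD^2 term enters the objective summed over anchors (weight
      # n_anchors), putting it on the same per-observation currency as the
      # per-spot reconstruction loss
      w <- cfg$delta * nrow(an$pairs)
      for (m in seq_len(nrow(an$pairs))) {
        ia <- an$pairs[m, 1L]; ib <- an$pairs[m, 2L]
        extra_gZ[[an$a]][ia, ] <- extra_gZ[[an$a]][ia, ] + w * mg$gA[m, ]
        extra_gZ[[an$b]][ib, ] <- extra_gZ[[an$b]][ib, ] + w * mg$gB[m, ]
      }
    }
    mmd_hist <- c(mmd_hist, mmd_total)
    if (cfg$freeze_encoder) next
    grads <- NULL
    for (t in seq_len(Tn)) {
      st <- slice_step(sdat[[t]], params, cfg$alpha, cfg$beta,
                       corrupt_seeds[ep, t], extra_gZ = extra_gZ[[t]])
      grads <- accumulate_grads(grads, st$grads)
    }
    upd <- adam_step(params, grads, opt, lr = cfg$lr)
    params <- upd$params
    opt <- upd$state
    class(params) <- "encoder_params"
  }

  # classifier refit on aligned embeddings (warm start), anchor consistency
  # active
  final_anchors <- refresh_anchors(current_Z())
  dc <- deconvolve(slices, graphs, ref, snn, params,
                   config = list(lambda = cfg$lambda, gamma = cfg$gamma,
                                 epochs = cfg$refit_epochs,
                                 lr = cfg$refit_lr, seed = cfg$seed),
                   anchors = final_anchors, clf_init = clf)
  list(params = params, embeddings = dc$embeddings,
       proportions = dc$proportions, clf = dc$clf,
       signatures = dc$signatures, Z_sc = dc$Z_sc,
       anchors = final_anchors, mmd_history = mmd_hist)
}

# ---- semi-supervised domain classifier ----

default_semi_config <- function() {
  list(hidden = c(512L, 512L), epochs = 300L, lr = 1e-3, seed = 0L)
}

#' Train the semi-supervised domain classifier
#'
#' A three-layer perceptron (d -> 512 -> 512 -> M, ReLU) minimizing mean
#' cross-entropy over the labeled spots of one annotated slice.
#'
#' @param Z_labeled n x d aligned embeddings of the labeled slice (matrix or
#'   `spot_embedding`).
#' @param labels per-spot domain labels.
#' @param config overrides: `hidden` (c(512, 512)), `epochs` (300),
#'   `lr` (1e-3), `seed` (0).
#' @return Object of class `semi_classifier` (weights, `domain_names`,
#'   `history`).
#' @export
train_semi_classifier <- function(Z_labeled, labels, config = list()) {
  cfg <- utils::modifyList(default_semi_config(), config)
  if (inherits(Z_labeled, "spot_embedding")) Z_labeled <- Z_labeled$Z
  Z <- as.matrix(Z_labeled)
  labels <- as.character(labels)
  if (length(labels) != nrow(Z)) stopf("one label per labeled spot required")
  domains <- sort(unique(labels))
  M <- length(domains)
  small <- table(labels)[table(labels) < 2L]
  if (length(small)) {
    warnf("domain(s) with fewer than 2 labeled spots: %s",
          paste(names(small), collapse = ", "))
  }
  y <- match(labels, domains)
  n <- nrow(Z)
  Y <- matrix(0, n, M); Y[cbind(seq_len(n), y)] <- 1
  h1 <- cfg$hidden[1L]; h2 <- cfg$hidden[2L]
  p <- with_seed(cfg$seed, list(
    U1 = glorot(ncol(Z), h1), d1 = numeric(h1),
    U2 = glorot(h1, h2), d2 = numeric(h2),
    U3 = glorot(h2, M), d3 = numeric(M)
  ))
  opt <- adam_init(p)
  hist <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    pre1 <- sweep(Z %*% p$U1, 2L, p$d1, "+"); A1 <- pmax(pre1, 0)
    pre2 <- sweep(A1 %*% p$U2, 2L, p$d2, "+"); A2 <- pmax(pre2, 0)
    logits <- sweep(A2 %*% p$U3, 2L, p$d3, "+")
    P <- softmax_rows(logits)
    hist[ep] <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
    dlog <- (P - Y) / n
    g <- list(U3 = crossprod(A2, dlog), d3 = colSums(dlog))
    dA2 <- dlog %*% t(p$U3); dA2[pre2 <= 0] <- 0
    g$U2 <- crossprod(A1, dA2); g$d2 <- colSums(dA2)
    dA1 <- dA2 %*% t(p$U2); dA1[pre1 <= 0] <- 0
    g$U1 <- crossprod(Z, dA1); g$d1 <- colSums(dA1)
    upd <- adam_step(p, g, opt, lr = cfg$lr)
    p <- upd$params; opt <- upd$state
  }
  structure(c(p, list(domain_names = domains, history = hist)),
            class = "semi_classifier")
}

#' Predict spatial domains with the semi-supervised classifier
#'
#' @param clf a trained `semi_classifier`.
#' @param Z n x d embeddings aligned into the training space (matrix or
#'   `spot_embedding`).
#' @return `domain_labels` with character labels (`domain_names`), source
#'   `"semi_classifier"`, and per-domain probabilities in attribute
#'   `"probabilities"`.
#' @export
predict_domains <- function(clf, Z) {
  if (inherits(Z, "spot_embedding")) Z <- Z$Z
  Z <- as.matrix(Z)
  if (ncol(Z) != nrow(clf$U1)) {
    stopf("embedding dim %d does not match classifier input %d",
          ncol(Z), nrow(clf$U1))
  }
  A1 <- pmax(sweep(Z %*% clf$U1, 2L, clf$d1, "+"), 0)
  A2 <- pmax(sweep(A1 %*% clf$U2, 2L, clf$d2, "+"), 0)
  P <- softmax_rows(sweep(A2 %*% clf$U3, 2L, clf$d3, "+"))
  colnames(P) <- clf$domain_names
  structure(list(labels = clf$domain_names[max.col(P, ties.method = "first")],
                 slice = NULL, source = "semi_classifier"),
            class = "domain_labels", probabilities = P)
}
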