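test_that("compute_signatures equals a group-by-mean oracle", {
  set.seed(14)
  X <- matrix(abs(rnorm(30 * 8)), 30, 8,
              dimnames = list(paste0("c", 1:30), paste0("g", 1:8)))
  lab <- sample(c("a", "b", "c"), 30, replace = TRUE)
  ref <- sc_reference(X, lab, normalized = TRUE)
  sig <- compute_signatures(ref)
  for (k in sig$cell_type_names) {
    expect_equal(unname(sig$B[k, ]), unname(colMeans(X[lab == k, ])))
  }
  # one cell per type: rows equal the cells themselves
  ref1 <- sc_reference(X[1:3, ], c("a", "b", "c"), normalized = TRUE)
  expect_equal(unname(compute_signatures(ref1)$B), unname(X[1:3, ]))
  # duplicating the reference leaves B unchanged
  ref2 <- sc_reference(rbind(X, X), c(lab, lab), normalized = TRUE)
  expect_equal(compute_signatures(ref2)$B, sig$B)
  expect_error(compute_signatures(ref, cell_types = c("a", "b", "zz")), "zz")
})

test_that("relabeling types permutes signature rows", {
  set.seed(15)
  X <- matrix(abs(rnorm(20 * 5)), 20, 5)
  lab <- sample(c("t1", "t2"), 20, replace = TRUE)
  ref <- sc_reference(X, lab, normalized = TRUE)
  sw <- c(t1 = "t2", t2 = "t1")
  refp <- sc_reference(X, unname(sw[lab]), normalized = TRUE)
  B1 <- compute_signatures(ref)$B
  B2 <- compute_signatures(refp)$B
  expect_equal(unname(B2["t2", ]), unname(B1["t1", ]))
  expect_equal(unname(B2["t1", ]), unname(B1["t2", ]))
})

test_that("classifier output is row-stochastic, uniform at zero weights", {
  clf <- init_classifier_params(4L, 3L, hidden = 6L, seed = 1L)
  Z <- matrix(rnorm(40), 10, 4)
  P <- classifier_forward(Z, clf)
  expect_equal(rowSums(P), rep(1, 10))
  clf0 <- clf
  for (nm in names(clf0)) clf0[[nm]][] <- 0
  expect_equal(classifier_forward(Z, clf0), matrix(1 / 3, 10, 3),
               ignore_attr = TRUE)
})

test_that("classifier loss reduces to cross-entropy when lambda = gamma = 0", {
  set.seed(16)
  nc <- 25L; d <- 4L; K <- 3L; D <- 7L
  Z_sc <- matrix(rnorm(nc * d), nc, d)
  types <- paste0("t", 1:K)
  labels <- sample(types, nc, replace = TRUE)
  Z_list <- list(matrix(rnorm(8 * d), 8, d))
  X_list <- list(matrix(abs(rnorm(8 * D)), 8, D))
  B <- matrix(abs(rnorm(K * D)), K, D)
  clf <- init_classifier_params(d, K, hidden = 5L, seed = 2L)
  l <- classifier_loss(clf, Z_sc, labels, Z_list, X_list, B,
                       lambda = 0, gamma = 0, cell_types = types)
  P <- classifier_forward(Z_sc, clf)
  ce <- -mean(log(P[cbind(seq_len(nc), match(labels, types))]))
  expect_equal(as.numeric(l), ce, tolerance = 1e-12)
})

test_that("classifier loss vanishes at a constructed optimum", {
  # one-hot embeddings, signatures equal to slice rows, huge logit margins
  d <- 3L; K <- 3L; D <- 4L
  types <- paste0("t", 1:K)
  Z_sc <- diag(3)[rep(1:3, each = 4), ]
  labels <- rep(types, each = 4)
  B <- matrix(abs(rnorm(K * D)), K, D)
  Z_list <- list(diag(3))             # one spot per type
  X_list <- list(B)                   # spot expression = its type's signature
  clf <- list(Wc1 = diag(3) * 50, bc1 = rep(0, 3),
              Wc2 = diag(3) * 50, bc2 = rep(0, 3))
  class(clf) <- "classifier_params"
  l <- classifier_loss(clf, Z_sc, labels, Z_list, X_list, B,
                       lambda = 1, gamma = 0, cell_types = types)
  expect_lt(as.numeric(l), 1e-6)
})

test_that("classifier gradients agree with finite differences", {
  set.seed(17)
  nc <- 20L; d <- 3L; K <- 3L; D <- 5L
  types <- paste0("t", 1:K)
  Z_sc <- matrix(rnorm(nc * d), nc, d)
  labels <- sample(types, nc, replace = TRUE)
  Z_list <- list(matrix(rnorm(7 * d), 7, d), matrix(rnorm(6 * d), 6, d))
  X_list <- list(matrix(abs(rnorm(7 * D)), 7, D),
                 matrix(abs(rnorm(6 * D)), 6, D))
  B <- matrix(abs(rnorm(K * D)), K, D)
  anchors <- list(list(a = 1L, b = 2L,
                       pairs = cbind(a = c(1L, 3L, 5L), b = c(2L, 4L, 6L))))
  clf <- init_classifier_params(d, K, hidden = 4L, seed = 3L)
  lg <- spotweave:::classifier_loss_grads(clf, Z_sc, labels, Z_list, X_list,
                                          B, 1, 1, types, anchors)
  f <- function(p) {
    class(p) <- "classifier_params"
    spotweave:::classifier_loss_grads(p, Z_sc, labels, Z_list, X_list,
                                      B, 1, 1, types, anchors)$loss
  }
  eps <- 1e-6
  for (nm in names(clf)) {
    idx <- if (length(clf[[nm]]) > 4L) sample(length(clf[[nm]]), 4L)
           else seq_along(clf[[nm]])
    for (i in idx) {
      pp <- clf; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- clf; pm[[nm]][i] <- pm[[nm]][i] - eps
      expect_equal(lg$grads[[nm]][i], (f(pp) - f(pm)) / (2 * eps),
                   tolerance = 1e-3, label = sprintf("clf grad %s[%d]", nm, i))
    }
  }
})

test_that("frozen-weight transfer embeds the reference without touching params", {
  prep <- tiny_prep()
  fit <- tiny_encoder()
  before <- fit$params
  emb <- embed_reference(prep$ref, prep$snn, fit$params)
  expect_identical(fit$params, before)
  expect_equal(dim(emb$Z), c(nrow(prep$ref$X_sc), 50L))
  # a slice treated as its own "reference" embeds identically
  s <- prep$slices[[1L]]
  g <- prep$graphs[[1L]]
  fake_ref <- sc_reference(s$X, rep(c("a", "b"), length.out = nrow(s$X)),
                           normalized = TRUE)
  emb2 <- embed_reference(fake_ref, g, fit$params)
  expect_equal(emb2$Z, fit$embeddings[[1L]]$Z)
  # same-type cells sit closer than a shuffled-label null
  Zs <- emb$Z
  lab <- prep$ref$cell_type_labels
  pd <- spotweave:::pairwise_dist(Zs)
  same <- outer(lab, lab, "==") & row(pd) != col(pd)
  gap <- mean(pd[!same & row(pd) != col(pd)]) - mean(pd[same])
  set.seed(5)
  labp <- sample(lab)
  samep <- outer(labp, labp, "==") & row(pd) != col(pd)
  gapp <- mean(pd[!samep & row(pd) != col(pd)]) - mean(pd[samep])
  expect_gt(gap, gapp)
})

test_that("deconvolution recovers pure spots and rejects an absent type", {
  # pure domains: mixing = identity rows, no batch effect
  mix <- diag(3)
  sim <- simulate_benchmark(seed = 19, n_types = 3L, n_genes = 250L,
                            n_markers = 15L, cells_per_type = 60L,
                            grid = c(6L, 6L), n_slices = 1L,
                            mixing = list(mix), batch_scale = 0,
                            cells_per_spot = 8L)
  slices <- lapply(sim$slices, filter_genes)
  gs <- Reduce(intersect, c(lapply(slices, `[[`, "gene_ids"),
                            list(sim$ref$gene_ids)))
  slices <- suppressWarnings(lapply(slices, normalize_log1p))
  refn <- suppressWarnings(normalize_reference(sim$ref))
  hz <- harmonize_genes(slices, refn, gs)
  graphs <- lapply(hz$slices, function(s) build_spatial_graph(s$coords, 5L))
  snn <- build_snn_graph(hz$ref$X_sc, k = 12L, n_pcs = 25L)
  enc <- train_encoder(hz$slices, graphs, config = list(epochs = 120L, seed = 19L))
  dc <- deconvolve(hz$slices, graphs, hz$ref, snn, enc$params,
                   config = list(epochs = 250L, seed = 19L))
  P <- dc$proportions[[1L]]$P
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  truth_type <- paste0("type", sim$truth_domains[[1L]]$labels)
  est_type <- dc$proportions[[1L]]$cell_type_names[max.col(P)]
  expect_gte(mean(est_type == truth_type), 0.95)
})

test_that("trained proportions reconstruct spots better than uniform", {
  prep <- tiny_prep()
  fit <- tiny_encoder()
  dc <- memo("tiny_deconv", deconvolve(prep$slices, prep$graphs, prep$ref,
                                       prep$snn, fit$params,
                                       config = list(epochs = 250L, seed = 7L)))
  B <- dc$signatures$B
  X <- prep$slices[[1L]]$X
  P <- dc$proportions[[1L]]$P
  Pu <- matrix(1 / ncol(P), nrow(P), ncol(P))
  expect_lt(sum((X - P %*% B)^2), sum((X - Pu %*% B)^2))
})

test_that("GMM domain clustering separates blobs and is deterministic", {
  set.seed(20)
  blob <- function(mu, n) sweep(matrix(rnorm(n * 3, sd = 0.05), n, 3), 2L, mu, "+")
  X <- rbind(blob(c(0, 0, 0), 40), blob(c(5, 5, 0), 40), blob(c(0, 5, 5), 40))
  truth <- rep(1:3, each = 40)
  d1 <- cluster_domains(X, 3L, seed = 1L)
  expect_equal(ari(d1$labels, truth), 1)
  d2 <- cluster_domains(X, 3L, seed = 1L)
  expect_identical(d1$labels, d2$labels)
  expect_equal(unique(cluster_domains(X, 1L, seed = 1L)$labels), 1L)
  expect_error(cluster_domains(X[1:2, ], 5L, seed = 1L), "exceeds")
  # cross-check against the reference mixture implementation
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  mc <- mclust::Mclust(X, G = 3L, modelNames = "VVI", verbose = FALSE)
  expect_equal(ari(d1$labels, mc$classification), 1)
})

test_that("cluster_domains on row-stochastic proportions tolerates rank deficiency", {
  set.seed(22)
  P1 <- matrix(abs(rnorm(60 * 4)), 60, 4); P1 <- P1 / rowSums(P1)
  ctr <- new_ctr <- structure(list(P = P1, cell_type_names = paste0("t", 1:4),
                                   slice_id = "S1"),
                              class = "cell_type_representation")
  d <- cluster_domains(ctr, 2L, seed = 3L)
  expect_equal(length(d$labels), 60L)
  expect_equal(levels(d$slice), "S1")
})
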