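test_that("gcn_layer matches the dense product oracle and is equivariant", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 10L; p <- 6L; q <- 4L
    co <- cbind(runif(n), runif(n))
    g <- build_spatial_graph(co, k = 3L)
    X <- matrix(rnorm(n * p), n, p)
    W <- matrix(rnorm(p * q), p, q)
    b <- rnorm(q)
    out <- gcn_layer(X, g$A_hat, W, b, slope = 0.25)
    pre <- as.matrix(g$A_hat) %*% X %*% W
    pre <- sweep(pre, 2L, b, "+")
    oracle <- ifelse(pre > 0, pre, 0.25 * pre)
    expect_lt(max(abs(out - oracle)), 1e-6)

    # node permutation permutes rows identically
    perm <- sample(n)
    P <- diag(n)[perm, ]
    Ahp <- P %*% as.matrix(g$A_hat) %*% t(P)
    outp <- gcn_layer(X[perm, ], Ahp, W, b, slope = 0.25)
    expect_equal(outp, out[perm, ], tolerance = 1e-10)
  }
  # identity graph + identity weights reproduce non-negative input
  Xp <- abs(matrix(rnorm(20), 5, 4))
  expect_equal(gcn_layer(Xp, Matrix::Diagonal(5), diag(4)), Xp,
               ignore_attr = TRUE)
  expect_error(gcn_layer(Xp, Matrix::Diagonal(5), diag(3)), "dimension")
})

test_that("encode_graph derives summary and local context as stated", {
  set.seed(3)
  n <- 12L
  co <- cbind(runif(n), runif(n))
  g <- build_spatial_graph(co, k = 3L)
  X <- abs(matrix(rnorm(n * 8), n, 8))
  params <- init_encoder_params(8L, hidden = 6L, latent_dim = 4L, seed = 1L)
  emb <- encode_graph(X, g, params)
  expect_equal(emb$s, colMeans(emb$Z))
  A <- as.matrix(g$A)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    expected <- if (length(nb)) 1 / (1 + exp(-colMeans(emb$Z[nb, , drop = FALSE])))
                else 1 / (1 + exp(-emb$Z[i, ]))
    expect_equal(unname(emb$g[i, ]), unname(expected), tolerance = 1e-10)
  }
})

test_that("identical features on a symmetric graph give identical embeddings", {
  # a 4-cycle is vertex-transitive; constant features stay constant
  A <- matrix(0, 4, 4)
  A[cbind(1:4, c(2, 3, 4, 1))] <- 1
  A <- pmax(A, t(A))
  g <- structure(list(n_nodes = 4L, A = Matrix::Matrix(A, sparse = TRUE),
                      A_hat = normalize_adjacency(A)),
                 class = "spatial_graph")
  X <- matrix(1, 4, 5)
  params <- init_encoder_params(5L, hidden = 4L, latent_dim = 3L, seed = 2L)
  emb <- encode_graph(X, g, params)
  expect_equal(emb$Z, emb$Z[c(2, 3, 4, 1), ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(sweep(emb$g, 2L, emb$g[1, ]))), 1e-12)
})

test_that("discriminate is a sigmoid bilinear score", {
  expect_equal(discriminate(c(1, 0), c(0, 1), diag(2)), 0.5)
  expect_equal(discriminate(c(1, 0), c(1, 0), diag(2)), 1 / (1 + exp(-1)))
  # strictly increasing in the bilinear form
  th <- diag(2)
  scores <- vapply(seq(-3, 3, length.out = 11), function(s)
    discriminate(c(s, 0), c(1, 0), th), numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("contrastive loss hits ln 2 at chance and 0 at the optimum", {
  n <- 7L; d <- 3L
  Z <- matrix(rnorm(n * d), n, d)
  G <- matrix(rnorm(n * d), n, d)
  expect_equal(contrastive_loss(Z, Z, G, matrix(0, d, d)), log(2),
               tolerance = 1e-12)
  # construct near-perfect discrimination
  Zp <- matrix(rep(c(1, 0, 0), each = n), n, d)
  Zn <- -Zp
  Gp <- Zp
  expect_lt(contrastive_loss(Zp, Zn, Gp, diag(d) * 50), 1e-6)
  # non-negative under clamping for arbitrary inputs
  set.seed(4)
  for (i in 1:10) {
    v <- contrastive_loss(matrix(rnorm(12), 4), matrix(rnorm(12), 4),
                          matrix(rnorm(12), 4), matrix(rnorm(9), 3))
    expect_gte(v, 0)
  }
})

test_that("spatial regularizer handles hand cases and degenerate input", {
  expect_equal(spatial_regularizer(matrix(1, 1, 2), matrix(0, 1, 2)), 0)
  # with injected normalized distances: 2 spots, d_c = 1, d_Z = 0.5
  d_c <- matrix(c(0, 1, 1, 0), 2)
  d_Z <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(spatial_regularizer(NULL, NULL, d_c = d_c, d_Z = d_Z), 0.25)
  expect_equal(spatial_regularizer(NULL, NULL, d_c = d_c,
                                   d_Z = matrix(c(0, 1, 1, 0), 2)), 0)
  # constant embedding: d_Z treated as zero, loss = mean of d_c
  set.seed(6)
  co <- cbind(runif(5), runif(5))
  dc <- spotweave:::minmax_offdiag(spotweave:::pairwise_dist(co))$scaled
  expect_equal(spatial_regularizer(matrix(1, 5, 3), co), sum(dc) / 25)
})

test_that("decode_graph with identity adjacency equals a dense MLP oracle", {
  set.seed(9)
  n <- 6L; d <- 4L
  params <- init_encoder_params(10L, hidden = 5L, latent_dim = d, seed = 3L)
  Z <- matrix(rnorm(n * d), n, d)
  g <- structure(list(A = Matrix::Matrix(0, n, n, sparse = TRUE),
                      A_hat = Matrix::Diagonal(n)), class = "spatial_graph")
  H <- decode_graph(Z, g, params)
  pre1 <- sweep(Z %*% params$V1, 2L, params$c1, "+")
  D1 <- ifelse(pre1 > 0, pre1, params$a3 * pre1)
  pre2 <- sweep(D1 %*% params$V2, 2L, params$c2, "+")
  oracle <- ifelse(pre2 > 0, pre2, params$a4 * pre2)
  expect_equal(H, oracle, tolerance = 1e-10)
  expect_error(decode_graph(matrix(0, 2, 3), g, params), "dim")
})

test_that("reconstruction loss is the summed squared residual", {
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(as.numeric(reconstruction_loss(X, X)), 0)
  expect_equal(as.numeric(reconstruction_loss(matrix(c(1, 0), 1),
                                              matrix(c(0, 0), 1))), 1)
  H <- matrix(rnorm(12), 3, 4)
  r <- reconstruction_loss(X, H)
  expect_equal(as.numeric(r), sum((X - H)^2))
  expect_equal(attr(r, "mean"), sum((X - H)^2) / 3)
  expect_error(reconstruction_loss(X, H[1:2, ]), "shape")
})

test_that("analytic training gradients agree with finite differences", {
  set.seed(42)
  n <- 10L; D <- 6L
  co <- cbind(runif(n), runif(n))
  g <- build_spatial_graph(co, k = 3L)
  X <- abs(matrix(rnorm(n * D), n, D))
  params <- init_encoder_params(D, hidden = 5L, latent_dim = 3L, seed = 1L)
  sd1 <- list(X = X, A_hat = g$A_hat,
              M = spotweave:::neighbor_mean_operator(g$A, warn_isolated = FALSE),
              d_c = spotweave:::minmax_offdiag(spotweave:::pairwise_dist(co))$scaled)
  loss_of <- function(p) {
    class(p) <- "encoder_params"
    spotweave:::slice_step(sd1, p, 1, 0.1, 77L)$loss
  }
  st <- spotweave:::slice_step(sd1, params, 1, 0.1, 77L)
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- if (length(params[[nm]]) > 4L) sample(length(params[[nm]]), 4L)
           else seq_along(params[[nm]])
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(st$grads[[nm]][i], num, tolerance = 1e-2,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  prep <- tiny_prep()
  fit <- tiny_encoder()
  h <- fit$history$total
  sm <- stats::filter(h, rep(1 / 10, 10), sides = 1)
  expect_lt(sm[length(h)], sm[10])
  expect_true(all(is.finite(h)))

  fit0 <- train_encoder(prep$slices[1], prep$graphs[1],
                        config = list(epochs = 0L, seed = 7L))
  fit0b <- train_encoder(prep$slices[1], prep$graphs[1],
                         config = list(epochs = 0L, seed = 7L))
  expect_identical(fit0$params, fit0b$params)

  fitA <- train_encoder(prep$slices[1], prep$graphs[1],
                        config = list(epochs = 5L, seed = 3L))
  fitB <- train_encoder(prep$slices[1], prep$graphs[1],
                        config = list(epochs = 5L, seed = 3L))
  expect_identical(fitA$history, fitB$history)
  expect_identical(fitA$embeddings[[1L]]$Z, fitB$embeddings[[1L]]$Z)
})

test_that("encoder is permutation-equivariant with fixed parameters", {
  prep <- tiny_prep()
  fit <- tiny_encoder()
  s <- prep$slices[[1L]]
  g <- prep$graphs[[1L]]
  n <- nrow(s$X)
  set.seed(1)
  perm <- sample(n)
  P <- Matrix::sparseMatrix(i = seq_len(n), j = perm, x = 1)
  Ap <- P %*% g$A %*% Matrix::t(P)
  gp <- structure(list(A = Ap, A_hat = normalize_adjacency(Ap)),
                  class = "spatial_graph")
  Zp <- encode_graph(s$X[perm, ], gp, fit$params)$Z
  Z <- fit$embeddings[[1L]]$Z
  expect_equal(Zp, Z[perm, ], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("embeddings separate domains and the decoder denoises", {
  prep <- tiny_prep()
  fit <- tiny_encoder()
  sim <- prep$sim
  # within-domain embedding distances smaller than between-domain
  Z <- fit$embeddings[[1L]]$Z
  dom <- sim$truth_domains[[1L]]$labels
  pd <- spotweave:::pairwise_dist(Z)
  same <- outer(dom, dom, "==") & row(pd) != col(pd)
  expect_lt(mean(pd[same]), mean(pd[!same & row(pd) != col(pd)]))

  # denoised expression correlates better with the noise-free domain means
  s <- prep$slices[[1L]]
  H <- decode_graph(Z, prep$graphs[[1L]], fit$params)
  mix <- sim$config$mixing[[1L]]
  tm <- attr(sim$ref, "type_means")[, s$gene_ids]
  expected_counts <- (mix %*% tm)[dom, ] * sim$config$cells_per_spot
  expected_norm <- log1p(expected_counts / rowSums(expected_counts) * 1e4)
  keep <- which(apply(expected_norm, 2L, stats::sd) > 0 &
                apply(s$X, 2L, stats::sd) > 0)
  cor_raw <- vapply(keep, function(j) cor(s$X[, j], expected_norm[, j]),
                    numeric(1))
  cor_den <- vapply(keep, function(j) {
    if (stats::sd(H[, j]) == 0) return(0)
    cor(H[, j], expected_norm[, j])
  }, numeric(1))
  expect_gt(mean(cor_den, na.rm = TRUE), mean(cor_raw, na.rm = TRUE))
})
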