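test_that("reference marker means hit the configured fold change", {
  cfg <- sim_config(n_types = 3L, n_genes = 200L, n_markers = 10L,
                    cells_per_type = 500L, seed = 33L)
  ref <- simulate_reference(cfg)
  means <- attr(ref, "type_means")
  markers <- attr(ref, "marker_sets")
  size <- 1 / cfg$nb_dispersion
  for (k in 1:3) {
    type <- paste0("type", k)
    rows <- ref$cell_type_labels == type
    gs <- markers[[k]][1:5]
    emp <- colMeans(ref$X_sc[rows, gs])
    mu <- means[type, gs]
    se <- sqrt((mu + mu^2 / size) / sum(rows))
    expect_true(all(abs(emp - mu) <= 3 * se + 1e-9))
    # marker mean is fold_change x the baseline carried by other types
    other <- paste0("type", setdiff(1:3, k)[1])
    expect_equal(unname(means[type, gs] / means[other, gs]),
                 rep(cfg$fold_change, 5))
  }
  expect_identical(simulate_reference(cfg)$X_sc, ref$X_sc)
})

test_that("fold change 1 erases type structure", {
  cfg <- sim_config(n_types = 3L, n_genes = 100L, n_markers = 10L,
                    cells_per_type = 30L, fold_change = 1, seed = 34L)
  ref <- simulate_reference(cfg)
  means <- attr(ref, "type_means")
  expect_equal(means[1, ], means[2, ])
  expect_equal(means[2, ], means[3, ])
})

test_that("slices realize the configured mixtures and record realized truth", {
  mix <- diag(3)
  cfg <- sim_config(n_types = 3L, n_genes = 150L, n_markers = 10L,
                    cells_per_type = 40L, n_slices = 1L, grid = c(5L, 6L),
                    mixing = list(mix), batch_scale = 0, seed = 35L)
  ref <- simulate_reference(cfg)
  sim <- simulate_slices(ref, cfg)
  P <- sim$truth_proportions[[1L]]$P
  expect_equal(rowSums(P), rep(1, nrow(P)), ignore_attr = TRUE)
  # pure domains: every realized truth row is one-hot
  expect_true(all(apply(P, 1L, max) == 1))
  expect_equal(nrow(sim$slices[[1L]]$X), 30L)
  # mixing rows that do not sum to one are rejected
  expect_error(sim_config(n_types = 3L, n_slices = 1L,
                          mixing = list(matrix(0.5, 3, 3))), "sum to 1")
})

test_that("expected spot counts follow the law of total expectation", {
  cfg <- sim_config(n_types = 3L, n_genes = 120L, n_markers = 10L,
                    cells_per_type = 80L, n_slices = 1L, grid = c(10L, 20L),
                    batch_scale = 0, cells_per_spot = 10L, seed = 36L)
  ref <- simulate_reference(cfg)
  sim <- simulate_slices(ref, cfg)
  s <- sim$slices[[1L]]
  dom <- sim$truth_domains[[1L]]$labels
  means <- attr(ref, "type_means")
  # within each domain, mean count per gene = cells_per_spot * sum_k mix * mu_k
  # (use the empirical reference means to absorb reference sampling noise)
  emp_type_mean <- rowsum(ref$X_sc, ref$cell_type_labels) /
    as.numeric(table(ref$cell_type_labels))
  for (d in 1:3) {
    rows <- dom == d
    n_d <- sum(rows)
    expected <- cfg$cells_per_spot *
      as.numeric(cfg$mixing[[1L]][d, ] %*% emp_type_mean)
    emp <- colMeans(s$X[rows, ])
    size <- 1 / cfg$nb_dispersion
    mu_cell <- as.numeric(cfg$mixing[[1L]][d, ] %*% means)
    var_spot <- cfg$cells_per_spot * (mu_cell + mu_cell^2 / size +
                                      mu_cell^2)  # + mixture variance slack
    se <- sqrt(var_spot / n_d)
    frac_ok <- mean(abs(emp - expected) <= 3 * se + 0.05)
    expect_gte(frac_ok, 0.97)
  }
})

test_that("benchmark preset encodes the divergent-domain design", {
  sim <- tiny_sim()
  cfg <- sim$config
  expect_identical(cfg$mixing[[1L]], cfg$mixing[[2L]])
  diff_rows <- which(rowSums(cfg$mixing[[3L]] != cfg$mixing[[1L]]) > 0)
  expect_equal(diff_rows, 3L)
  expect_equal(sum(vapply(sim$slices, function(s) nrow(s$X), integer(1))),
               3L * 49L)
  expect_equal(length(unique(sim$truth_domains[[1L]]$labels)), 3L)
})

test_that("without batch effects S1 and S2 are exchangeable", {
  sim <- simulate_benchmark(seed = 37, n_genes = 200L, n_markers = 10L,
                            cells_per_type = 50L, grid = c(8L, 8L),
                            batch_scale = 0)
  m1 <- colMeans(sim$slices[[1L]]$X)
  m2 <- colMeans(sim$slices[[2L]]$X)
  # paired per-gene comparison: overall means differ by < 5%
  expect_lt(abs(sum(m1) - sum(m2)) / sum(m1), 0.05)
  expect_gt(cor(m1, m2), 0.99)
})

test_that("batch effect shifts gene means between slices", {
  sim <- simulate_benchmark(seed = 38, n_genes = 200L, n_markers = 10L,
                            cells_per_type = 50L, grid = c(8L, 8L),
                            batch_scale = 0.4)
  m1 <- colMeans(sim$slices[[1L]]$X)
  m2 <- colMeans(sim$slices[[2L]]$X)
  keep <- m1 > 0.5
  ratio <- m2[keep] / m1[keep]
  # S1 and S2 share mixing, so dispersion in the ratio reflects the batch
  expect_gt(stats::sd(log(ratio)), 0.2)
})

test_that("truth proportions are recoverable from noise-free expected counts", {
  # oracle sanity for the benchmark itself: non-negative least squares on
  # expected domain-level counts against the true type means
  cfg <- sim_config(n_types = 4L, n_genes = 150L, n_markers = 12L,
                    cells_per_type = 30L, n_slices = 1L, seed = 39L)
  ref <- simulate_reference(cfg)
  means <- attr(ref, "type_means")
  mix <- cfg$mixing[[1L]]
  expected <- mix %*% means          # domain x gene, noise free
  nnls <- function(y, B) {
    K <- nrow(B); p <- rep(1 / K, K)
    G <- B %*% t(B); h <- B %*% y
    for (it in 1:2000) for (k in 1:K) {
      p[k] <- max(0, p[k] + (h[k] - sum(G[k, ] * p)) / G[k, k])
    }
    p / sum(p)
  }
  for (d in seq_len(nrow(mix))) {
    est <- nnls(expected[d, ], means)
    expect_equal(unname(est), unname(mix[d, ]), tolerance = 1e-4)
  }
})

test_that("write_simulation emits loadable inputs and truth tables", {
  sim <- simulate_benchmark(seed = 40, n_genes = 80L, n_markers = 8L,
                            cells_per_type = 20L, grid = c(4L, 4L),
                            n_slices = 2L)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- load_slice(file.path(dir, "S1", "counts.mtx"),
                     file.path(dir, "S1", "coords.tsv"),
                     file.path(dir, "S1", "labels.tsv"))
  expect_equal(unname(back$X), unname(sim$slices[[1L]]$X))
  expect_equal(back$domain_labels, sim$slices[[1L]]$domain_labels)
  ref <- load_reference(file.path(dir, "reference", "counts.mtx"),
                        file.path(dir, "reference", "labels.tsv"))
  expect_equal(unname(ref$X_sc), unname(sim$ref$X_sc))
  tp <- read.table(file.path(dir, "S1", "truth_proportions.tsv"),
                   header = TRUE, check.names = FALSE)
  expect_equal(as.matrix(tp[, -1]), sim$truth_proportions[[1L]]$P,
               ignore_attr = TRUE)
})
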