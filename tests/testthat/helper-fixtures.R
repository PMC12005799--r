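# Shared fixtures. Heavy objects are built once per test run and cached in
# this environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small three-slice benchmark (reduced genes/cells/grid) for unit tests.
tiny_sim <- function() {
  memo("tiny_sim", simulate_benchmark(
    seed = 7, n_genes = 300L, n_markers = 12L, cells_per_type = 60L,
    grid = c(7L, 7L)))
}

# Preprocessed version: filtered, normalized, harmonized + graphs.
tiny_prep <- function() {
  memo("tiny_prep", {
    sim <- tiny_sim()
    slices <- lapply(sim$slices, filter_genes)
    gs <- Reduce(intersect, c(lapply(slices, `[[`, "gene_ids"),
                              list(sim$ref$gene_ids)))
    slices <- suppressWarnings(lapply(slices, normalize_log1p))
    refn <- suppressWarnings(normalize_reference(sim$ref))
    hz <- harmonize_genes(slices, refn, gs)
    graphs <- lapply(hz$slices, function(s) build_spatial_graph(s$coords, 6L))
    snn <- build_snn_graph(hz$ref$X_sc, k = 15L, n_pcs = 30L)
    list(sim = sim, slices = hz$slices, ref = hz$ref, graphs = graphs,
         snn = snn)
  })
}

# A short encoder fit on the tiny benchmark, reused by several files.
tiny_encoder <- function() {
  memo("tiny_encoder", {
    prep <- tiny_prep()
    train_encoder(prep$slices, prep$graphs,
                  config = list(epochs = 150L, seed = 7L))
  })
}

random_counts <- function(n, m, seed = 1L, lambda = 2) {
  set.seed(seed)
  matrix(stats::rpois(n * m, lambda), n, m,
         dimnames = list(paste0("s", seq_len(n)), paste0("g", seq_len(m))))
}

make_slice <- function(n = 10L, m = 20L, seed = 1L, lambda = 2) {
  X <- random_counts(n, m, seed, lambda)
  set.seed(seed + 1L)
  spatial_slice(X, cbind(runif(n), runif(n)), slice_id = "test")
}

# Brute-force Delaunay edges by the empty-circumcircle property (O(n^4)),
# an oracle independent of the deldir code path.
brute_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  edges <- matrix(integer(0), 0, 2)
  in_circumcircle <- function(a, b, c, p) {
    m <- cbind(rbind(a, b, c) - rep(p, each = 3),
               c(sum(a^2), sum(b^2), sum(c^2)) - sum(p^2))
    det(m)
  }
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    orient <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(orient) < 1e-12) next
    if (orient < 0) { tmp <- b; b <- c; c <- tmp }
    ok <- TRUE
    for (p in seq_len(n)) {
      if (p %in% c(i, j, k)) next
      if (in_circumcircle(a, b, c, pts[p, ]) > 1e-9) { ok <- FALSE; break }
    }
    if (ok) edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  unique(t(apply(edges, 1L, sort)))
}

edge_set <- function(A) {
  ij <- Matrix::which(A != 0, arr.ind = TRUE)
  ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  paste(ij[, 1], ij[, 2], sep = "-")
}

# Independent pair-counting ARI (O(n^2)), the oracle for the contingency
# implementation.
pair_count_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  ri <- (s11 + s00) / choose(n, 2)
  # expected RI from the hypergeometric model via sums over marginals
  ta <- table(a); tb <- table(b)
  sum_a <- sum(choose(ta, 2)); sum_b <- sum(choose(tb, 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}
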