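# Neighborhood graphs: the alpha-complex spatial graph over spot coordinates,
# the shared-nearest-neighbor graph over reference cells, symmetric adjacency
# normalization and the corrupted-features view used by the contrastive loss.

new_spatial_graph <- function(A, radius_r = NA_real_, k_neighbors = NA_integer_) {
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  structure(
    list(n_nodes = nrow(A), A = A, A_hat = normalize_adjacency(A),
         radius_r = radius_r, k_neighbors = k_neighbors),
    class = "spatial_graph"
  )
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph: %d nodes, %d edges%s\n", x$n_nodes,
              Matrix::nnzero(x$A) / 2,
              if (is.na(x$radius_r)) "" else sprintf(", r = %.4g", x$radius_r)))
  invisible(x)
}

knn_index <- function(coords, k) {
  # RANN breaks distance ties arbitrarily; re-sort by (distance, index) so
  # neighbor sets are reproducible.
  nn <- RANN::nn2(coords, k = min(k + 1L, nrow(coords)))
  idx <- nn$nn.idx
  d <- nn$nn.dists
  t(vapply(seq_len(nrow(coords)), function(i) {
    o <- order(d[i, ], idx[i, ])
    ii <- idx[i, o]
    ii <- ii[ii != i]
    ii[seq_len(k)]
  }, integer(k)))
}

#' Build the alpha-complex spatial graph of one slice
#'
#' Edges are the Delaunay-triangulation 1-skeleton filtered to length at most
#' r, where r is the mean over all spots of the mean distance to their k
#' nearest neighbors. Degenerate coordinate sets (collinear spots) fall back
#' to a k-nearest-neighbor graph with a warning.
#'
#' @param coords spot x 2 coordinate matrix.
#' @param k neighborhood size used to estimate the radius (default 6).
#' @return A `spatial_graph` with binary adjacency `A`, its normalization
#'   `A_hat`, and the radius `radius_r`.
#' @export
build_spatial_graph <- function(coords, k = 6L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stopf("at least 2 spots are required")
  if (k >= n) stopf("k (%d) must be smaller than the number of spots (%d)", k, n)
  if (!all(is.finite(coords))) stopf("coordinates must be finite")
  nn <- RANN::nn2(coords, k = k + 1L)
  r <- mean(rowMeans(nn$nn.dists[, -1L, drop = FALSE]))

  edges <- tryCatch({
    dd <- deldir::deldir(coords[, 1L], coords[, 2L], suppressMsge = TRUE)
    cbind(dd$delsgs$ind1, dd$delsgs$ind2)
  }, error = function(e) NULL)
  if (is.null(edges) || nrow(edges) == 0L) {
    warnf("degenerate triangulation; falling back to a %d-NN graph", k)
    idx <- knn_index(coords, k)
    edges <- cbind(rep(seq_len(n), each = k), as.vector(t(idx)))
  }
  len <- sqrt(rowSums((coords[edges[, 1L], , drop = FALSE] -
                       coords[edges[, 2L], , drop = FALSE])^2))
  edges <- edges[len <= r, , drop = FALSE]
  A <- Matrix::sparseMatrix(i = c(edges[, 1L], edges[, 2L]),
                            j = c(edges[, 2L], edges[, 1L]),
                            x = 1, dims = c(n, n), use.last.ij = TRUE)
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  g <- new_spatial_graph(A, radius_r = r, k_neighbors = as.integer(k))
  g
}

#' Build the shared-nearest-neighbor graph of the reference
#'
#' Cells are embedded with PCA on the normalized expression matrix; for each
#' cell the k nearest neighbors in PC space are found (Euclidean distance,
#' ties by index) and edge (i, j), j in kNN(i), is weighted by the fraction
#' of shared neighbors `|kNN(i) intersect kNN(j)| / k`, symmetrized by the
#' elementwise maximum.
#'
#' @param X cell x gene normalized matrix.
#' @param k number of nearest neighbors (default 20).
#' @param n_pcs number of principal components (default 40; reduced with a
#'   warning when it exceeds the matrix rank).
#' @return A `spatial_graph` with weighted adjacency in `[0, 1]`.
#' @export
build_snn_graph <- function(X, k = 20L, n_pcs = 40L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k + 1L) stopf("need at least k + 1 = %d cells, got %d", k + 1L, n)
  max_pc <- min(n, ncol(X)) - 1L
  if (n_pcs > max_pc) {
    warnf("n_pcs reduced from %d to %d", n_pcs, max_pc)
    n_pcs <- max_pc
  }
  Xc <- sweep(X, 2L, colMeans(X))
  pcs <- if (n > 300L && n_pcs < max_pc / 3) {
    sv <- irlba::irlba(Xc, nv = n_pcs)
    sv$u %*% diag(sv$d, n_pcs)
  } else {
    sv <- svd(Xc, nu = max_pc, nv = 0L)
    sv$u[, seq_len(n_pcs), drop = FALSE] %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  }
  idx <- knn_index(pcs, k)
  # Nmat[i, j] = 1 iff j is one of the k nearest neighbors of i; the sparse
  # product Nmat Nmat^T then counts shared neighbors for every pair at once.
  Nmat <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                               j = as.vector(t(idx)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(Nmat)
  Au <- methods::as(methods::as(Nmat * shared / k, "generalMatrix"),
                    "CsparseMatrix")
  A <- pmax_sparse(Au, Matrix::t(Au))
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  new_spatial_graph(A, k_neighbors = as.integer(k))
}

pmax_sparse <- function(a, b) {
  d <- (a + b) / 2 + abs(a - b) / 2   # elementwise max for sparse matrices
  methods::as(methods::as(d, "generalMatrix"), "CsparseMatrix")
}

#' Symmetrically normalize an adjacency matrix
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` with D the degree matrix of `A + I`
#' (so isolated nodes get a unit diagonal entry).
#'
#' @param A symmetric non-negative adjacency (sparse or dense).
#' @return Sparse symmetric normalized adjacency.
#' @export
normalize_adjacency <- function(A) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (!Matrix::isSymmetric(A, tol = 1e-10)) stopf("adjacency must be symmetric")
  if (any(A@x < 0)) stopf("adjacency must be non-negative")
  n <- nrow(A)
  Ai <- A + Matrix::Diagonal(n)
  dinv <- 1 / sqrt(Matrix::rowSums(Ai))
  Dh <- Matrix::Diagonal(n, dinv)
  methods::as(methods::as(Dh %*% Ai %*% Dh, "generalMatrix"), "CsparseMatrix")
}

#' Corrupt node features for contrastive learning
#'
#' Returns a seeded uniform random row permutation of the feature matrix; the
#' graph structure is left untouched, so corrupted nodes keep their neighbors
#' but carry another node's expression.
#'
#' @param X node x feature matrix.
#' @param seed integer seed for the permutation.
#' @return Matrix of the same shape with permuted rows; the permutation is in
#'   attribute `"perm"`.
#' @export
corrupt_features <- function(X, seed) {
  perm <- with_seed(seed, sample.int(nrow(X)))
  out <- X[perm, , drop = FALSE]
  rownames(out) <- rownames(X)
  attr(out, "perm") <- perm
  out
}

# Row-normalized neighbor-averaging operator used for the local context g:
# row i averages over the graph neighbors of i, or falls back to node i
# itself when it is isolated.
neighbor_mean_operator <- function(A, warn_isolated = TRUE) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  deg <- Matrix::rowSums(A)
  iso <- deg == 0
  if (any(iso)) {
    if (warn_isolated) warnf("%d isolated node(s): local context uses the node itself", sum(iso))
    A <- A + Matrix::sparseMatrix(i = which(iso), j = which(iso),
                                  x = 1, dims = dim(A))
    deg[iso] <- 1
  }
  Matrix::Diagonal(nrow(A), 1 / deg) %*% A
}
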