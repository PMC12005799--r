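# Input/output and preprocessing: reading slices and references, gene
# filtering, per-spot library-size normalization and highly-variable-gene
# selection.

#' Construct a spatial slice object
#'
#' A slice bundles one tissue section's spot-by-gene expression matrix, the
#' 2-D spot coordinates, and optional per-spot domain labels.
#'
#' @param X spot x gene matrix of non-negative values (raw counts unless
#'   `normalized = TRUE`). Dimnames are taken as spot and gene identifiers
#'   when `spot_ids`/`gene_ids` are not given.
#' @param coords spot x 2 numeric matrix of (x, y) platform coordinates.
#' @param slice_id character scalar naming the slice.
#' @param spot_ids,gene_ids character vectors of unique identifiers.
#' @param domain_labels optional per-spot labels (character or factor).
#' @param normalized logical; `TRUE` once `X` holds log-normalized values.
#' @return An object of class `spatial_slice`.
#' @export
spatial_slice <- function(X, coords, slice_id = "slice",
                          spot_ids = rownames(X), gene_ids = colnames(X),
                          domain_labels = NULL, normalized = FALSE) {
  X <- as.matrix(X)
  coords <- as.matrix(coords)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(X)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(X)))
  if (nrow(X) != nrow(coords)) {
    stopf("X has %d spots but coords has %d rows", nrow(X), nrow(coords))
  }
  if (ncol(coords) != 2L) stopf("coords must have exactly 2 columns")
  if (anyDuplicated(spot_ids)) stopf("spot_ids must be unique")
  if (anyDuplicated(gene_ids)) stopf("gene_ids must be unique")
  if (any(X < 0)) stopf("expression values must be non-negative")
  if (!normalized && any(abs(X - round(X)) > 1e-8)) {
    stopf("raw counts must be integral; pass normalized = TRUE for processed data")
  }
  if (!is.null(domain_labels) && length(domain_labels) != nrow(X)) {
    stopf("domain_labels length (%d) != number of spots (%d)",
          length(domain_labels), nrow(X))
  }
  dimnames(X) <- list(spot_ids, gene_ids)
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")
  structure(
    list(slice_id = slice_id, X = X, spot_ids = spot_ids, gene_ids = gene_ids,
         coords = coords,
         domain_labels = if (is.null(domain_labels)) NULL else as.character(domain_labels),
         normalized = normalized),
    class = "spatial_slice"
  )
}

#' @export
print.spatial_slice <- function(x, ...) {
  cat(sprintf("spatial_slice '%s': %d spots x %d genes (%s)%s\n",
              x$slice_id, nrow(x$X), ncol(x$X),
              if (x$normalized) "normalized" else "raw counts",
              if (is.null(x$domain_labels)) "" else ", with domain labels"))
  invisible(x)
}

#' Construct a single-cell reference object
#'
#' @param X_sc cell x gene matrix of counts (or normalized values).
#' @param cell_type_labels per-cell labels over at least two types.
#' @param cell_ids,gene_ids unique identifiers.
#' @param normalized logical flag as in [spatial_slice()].
#' @return An object of class `sc_reference`.
#' @export
sc_reference <- function(X_sc, cell_type_labels,
                         cell_ids = rownames(X_sc), gene_ids = colnames(X_sc),
                         normalized = FALSE) {
  X_sc <- as.matrix(X_sc)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(X_sc)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(X_sc)))
  cell_type_labels <- as.character(cell_type_labels)
  if (length(cell_type_labels) != nrow(X_sc)) {
    stopf("one label per cell required (%d labels, %d cells)",
          length(cell_type_labels), nrow(X_sc))
  }
  if (anyNA(cell_type_labels)) stopf("every cell must carry a cell-type label")
  if (length(unique(cell_type_labels)) < 2L) {
    stopf("reference must contain at least 2 cell types")
  }
  if (anyDuplicated(gene_ids)) stopf("gene_ids must be unique")
  dimnames(X_sc) <- list(cell_ids, gene_ids)
  structure(
    list(X_sc = X_sc, cell_ids = cell_ids, gene_ids = gene_ids,
         cell_type_labels = cell_type_labels, normalized = normalized),
    class = "sc_reference"
  )
}

#' @export
print.sc_reference <- function(x, ...) {
  cat(sprintf("sc_reference: %d cells x %d genes, %d cell types (%s)\n",
              nrow(x$X_sc), ncol(x$X_sc), length(unique(x$cell_type_labels)),
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

read_count_matrix <- function(counts_path) {
  if (grepl("\\.mtx$", counts_path)) {
    m <- as.matrix(Matrix::readMM(counts_path))
    dir <- dirname(counts_path)
    feat <- file.path(dir, "features.tsv")
    barc <- file.path(dir, "barcodes.tsv")
    if (!file.exists(feat) || !file.exists(barc)) {
      stopf("MatrixMarket input needs features.tsv and barcodes.tsv beside %s",
            counts_path)
    }
    genes <- utils::read.table(feat, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    spots <- utils::read.table(barc, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    # rows = spots, cols = genes in this package's dialect
    if (nrow(m) == length(genes) && ncol(m) == length(spots) &&
        length(genes) != length(spots)) {
      m <- t(m)  # tolerate the common genes-by-cells orientation
    }
    if (nrow(m) != length(spots) || ncol(m) != length(genes)) {
      stopf("matrix is %d x %d but sidecars name %d spots and %d genes",
            nrow(m), ncol(m), length(spots), length(genes))
    }
    dimnames(m) <- list(spots, genes)
    m
  } else {
    df <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                            row.names = 1L, check.names = FALSE)
    as.matrix(df)
  }
}

#' Load one spatial slice from disk
#'
#' Counts may be MatrixMarket (`.mtx` with `features.tsv`/`barcodes.tsv`
#' sidecars in the same directory) or a dense TSV (header row = gene ids,
#' first column = spot ids). Coordinates are a TSV with columns
#' `spot_id`, `x`, `y`; the coordinate file's spot order wins.
#'
#' @param counts_path path to the count matrix.
#' @param coords_path path to the coordinate TSV.
#' @param labels_path optional TSV with columns `id`, `label` for per-spot
#'   domain annotations.
#' @param slice_id slice name; defaults to the counts file stem.
#' @return A [spatial_slice()].
#' @export
load_slice <- function(counts_path, coords_path, labels_path = NULL,
                       slice_id = NULL) {
  m <- read_count_matrix(counts_path)
  co <- utils::read.table(coords_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% colnames(co))) {
    stopf("coords TSV must have columns spot_id, x, y")
  }
  missing <- setdiff(rownames(m), co$spot_id)
  if (length(missing)) {
    stopf("coords file lacks spot_id(s): %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  extra <- setdiff(co$spot_id, rownames(m))
  if (length(extra)) {
    stopf("coords file has spot_id(s) absent from the matrix: %s",
          paste(utils::head(extra, 5L), collapse = ", "))
  }
  m <- m[co$spot_id, , drop = FALSE]
  labels <- NULL
  if (!is.null(labels_path)) {
    lb <- utils::read.table(labels_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (!all(c("id", "label") %in% colnames(lb))) {
      stopf("labels TSV must have columns id, label")
    }
    idx <- match(co$spot_id, lb$id)
    if (anyNA(idx)) {
      stopf("labels file lacks spot_id(s): %s",
            paste(utils::head(co$spot_id[is.na(idx)], 5L), collapse = ", "))
    }
    labels <- lb$label[idx]
  }
  if (is.null(slice_id)) {
    slice_id <- sub("\\.(mtx|tsv)$", "", basename(counts_path))
  }
  spatial_slice(m, as.matrix(co[, c("x", "y")]), slice_id = slice_id,
                spot_ids = co$spot_id, domain_labels = labels)
}

#' Load a single-cell reference from disk
#'
#' @param counts_path count matrix (same dialects as [load_slice()]).
#' @param labels_path TSV with columns `id`, `label` giving each cell's type.
#' @return An [sc_reference()].
#' @export
load_reference <- function(counts_path, labels_path) {
  m <- read_count_matrix(counts_path)
  lb <- utils::read.table(labels_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% colnames(lb))) {
    stopf("labels TSV must have columns id, label")
  }
  idx <- match(rownames(m), lb$id)
  if (anyNA(idx)) {
    stopf("labels file lacks cell id(s): %s",
          paste(utils::head(rownames(m)[is.na(idx)], 5L), collapse = ", "))
  }
  sc_reference(m, lb$label[idx])
}

#' Write a count matrix in MatrixMarket form with sidecars
#'
#' @param X spot x gene matrix.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the `.mtx` file.
#' @return Invisibly, the `.mtx` path.
#' @export
write_matrix_mtx <- function(X, dir, prefix = "counts") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(prefix, ".mtx"))
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  path)
  utils::write.table(data.frame(g = colnames(X)), file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(b = rownames(X)), file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a slice's inputs (counts, coordinates, optional labels) to a directory
#'
#' Emits the exact dialects [load_slice()] reads.
#'
#' @param slice a [spatial_slice()].
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_slice <- function(slice, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_mtx(slice$X, dir, "counts")
  utils::write.table(
    data.frame(spot_id = slice$spot_ids,
               x = slice$coords[, 1L], y = slice$coords[, 2L]),
    file.path(dir, "coords.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(slice$domain_labels)) {
    utils::write.table(
      data.frame(id = slice$spot_ids, label = slice$domain_labels),
      file.path(dir, "labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Remove genes detected in too few spots
#'
#' Keeps genes with a nonzero count in at least `min_spots` spots; gene order
#' is preserved. Idempotent.
#'
#' @param slice a [spatial_slice()] holding raw counts.
#' @param min_spots minimum number of spots a gene must be detected in
#'   (default 3).
#' @return The filtered slice.
#' @export
filter_genes <- function(slice, min_spots = 3L) {
  keep <- colSums(slice$X > 0) >= min_spots
  if (!any(keep)) stopf("gene filtering removed all genes (min_spots = %d)", min_spots)
  slice$X <- slice$X[, keep, drop = FALSE]
  slice$gene_ids <- slice$gene_ids[keep]
  slice
}

log1p_normalize_matrix <- function(X, scale = 1e4) {
  tot <- rowSums(X)
  zero <- tot == 0
  if (any(zero)) {
    warnf("%d spot(s)/cell(s) have zero total count; left all-zero", sum(zero))
    tot[zero] <- 1
  }
  log1p(X / tot * scale)
}

#' Library-size normalize and log-transform a slice
#'
#' Each value v in a spot with total count T becomes `log(1 + 10000 * v / T)`.
#' Spots with zero total count are retained as all-zero rows (with a warning).
#'
#' @param slice a [spatial_slice()] with raw counts.
#' @param scale scale factor (default 10000).
#' @return The slice with normalized `X` and `normalized = TRUE`.
#' @export
normalize_log1p <- function(slice, scale = 1e4) {
  if (slice$normalized) stopf("slice is already normalized")
  slice$X <- log1p_normalize_matrix(slice$X, scale)
  slice$normalized <- TRUE
  slice
}

#' Library-size normalize and log-transform a reference
#'
#' @param ref an [sc_reference()] with raw counts.
#' @param scale scale factor (default 10000).
#' @return The normalized reference.
#' @export
normalize_reference <- function(ref, scale = 1e4) {
  if (ref$normalized) stopf("reference is already normalized")
  ref$X_sc <- log1p_normalize_matrix(ref$X_sc, scale)
  ref$normalized <- TRUE
  ref
}

#' Select highly variable genes by standardized variance
#'
#' Ranks genes by the variance of clipped, mean-variance-standardized raw
#' counts (the seurat_v3 convention): expected variance is obtained from a
#' loess fit of log10(variance) on log10(mean), counts are standardized to
#' `(x - mean) / expected sd` and clipped at `sqrt(N)`, and genes are ranked
#' by the variance of the clipped values. Ties break by input gene order.
#'
#' @param x a [spatial_slice()] or [sc_reference()] holding raw counts, or a
#'   plain observation x gene count matrix.
#' @param n_top number of genes to return.
#' @return Character vector of `n_top` gene ids, ranked.
#' @export
select_hvg <- function(x, n_top = 3000L) {
  X <- if (inherits(x, "spatial_slice")) x$X
       else if (inherits(x, "sc_reference")) x$X_sc
       else as.matrix(x)
  n <- nrow(X)
  genes <- colnames(X) %||% paste0("gene", seq_len(ncol(X)))
  if (n_top > ncol(X)) {
    warnf("n_top (%d) exceeds gene count (%d); returning all genes",
          n_top, ncol(X))
    n_top <- ncol(X)
  }
  mu <- colMeans(X)
  v <- apply(X, 2L, stats::var)
  notnull <- v > 0 & mu > 0
  est_var <- v
  if (sum(notnull) >= 10L) {
    fit <- stats::loess(log10(v[notnull]) ~ log10(mu[notnull]), span = 0.3)
    est_var[notnull] <- 10^fit$fitted
  }
  clip <- sqrt(n)
  std_var <- vapply(seq_len(ncol(X)), function(j) {
    if (!notnull[j]) return(0)
    z <- (X[, j] - mu[j]) / sqrt(est_var[j])
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    sum((z - mean(z))^2) / (n - 1)
  }, numeric(1))
  ord <- order(-std_var, seq_along(std_var))
  genes[ord[seq_len(n_top)]]
}

#' Restrict slices and reference to a common gene set
#'
#' All matrices are subset to `gene_set` in identical column order, so the
#' signature matrix and every slice share columns downstream.
#'
#' @param slices list of [spatial_slice()] objects.
#' @param ref an [sc_reference()].
#' @param gene_set character vector of gene ids; must be present in every
#'   input.
#' @return List with elements `slices` and `ref`.
#' @export
harmonize_genes <- function(slices, ref, gene_set) {
  universe <- Reduce(intersect, c(lapply(slices, `[[`, "gene_ids"),
                                  list(ref$gene_ids)))
  if (length(universe) == 0L) stopf("slices and reference share no genes")
  absent <- setdiff(gene_set, universe)
  if (length(absent)) {
    stopf("gene(s) not present in all inputs: %s",
          paste(utils::head(absent, 5L), collapse = ", "))
  }
  slices <- lapply(slices, function(s) {
    s$X <- s$X[, gene_set, drop = FALSE]
    s$gene_ids <- gene_set
    s
  })
  ref$X_sc <- ref$X_sc[, gene_set, drop = FALSE]
  ref$gene_ids <- gene_set
  list(slices = slices, ref = ref)
}
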