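# Evaluation metrics: adjusted Rand index and normalized mutual information
# for domain partitions, per-spot PCC/MSE for estimated proportions, and
# marker-gene-based proportion validation.

as_label_vector <- function(x) {
  if (inherits(x, "domain_labels")) x <- x$labels
  as.character(x)
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions, computed
#' from the contingency table:
#' `ARI = (RI - E[RI]) / (max RI - E[RI])`. Invariant to label renaming;
#' 1 for identical partitions, about 0 for independent ones (can be
#' negative).
#'
#' @param a,b label vectors of equal length (>= 2), or `domain_labels`.
#' @return Scalar ARI.
#' @export
ari <- function(a, b) {
  a <- as_label_vector(a); b <- as_label_vector(b)
  if (length(a) != length(b)) stopf("label vectors differ in length")
  if (length(a) < 2L) stopf("need at least 2 observations")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' `2 I(U; V) / (H(U) + H(V))` from the contingency table (natural logs);
#' 0 when either partition has a single class, 1 for identical partitions
#' with at least two classes.
#'
#' @param a,b label vectors of equal length (>= 2), or `domain_labels`.
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  a <- as_label_vector(a); b <- as_label_vector(b)
  if (length(a) != length(b)) stopf("label vectors differ in length")
  if (length(a) < 2L) stopf("need at least 2 observations")
  n <- length(a)
  tab <- table(a, b) / n
  pu <- rowSums(tab); pv <- colSums(tab)
  hu <- -sum(pu[pu > 0] * log(pu[pu > 0]))
  hv <- -sum(pv[pv > 0] * log(pv[pv > 0]))
  if (hu == 0 || hv == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / (pu[row(tab)[nz]] * pv[col(tab)[nz]])))
  2 * mi / (hu + hv)
}

#' Per-spot PCC and MSE of estimated proportions
#'
#' For each spot, the Pearson correlation and mean squared error between the
#' estimated and true K-vectors of cell-type proportions. Spots whose
#' estimated vector is constant have undefined PCC and are excluded from the
#' median with a warning.
#'
#' @param P_est,P_true `cell_type_representation`s (or plain matrices) over
#'   the same spots and type order.
#' @return List of class `metrics_report`: `pcc_per_spot`, `mse_per_spot`,
#'   `median_pcc`, `median_mse`.
#' @export
proportion_pcc_mse <- function(P_est, P_true) {
  E <- if (inherits(P_est, "cell_type_representation")) P_est$P else as.matrix(P_est)
  Tm <- if (inherits(P_true, "cell_type_representation")) P_true$P else as.matrix(P_true)
  if (!all(dim(E) == dim(Tm))) stopf("proportion matrices differ in shape")
  n <- nrow(E)
  pcc <- vapply(seq_len(n), function(i) {
    if (stats::sd(E[i, ]) == 0 || stats::sd(Tm[i, ]) == 0) return(NA_real_)
    stats::cor(E[i, ], Tm[i, ])
  }, numeric(1))
  mse <- rowMeans((E - Tm)^2)
  if (anyNA(pcc)) {
    warnf("%d spot(s) with constant proportion vector excluded from the PCC median",
          sum(is.na(pcc)))
  }
  structure(list(pcc_per_spot = pcc, mse_per_spot = mse,
                 median_pcc = stats::median(pcc, na.rm = TRUE),
                 median_mse = stats::median(mse)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: median PCC = %.3f, median MSE = %.4g (%d spots)\n",
              x$median_pcc, x$median_mse, length(x$mse_per_spot)))
  invisible(x)
}

#' Rank marker genes per cell type from the reference
#'
#' Genes are ranked per type by the mean difference of normalized expression
#' in that type versus all other cells (a log-fold-change on the log scale).
#'
#' @param ref normalized [sc_reference()].
#' @param n_markers markers per type (default 20; types with fewer rankable
#'   genes use all available, with a warning).
#' @return Named list of character vectors of gene ids.
#' @export
rank_markers <- function(ref, n_markers = 20L) {
  types <- sort(unique(ref$cell_type_labels))
  X <- ref$X_sc
  out <- lapply(types, function(k) {
    ink <- ref$cell_type_labels == k
    lfc <- colMeans(X[ink, , drop = FALSE]) - colMeans(X[!ink, , drop = FALSE])
    rankable <- which(lfc > 0)
    if (length(rankable) < n_markers) {
      warnf("type %s has only %d rankable marker genes", k, length(rankable))
    }
    ord <- order(-lfc, seq_along(lfc))
    ref$gene_ids[ord[seq_len(min(n_markers, max(length(rankable), 1L)))]]
  })
  names(out) <- types
  out
}

#' Marker-based validation of estimated proportions
#'
#' For each cell type, the Pearson correlation across spots between the mean
#' normalized expression of that type's top marker genes and the type's
#' column-normalized proportions (each type's proportions divided by their
#' sum over spots, so they sum to 1).
#'
#' @param P `cell_type_representation` for one slice.
#' @param slice the matching normalized [spatial_slice()].
#' @param ref normalized [sc_reference()] used to rank markers.
#' @param n_markers markers per type (default 20).
#' @return Named numeric vector of per-type PCCs.
#' @export
marker_validation <- function(P, slice, ref, n_markers = 20L) {
  if (!slice$normalized) stopf("slice must be normalized")
  markers <- rank_markers(ref, n_markers)
  Pm <- P$P
  csum <- colSums(Pm)
  csum[csum == 0] <- 1
  Pn <- sweep(Pm, 2L, csum, "/")     # each type sums to 1 across spots
  vapply(P$cell_type_names, function(k) {
    gs <- intersect(markers[[k]], slice$gene_ids)
    if (length(gs) == 0L) return(NA_real_)
    expr <- rowMeans(slice$X[, gs, drop = FALSE])
    if (stats::sd(expr) == 0 || stats::sd(Pn[, k]) == 0) return(NA_real_)
    stats::cor(expr, Pn[, k])
  }, numeric(1))
}
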