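# Synthetic benchmark generator: a labeled scRNA-seq reference with
# marker-structured negative-binomial counts, and grid slices whose spots
# mix reference cells according to domain-specific compositions, with a
# controllable multiplicative gene-wise batch effect per slice. Ground-truth
# per-spot proportions are the REALIZED draws, so deconvolution is scored
# against what is actually in each spot.

#' Simulation configuration
#'
#' @param n_types number of cell types K (>= 2).
#' @param n_genes number of genes D.
#' @param n_markers marker genes per type (disjoint sets; fold-change
#'   `fold_change` over baseline in that type).
#' @param cells_per_type reference cells simulated per type.
#' @param fold_change marker fold-change (default 5).
#' @param n_slices number of slices.
#' @param grid c(rows, cols) of the spot lattice per slice.
#' @param n_domains number of vertical-band domains.
#' @param mixing list (length `n_slices`) of `n_domains` x `n_types`
#'   row-stochastic matrices; a single matrix is recycled to all slices.
#'   Default: domain d is dominated (0.6) by type d with the rest uniform.
#' @param batch_scale per-slice gene-wise log-normal sdlog of the batch
#'   factor (first slice is the unscaled baseline).
#' @param cells_per_spot cells drawn per spot.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param baseline_shape,baseline_rate gamma parameters of per-gene baseline
#'   mean expression.
#' @param seed integer seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_types = 5L, n_genes = 2000L, n_markers = 40L,
                       cells_per_type = 500L, fold_change = 5,
                       n_slices = 3L, grid = c(15L, 15L), n_domains = 3L,
                       mixing = NULL, batch_scale = 0.2, cells_per_spot = 10L,
                       nb_dispersion = 0.5, baseline_shape = 0.3,
                       baseline_rate = 3, seed = 0L) {
  if (n_types < 2L) stopf("n_types must be >= 2")
  if (n_markers * n_types > n_genes) {
    stopf("marker sets (%d x %d) exceed the gene count (%d)",
          n_types, n_markers, n_genes)
  }
  if (is.null(mixing)) {
    base <- matrix(0.4 / (n_types - 1), n_domains, n_types)
    for (d in seq_len(n_domains)) base[d, 1 + (d - 1) %% n_types] <- 0.6
    mixing <- rep(list(base), n_slices)
  }
  if (is.matrix(mixing)) mixing <- rep(list(mixing), n_slices)
  if (length(mixing) != n_slices) stopf("one mixing matrix per slice required")
  for (m in mixing) {
    if (!all(dim(m) == c(n_domains, n_types))) {
      stopf("mixing matrices must be %d x %d", n_domains, n_types)
    }
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
      stopf("mixing rows must be non-negative and sum to 1")
    }
  }
  structure(list(n_types = n_types, n_genes = n_genes, n_markers = n_markers,
                 cells_per_type = cells_per_type, fold_change = fold_change,
                 n_slices = n_slices, grid = grid, n_domains = n_domains,
                 mixing = mixing, batch_scale = batch_scale,
                 cells_per_spot = cells_per_spot,
                 nb_dispersion = nb_dispersion,
                 baseline_shape = baseline_shape, baseline_rate = baseline_rate,
                 seed = seed),
            class = "sim_config")
}

#' Simulate the labeled single-cell reference
#'
#' Per-gene baseline means are gamma-distributed; each type's marker genes
#' get `fold_change` times the baseline; counts are negative-binomial with
#' fixed dispersion.
#'
#' @param cfg a [sim_config()].
#' @return An [sc_reference()] (raw counts) with attributes `"type_means"`
#'   (K x D expected counts) and `"marker_sets"` (per-type gene-id list).
#' @export
simulate_reference <- function(cfg) {
  with_seed(cfg$seed, {
    D <- cfg$n_genes; K <- cfg$n_types
    baseline <- stats::rgamma(D, shape = cfg$baseline_shape,
                              rate = cfg$baseline_rate)
    genes <- sprintf("gene%04d", seq_len(D))
    types <- paste0("type", seq_len(K))
    marker_sets <- split(seq_len(K * cfg$n_markers),
                         rep(seq_len(K), each = cfg$n_markers))
    means <- matrix(baseline, K, D, byrow = TRUE,
                    dimnames = list(types, genes))
    for (k in seq_len(K)) {
      means[k, marker_sets[[k]]] <- baseline[marker_sets[[k]]] * cfg$fold_change
    }
    size <- 1 / cfg$nb_dispersion
    n_cells <- K * cfg$cells_per_type
    labels <- rep(types, each = cfg$cells_per_type)
    X <- matrix(0L, n_cells, D, dimnames = list(
      sprintf("cell%05d", seq_len(n_cells)), genes))
    for (k in seq_len(K)) {
      rows <- which(labels == types[k])
      X[rows, ] <- matrix(
        stats::rnbinom(length(rows) * D, mu = rep(means[k, ], each = length(rows)),
                       size = size),
        length(rows), D)
    }
    ref <- sc_reference(X, labels)
    attr(ref, "type_means") <- means
    attr(ref, "marker_sets") <- lapply(marker_sets, function(ix) genes[ix])
    ref
  })
}

#' Simulate spatial slices from a reference
#'
#' Spots sit on a `grid` lattice split into vertical-band domains; each spot
#' sums the counts of `cells_per_spot` reference cells whose types are drawn
#' from the spot's domain mixing row. The recorded truth proportions are the
#' realized type fractions of the drawn cells. Slices beyond the first get a
#' gene-wise log-normal batch factor (sdlog `batch_scale`) applied before
#' rounding.
#'
#' @param ref [simulate_reference()] output (raw counts).
#' @param cfg the same [sim_config()].
#' @return List with `slices` (raw-count [spatial_slice()]s carrying
#'   ground-truth `domain_labels`), `truth_proportions` (per-slice
#'   `cell_type_representation`), `truth_domains` (per-slice `domain_labels`
#'   with source `"ground_truth"`).
#' @export
simulate_slices <- function(ref, cfg) {
  if (ncol(ref$X_sc) != cfg$n_genes) {
    stopf("reference gene universe does not match the configuration")
  }
  with_seed(cfg$seed + 1L, {
    types <- sort(unique(ref$cell_type_labels))
    K <- length(types)
    cells_by_type <- split(seq_len(nrow(ref$X_sc)),
                           factor(ref$cell_type_labels, levels = types))
    nr <- cfg$grid[1L]; ncg <- cfg$grid[2L]
    n_spots <- nr * ncg
    coords <- cbind(x = rep(seq_len(ncg), each = nr),
                    y = rep(seq_len(nr), times = ncg))
    band <- pmin(((coords[, "x"] - 1) * cfg$n_domains) %/% ncg + 1,
                 cfg$n_domains)
    slices <- list(); truth_p <- list(); truth_d <- list()
    for (t in seq_len(cfg$n_slices)) {
      mix <- cfg$mixing[[t]]
      batch <- if (t == 1L || cfg$batch_scale == 0) {
        rep(1, cfg$n_genes)
      } else {
        stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = cfg$batch_scale)
      }
      X <- matrix(0, n_spots, cfg$n_genes)
      Ptrue <- matrix(0, n_spots, K, dimnames = list(NULL, types))
      for (i in seq_len(n_spots)) {
        tv <- sample.int(K, cfg$cells_per_spot, replace = TRUE,
                         prob = mix[band[i], ])
        cells <- vapply(tv, function(k) {
          ix <- cells_by_type[[k]]
          ix[sample.int(length(ix), 1L)]
        }, integer(1))
        X[i, ] <- colSums(ref$X_sc[cells, , drop = FALSE])
        tb <- tabulate(tv, nbins = K)
        Ptrue[i, ] <- tb / sum(tb)
      }
      X <- round(sweep(X, 2L, batch, "*"))
      sid <- paste0("S", t)
      spot_ids <- sprintf("%s_spot%03d", sid, seq_len(n_spots))
      rownames(X) <- spot_ids
      colnames(X) <- ref$gene_ids
      rownames(Ptrue) <- spot_ids
      slices[[t]] <- spatial_slice(X, coords, slice_id = sid,
                                   domain_labels = paste0("D", band))
      truth_p[[t]] <- new_ctr(Ptrue, types, sid)
      truth_d[[t]] <- structure(
        list(labels = band, slice = factor(rep(sid, n_spots)),
             source = "ground_truth"),
        class = "domain_labels")
    }
    names(slices) <- names(truth_p) <- names(truth_d) <-
      paste0("S", seq_len(cfg$n_slices))
    list(slices = slices, truth_proportions = truth_p, truth_domains = truth_d)
  })
}

#' Three-slice benchmark preset
#'
#' The standard study conditions used throughout the package's tests:
#' K = 5 cell types, three 15 x 15 slices with three vertical-band domains,
#' S1 and S2 sharing domain-wise compositions, S3 diverging in exactly one
#' domain's composition row, 10 cells per spot, and a mild (sdlog 0.2)
#' gene-wise batch effect between slices.
#'
#' @param seed integer seed.
#' @param ... [sim_config()] overrides (e.g. `batch_scale`, `n_slices`,
#'   `grid`).
#' @return List with `ref`, `slices`, `truth_proportions`, `truth_domains`,
#'   `config`.
#' @export
simulate_benchmark <- function(seed = 0L, ...) {
  shared <- rbind(
    c(0.60, 0.10, 0.10, 0.10, 0.10),
    c(0.10, 0.60, 0.10, 0.10, 0.10),
    c(0.10, 0.10, 0.60, 0.10, 0.10)
  )
  s3 <- shared
  s3[3L, ] <- c(0.05, 0.05, 0.05, 0.60, 0.25)  # the divergent domain
  dots <- list(...)
  n_slices <- dots$n_slices %||% 3L
  mixing <- dots$mixing %||% c(rep(list(shared), min(2L, n_slices)),
                               rep(list(s3), max(0L, n_slices - 2L)))[seq_len(n_slices)]
  dots$mixing <- NULL
  args <- utils::modifyList(
    list(n_types = 5L, n_slices = n_slices, grid = c(15L, 15L),
         n_domains = 3L, batch_scale = 0.2, cells_per_spot = 10L,
         seed = seed),
    dots)
  args$mixing <- mixing
  cfg <- do.call(sim_config, args)
  ref <- simulate_reference(cfg)
  sim <- simulate_slices(ref, cfg)
  c(list(ref = ref, config = cfg), sim)
}

#' Write a simulated benchmark to disk in the package's input dialects
#'
#' Each slice gets a directory with `counts.mtx` (+ sidecars), `coords.tsv`,
#' `labels.tsv`, `truth_proportions.tsv` and `truth_domains.tsv`; the
#' reference goes under `reference/`.
#'
#' @param sim [simulate_benchmark()] output.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$slices)) {
    sd <- file.path(dir, nm)
    write_slice(sim$slices[[nm]], sd)
    tp <- sim$truth_proportions[[nm]]
    utils::write.table(
      data.frame(spot_id = sim$slices[[nm]]$spot_ids, tp$P,
                 check.names = FALSE),
      file.path(sd, "truth_proportions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(id = sim$slices[[nm]]$spot_ids,
                 label = sim$truth_domains[[nm]]$labels),
      file.path(sd, "truth_domains.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rd <- file.path(dir, "reference")
  write_matrix_mtx(sim$ref$X_sc, rd, "counts")
  utils::write.table(
    data.frame(id = sim$ref$cell_ids, label = sim$ref$cell_type_labels),
    file.path(rd, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
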