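# End-to-end orchestration: preprocess -> graphs -> encoder -> reference
# embedding -> deconvolution -> alignment -> domain calling (unsupervised
# GMM or semi-supervised label transfer), with seeded reproducibility, a
# config schema with unknown-key rejection, and on-disk output artifacts
# plus a manifest.

#' Default pipeline configuration
#'
#' Nested named list covering every stage; [run_pipeline()] validates user
#' overrides against this schema and rejects unknown keys.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    mode = "unsupervised",            # or "semi"
    seed = 0L,
    output_dir = NULL,
    io = list(min_spots = 3L, n_top = 3000L, gene_list = NULL),
    graphs = list(k_spatial = 6L, k_snn = 20L, n_pcs = 40L),
    encoder = list(latent_dim = 50L, hidden = 256L, alpha = 1.0, beta = 0.1,
                   epochs = 400L, lr = 1e-3),
    deconv = list(lambda = 1, gamma = 1, epochs = 300L, lr = 1e-3,
                  hidden = 128L, n_domains = 3L),
    align = list(enabled = TRUE, delta = 1.0, k_anchor = 5L, lr = 1e-4,
                 space = "proportions", epochs = 100L, anchor_refresh = 50L,
                 refit_epochs = 150L, refit_lr = 1e-3,
                 freeze_encoder = FALSE),
    semi = list(labeled_slice = 1L, epochs = 300L, hidden = c(512L, 512L))
  )
}

validate_config <- function(config, schema = default_config(), path = "") {
  if (!is.list(config)) stopf("config%s must be a list", path)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    stopf("unknown config key(s)%s: %s", path, paste(unknown, collapse = ", "))
  }
  for (nm in names(config)) {
    if (is.list(schema[[nm]]) && !is.null(names(schema[[nm]]))) {
      validate_config(config[[nm]] %||% list(), schema[[nm]],
                      paste0(path, "$", nm))
    }
  }
  merged <- utils::modifyList(schema, config)
  if (path == "" && !merged$mode %in% c("unsupervised", "semi")) {
    stopf("mode must be 'unsupervised' or 'semi'")
  }
  merged
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full multi-slice integration pipeline
#'
#' Preprocesses the inputs (gene filtering, library-size log-normalization,
#' highly-variable-gene selection, gene harmonization), builds the spatial
#' and SNN graphs, trains the shared graph-contrastive encoder, deconvolves
#' spots against the reference, aligns slices via anchor MMD (when more than
#' one slice), and calls spatial domains either by Gaussian mixture
#' clustering of the pooled proportions (`mode = "unsupervised"`) or by
#' training the domain classifier on one annotated slice and predicting the
#' rest (`mode = "semi"`).
#'
#' @param slices list of raw-count [spatial_slice()]s (for `mode = "semi"`,
#'   the labeled slice must carry `domain_labels`).
#' @param ref raw-count [sc_reference()].
#' @param config nested overrides of [default_config()]; unknown keys are
#'   rejected.
#' @return Bundle list: `slices` (normalized), `graphs`, `encoder_fit`,
#'   `proportions` (and `proportions_prealign`), `embeddings`, `domains`
#'   (`domain_labels` over the pooled spots), `denoised` (per-slice
#'   matrices), `signatures`, `anchors`, `mmd_history`, `manifest`, plus
#'   `semi_fit` in semi mode. If `config$output_dir` is
#'   set, per-slice `denoised.mtx`, `embeddings.tsv`, `domains.tsv`,
#'   `proportions.tsv` and a `manifest.json` are written there.
#' @export
run_pipeline <- function(slices, ref, config = list()) {
  cfg <- validate_config(config)
  if (inherits(slices, "spatial_slice")) slices <- list(slices)
  seed <- as.integer(cfg$seed) %% 1000000L

  if (cfg$mode == "semi") {
    ls <- cfg$semi$labeled_slice
    if (ls > length(slices) || is.null(slices[[ls]]$domain_labels)) {
      stopf("mode 'semi' needs domain_labels on slice %d", ls)
    }
  }

  # ---- preprocessing
  pp <- stage("preprocess", {
    slices <- lapply(slices, filter_genes, min_spots = cfg$io$min_spots)
    gene_universe <- Reduce(intersect, c(lapply(slices, `[[`, "gene_ids"),
                                         list(ref$gene_ids)))
    if (length(gene_universe) == 0L) stopf("slices and reference share no genes")
    gene_set <- if (!is.null(cfg$io$gene_list)) {
      intersect(cfg$io$gene_list, gene_universe)
    } else {
      pooled <- do.call(rbind, lapply(slices, function(s)
        s$X[, gene_universe, drop = FALSE]))
      suppressWarnings(select_hvg(pooled, n_top = cfg$io$n_top))
    }
    slices <- suppressWarnings(lapply(slices, normalize_log1p))
    refn <- suppressWarnings(normalize_reference(ref))
    harmonize_genes(slices, refn, gene_set)
  })
  slices <- pp$slices
  refn <- pp$ref

  graphs <- stage("graphs", lapply(slices, function(s)
    build_spatial_graph(s$coords, k = cfg$graphs$k_spatial)))
  snn <- stage("graphs", build_snn_graph(refn$X_sc, k = cfg$graphs$k_snn,
                                         n_pcs = cfg$graphs$n_pcs))

  enc <- stage("train_encoder", train_encoder(
    slices, graphs,
    config = c(cfg$encoder, list(seed = seed))))

  dec <- stage("deconvolve", deconvolve(
    slices, graphs, refn, snn, enc$params,
    config = c(cfg$deconv[setdiff(names(cfg$deconv), "n_domains")],
               list(seed = seed))))

  params <- enc$params
  proportions <- dec$proportions
  proportions_prealign <- dec$proportions
  embeddings <- dec$embeddings
  clf <- dec$clf
  anchors <- NULL
  mmd_history <- NULL
  if (cfg$align$enabled && length(slices) >= 2L) {
    al <- stage("align_slices", align_slices(
      slices, graphs, refn, snn, enc$params, dec$clf,
      config = c(cfg$align[setdiff(names(cfg$align), "enabled")],
                 list(alpha = cfg$encoder$alpha, beta = cfg$encoder$beta,
                      lambda = cfg$deconv$lambda, gamma = cfg$deconv$gamma,
                      seed = seed))))
    params <- al$params
    proportions <- al$proportions
    embeddings <- al$embeddings
    clf <- al$clf
    anchors <- al$anchors
    mmd_history <- al$mmd_history
  }

  denoised <- stage("decode", mapply(function(e, g) {
    decode_graph(e$Z, g, params)
  }, embeddings, graphs, SIMPLIFY = FALSE))
  for (t in seq_along(denoised)) {
    dimnames(denoised[[t]]) <- dimnames(slices[[t]]$X)
  }

  semi_fit <- NULL
  domains <- if (cfg$mode == "semi") {
    ls <- cfg$semi$labeled_slice
    semi_fit <- stage("train_semi_classifier", train_semi_classifier(
      embeddings[[ls]]$Z, slices[[ls]]$domain_labels,
      config = list(hidden = cfg$semi$hidden, epochs = cfg$semi$epochs,
                    seed = seed)))
    pred <- lapply(seq_along(slices), function(t) {
      if (t == ls) slices[[t]]$domain_labels
      else predict_domains(semi_fit, embeddings[[t]]$Z)$labels
    })
    structure(list(
      labels = unlist(pred),
      slice = factor(rep(vapply(slices, `[[`, character(1), "slice_id"),
                         vapply(slices, function(s) nrow(s$X), integer(1)))),
      source = "semi_classifier"), class = "domain_labels")
  } else {
    stage("cluster_domains",
          cluster_domains(proportions, cfg$deconv$n_domains, seed = seed))
  }

  manifest <- list(
    package = "spotweave",
    version = as.character(utils::packageVersion("spotweave")),
    seed = cfg$seed,
    mode = cfg$mode,
    n_slices = length(slices),
    n_genes = ncol(slices[[1L]]$X),
    config_hash = digest::digest(cfg),
    config = cfg
  )

  bundle <- list(slices = slices, graphs = graphs, encoder_fit = enc,
                 params = params, proportions = proportions,
                 proportions_prealign = proportions_prealign,
                 embeddings = embeddings, clf = clf, domains = domains,
                 denoised = denoised, signatures = dec$signatures,
                 anchors = anchors, mmd_history = mmd_history,
                 semi_fit = semi_fit, manifest = manifest)
  if (!is.null(cfg$output_dir)) write_bundle(bundle, cfg$output_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(bundle$slices, `[[`, character(1), "slice_id")
  off <- 0L
  for (t in seq_along(bundle$slices)) {
    s <- bundle$slices[[t]]
    sd <- file.path(dir, s$slice_id)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    write_matrix_mtx(bundle$denoised[[t]], sd, "denoised")
    emb <- data.frame(spot_id = s$spot_ids, bundle$embeddings[[t]]$Z)
    colnames(emb) <- c("spot_id", paste0("dim", seq_len(ncol(emb) - 1L)))
    utils::write.table(emb, file.path(sd, "embeddings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n <- nrow(s$X)
    utils::write.table(
      data.frame(spot_id = s$spot_ids,
                 domain = bundle$domains$labels[off + seq_len(n)]),
      file.path(sd, "domains.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(spot_id = s$spot_ids, bundle$proportions[[t]]$P,
                 check.names = FALSE),
      file.path(sd, "proportions.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    off <- off + n
  }
  sig <- bundle$signatures
  utils::write.table(
    data.frame(cell_type = sig$cell_type_names, sig$B, check.names = FALSE),
    file.path(dir, "signatures.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' Evaluate pipeline output against ground truth
#'
#' @param bundle [run_pipeline()] output.
#' @param truth_domains list of per-slice ground-truth `domain_labels`.
#' @param truth_proportions list of per-slice true
#'   `cell_type_representation`s.
#' @return List with pooled and per-slice `ari`/`nmi` and per-slice
#'   proportion `metrics_report`s.
#' @export
evaluate_bundle <- function(bundle, truth_domains = NULL,
                            truth_proportions = NULL) {
  out <- list()
  if (!is.null(truth_domains)) {
    truth_all <- unlist(lapply(truth_domains, `[[`, "labels"))
    out$ari <- ari(bundle$domains$labels, truth_all)
    out$nmi <- nmi(bundle$domains$labels, truth_all)
    ids <- levels(bundle$domains$slice)
    out$ari_per_slice <- vapply(seq_along(truth_domains), function(t) {
      sel <- bundle$domains$slice == ids[t]
      ari(bundle$domains$labels[sel], truth_domains[[t]]$labels)
    }, numeric(1))
    names(out$ari_per_slice) <- ids
  }
  if (!is.null(truth_proportions)) {
    out$proportions <- mapply(function(est, tr) {
      proportion_pcc_mse(est, align_type_columns(est, tr))
    }, bundle$proportions, truth_proportions, SIMPLIFY = FALSE)
  }
  out
}

# Reorder the truth's type columns to the estimate's type order.
align_type_columns <- function(est, truth) {
  if (!inherits(truth, "cell_type_representation")) return(truth)
  ix <- match(est$cell_type_names, truth$cell_type_names)
  if (anyNA(ix)) stopf("cell types of estimate and truth do not match")
  new_ctr(truth$P[, ix, drop = FALSE], est$cell_type_names, truth$slice_id)
}
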