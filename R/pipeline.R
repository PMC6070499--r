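# Orchestration of the full analysis: resolved config, the
# outlier-sensitive pass, the robust pass, and the two-sample integration,
# each runnable programmatically or through the thin CLI wrapper in
# inst/cli/ctcseek.R.

PIPELINE_DEFAULTS <- list(
  scale_factor = 1e4,   # log-normalization target library size
  min_genes = 200L,     # strict per-cell detected-gene QC bound
  min_cells = 5L,       # robust-pass gene filter (outlier pass uses 0)
  n_bins = 30L,         # HVG mean-expression bins
  z_cutoff = 1,         # within-bin dispersion z cutoff
  min_mean = NULL,      # HVG lower mean bound; NULL = none (outlier pass)
  cap = 10,             # robust-pass scaling cap (outlier pass: uncapped)
  n_pcs = 20L,
  n_pcs_test = 5L,      # PCs scanned by the outlier caller
  z_threshold = 30,     # robust-z flag threshold
  k = 30L,              # kNN neighbors
  resolution = 0.8,     # Louvain resolution
  perplexity = 30,      # tSNE perplexity
  n_cv = 20L,           # canonical vectors for integration
  n_top_dispersion = 2000L,
  n_perm = 1000L,       # GSEA permutations
  weight = 1,           # GSEA hit-increment exponent
  seed = 1L
)

#' Resolved pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults; unknown keys
#' are rejected. The resolved config is persisted verbatim alongside any
#' outputs a pipeline stage writes, and its fingerprint goes into every
#' output TSV header.
#'
#' @param ... Overrides of the defaults (see `ctcseek:::PIPELINE_DEFAULTS`).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("pipeline_config: all arguments must be named")
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("pipeline_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- PIPELINE_DEFAULTS
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

persist_config <- function(config, out_dir) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s=%s", k, if (is.null(v)) "none"
            else paste(format(v, digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, file.path(out_dir, "config.txt"))
}

#' Simulate a dataset and write it as a fixture directory
#'
#' Wraps [generate_dataset()] + [write_dataset()]: writes `matrix.mtx`,
#' `genes.tsv`, `barcodes.tsv`, `truth.tsv` and `sets.gmt`.
#'
#' @param sim_cfg A [sim_config()].
#' @param out_dir Output directory; refuses to overwrite a non-empty
#'   directory unless `force = TRUE`.
#' @param force Overwrite.
#' @return `out_dir`, invisibly.
#' @export
simulate_to_dir <- function(sim_cfg, out_dir, force = FALSE) {
  sim <- generate_dataset(sim_cfg)
  write_dataset(sim, out_dir, force = force)
}

#' Run the outlier-sensitive pass end to end
#'
#' QC -> cell filter -> log-normalization -> covariate regression ->
#' uncapped scaling -> HVG selection with no lower mean bound -> PCA on the
#' HVGs -> robust-z outlier calling; for flagged cells, PC-loading report,
#' per-cell residual DE scores, and (when gene sets are given) preranked
#' GSEA per flagged cell. Zero flagged cells is a valid outcome: the result
#' carries `n_ctcs = 0` and a "no candidate CTCs" note, mirroring a
#' tumor-free sample.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param gene_sets Optional named list of gene sets for GSEA.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every intermediate table
#'   is written as headered TSV plus the resolved config.
#' @return List of class `outlier_pass`: `qc`, `hvg`, `pca`, `calls`,
#'   `flagged` (barcodes), `n_ctcs`, `loading_report`, `de_scores` (list
#'   per flagged cell plus `"pooled"`), `gsea` (list per flagged cell),
#'   `lognorm`, `scaled`, `note`.
#' @export
run_outlier_pass <- function(counts, gene_sets = NULL,
                             config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  qc0 <- compute_qc(counts)
  counts <- filter_cells(counts, qc0, min_genes = config$min_genes)
  # all genes kept regardless of how few cells express them
  counts <- filter_genes(counts, min_cells = 0L)
  qc <- qc0[colnames(counts), ]
  lognorm <- lognormalize(counts, scale_factor = config$scale_factor)
  residual <- regress_covariates(lognorm, qc)
  scaled <- scale_genes(residual, cap = NULL)   # no upper bound
  hvg <- select_hvg(lognorm, n_bins = config$n_bins,
                    z_cutoff = config$z_cutoff, min_mean = NULL)
  hvg_genes <- hvg$gene[hvg$selected]
  n_pcs <- min(config$n_pcs, length(hvg_genes), ncol(scaled))
  pca <- run_pca(scaled, hvg_genes = hvg_genes, n_pcs = n_pcs)
  calls <- call_outliers(pca, n_pcs_test = config$n_pcs_test,
                         z_threshold = config$z_threshold)
  flagged <- calls$barcode[calls$flagged]

  res <- list(qc = qc, hvg = hvg, pca = pca, calls = calls,
              flagged = flagged, n_ctcs = length(flagged),
              lognorm = lognorm, scaled = scaled, config = config)
  if (length(flagged)) {
    res$loading_report <- loading_report(pca, pc = 1L, top_n = 50L,
                                         flagged = flagged)
    de <- lapply(flagged, function(bc) residual_de_score(scaled, bc))
    names(de) <- flagged
    de$pooled <- residual_de_score(scaled, flagged)
    res$de_scores <- de
    if (!is.null(gene_sets)) {
      res$gsea <- lapply(de[flagged], function(tab) {
        scores <- stats::setNames(tab$score, tab$gene)
        preranked_gsea(scores, gene_sets, weight = config$weight,
                       n_perm = config$n_perm, seed = config$seed)
      })
    }
    res$note <- sprintf("%d candidate CTC(s)", length(flagged))
  } else {
    res$note <- "no candidate CTCs"
  }
  class(res) <- "outlier_pass"
  if (!is.null(out_dir)) write_outlier_pass(res, out_dir)
  res
}

write_outlier_pass <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  persist_config(cfg, out_dir)
  write_result_tsv(res$qc, file.path(out_dir, "qc.tsv"), "compute_qc", cfg)
  write_result_tsv(res$hvg, file.path(out_dir, "hvg.tsv"), "select_hvg", cfg)
  emb <- data.frame(barcode = rownames(res$pca$embeddings),
                    res$pca$embeddings, stringsAsFactors = FALSE)
  write_result_tsv(emb, file.path(out_dir, "pca_embeddings.tsv"),
                   "run_pca", cfg)
  write_result_tsv(res$calls, file.path(out_dir, "outlier_calls.tsv"),
                   "call_outliers", cfg)
  if (res$n_ctcs > 0) {
    write_result_tsv(res$loading_report,
                     file.path(out_dir, "pc1_loadings.tsv"),
                     "loading_report", cfg)
    write_result_tsv(res$de_scores$pooled,
                     file.path(out_dir, "de_scores_pooled.tsv"),
                     "residual_de_score", cfg)
    if (!is.null(res$gsea)) {
      for (bc in names(res$gsea))
        write_result_tsv(res$gsea[[bc]],
                         file.path(out_dir, paste0("gsea_", bc, ".tsv")),
                         "preranked_gsea", cfg)
    }
  } else {
    writeLines("no candidate CTCs", file.path(out_dir, "no_ctcs.txt"))
  }
  invisible(out_dir)
}

#' Run the robust pass on the blood compartment
#'
#' Gene filter (drop genes in < `min_cells` cells) -> log-normalization ->
#' covariate regression -> capped scaling -> PCA on all retained genes ->
#' kNN/Jaccard graph -> Louvain clustering -> supervised CTC labeling ->
#' tSNE -> AUC and hurdle-LRT markers per cluster (markers are computed on
#' non-CTC cells only).
#'
#' @param counts Sparse genes x cells count matrix.
#' @param outlier_calls Optional [call_outliers()] table (or flagged
#'   barcode vector) for supervised labeling.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param run_tsne Set `FALSE` to skip the visualization embedding.
#' @param compute_markers Set `FALSE` to stop after labeling (skips the AUC
#'   and LRT marker tables).
#' @return List of class `robust_pass`: `qc`, `pca`, `graph`, `clusters`,
#'   `labels`, `tsne`, `markers_auc`, `markers_lrt`, `lognorm`.
#' @export
run_robust_pass <- function(counts, outlier_calls = NULL,
                            config = pipeline_config(), out_dir = NULL,
                            run_tsne = TRUE, compute_markers = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  qc0 <- compute_qc(counts)
  counts <- filter_cells(counts, qc0, min_genes = config$min_genes)
  counts <- filter_genes(counts, min_cells = config$min_cells)
  qc <- qc0[colnames(counts), ]
  lognorm <- lognormalize(counts, scale_factor = config$scale_factor)
  residual <- regress_covariates(lognorm, qc)
  scaled <- scale_genes(residual, cap = config$cap)
  n_pcs <- min(config$n_pcs, nrow(scaled), ncol(scaled))
  pca <- run_pca(scaled, hvg_genes = NULL, n_pcs = n_pcs)
  k <- min(config$k, ncol(counts) - 1L)
  graph <- knn_graph(pca$embeddings, k = k)
  clusters <- modularity_cluster(graph, resolution = config$resolution,
                                 seed = config$seed)
  labels <- supervised_label(clusters, if (is.null(outlier_calls))
    character(0) else outlier_calls)
  tsne <- NULL
  if (run_tsne && nrow(pca$embeddings) - 1 > 3 * config$perplexity)
    tsne <- tsne_embed(pca$embeddings, perplexity = config$perplexity,
                       seed = config$seed)

  blood <- labels$barcode[labels$label != "CTC"]
  blood <- intersect(blood, colnames(lognorm))
  lab_blood <- labels$label[match(blood, labels$barcode)]
  markers_auc <- NULL
  markers_lrt <- NULL
  if (compute_markers && length(unique(lab_blood)) >= 2) {
    ln_blood <- lognorm[, blood, drop = FALSE]
    markers_auc <- auc_markers(ln_blood, lab_blood)
    lrt <- lapply(unique(lab_blood), function(cl) {
      tab <- bimod_lrt(ln_blood, which(lab_blood == cl),
                       which(lab_blood != cl))
      tab$cluster <- cl
      tab
    })
    markers_lrt <- do.call(rbind, lrt)
  }
  res <- list(qc = qc, pca = pca, graph = graph, clusters = clusters,
              labels = labels, tsne = tsne, markers_auc = markers_auc,
              markers_lrt = markers_lrt, lognorm = lognorm, config = config)
  class(res) <- "robust_pass"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    persist_config(config, out_dir)
    write_result_tsv(res$labels, file.path(out_dir, "cluster_labels.tsv"),
                     "supervised_label", config)
    if (!is.null(tsne))
      write_result_tsv(data.frame(barcode = rownames(tsne), tsne),
                       file.path(out_dir, "tsne.tsv"), "tsne_embed", config)
    if (!is.null(markers_auc))
      write_result_tsv(markers_auc, file.path(out_dir, "markers_auc.tsv"),
                       "auc_markers", config)
    if (!is.null(markers_lrt))
      write_result_tsv(markers_lrt, file.path(out_dir, "markers_lrt.tsv"),
                       "bimod_lrt", config)
  }
  res
}

#' Combined two-sample analysis via CCA alignment
#'
#' Union of per-dataset top-dispersion genes -> CCA (`n_cv` canonical
#' vectors) -> per-component quantile alignment -> joint kNN/Louvain
#' clustering on the aligned embeddings -> AUC + hurdle-LRT markers on the
#' combined log-normalized data.
#'
#' @param counts_1,counts_2 Sparse genes x cells count matrices sharing a
#'   gene namespace.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List of class `integration`: `genes`, `cca`, `clusters`,
#'   `labels` (with dataset of origin), `markers_auc`, `markers_lrt`.
#' @export
run_integration <- function(counts_1, counts_2,
                            config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  prep <- function(counts) {
    qc0 <- compute_qc(counts)
    counts <- filter_cells(counts, qc0, min_genes = config$min_genes)
    counts <- filter_genes(counts, min_cells = config$min_cells)
    lognormalize(counts, scale_factor = config$scale_factor)
  }
  ln1 <- prep(counts_1)
  ln2 <- prep(counts_2)
  genes <- union_top_dispersion(ln1, ln2, n_top = config$n_top_dispersion)
  n_cv <- min(config$n_cv, ncol(ln1), ncol(ln2))
  cca <- run_cca(ln1, ln2, genes, n_cv = n_cv, cap = config$cap)
  emb <- cca$aligned_embeddings
  k <- min(config$k, nrow(emb) - 1L)
  graph <- knn_graph(emb, k = k)
  clusters <- modularity_cluster(graph, resolution = config$resolution,
                                 seed = config$seed)
  clusters$dataset <- attr(emb, "dataset")

  joint <- cbind(ln1[genes, , drop = FALSE], ln2[genes, , drop = FALSE])
  markers_auc <- NULL
  markers_lrt <- NULL
  if (nlevels(clusters$cluster) >= 2) {
    lab <- as.character(clusters$cluster)
    markers_auc <- auc_markers(joint, lab)
    lrt <- lapply(unique(lab), function(cl) {
      tab <- bimod_lrt(joint, which(lab == cl), which(lab != cl))
      tab$cluster <- cl
      tab
    })
    markers_lrt <- do.call(rbind, lrt)
  }
  res <- list(genes = genes, cca = cca, clusters = clusters,
              markers_auc = markers_auc, markers_lrt = markers_lrt,
              config = config)
  class(res) <- "integration"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    persist_config(config, out_dir)
    write_result_tsv(clusters, file.path(out_dir, "joint_clusters.tsv"),
                     "run_integration", config)
    emb_df <- data.frame(barcode = rownames(emb),
                         dataset = attr(emb, "dataset"), emb,
                         stringsAsFactors = FALSE)
    write_result_tsv(emb_df, file.path(out_dir, "cca_aligned.tsv"),
                     "run_cca", config)
    if (!is.null(markers_auc))
      write_result_tsv(markers_auc, file.path(out_dir, "markers_auc.tsv"),
                       "auc_markers", config)
  }
  res
}
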