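# The outlier-sensitive pass: PCA on uncapped-scaled HVG expression,
# automated robust-z outlier (candidate-CTC) calling, PC-loading reports,
# per-cell residual DE scores, and the top-expressed-gene overlap statistic.

#' PCA on scaled expression, cells as observations
#'
#' Exact SVD-based PCA of the gene-restricted scaled matrix. Deterministic
#' up to component sign; the sign is fixed so each loading column's
#' largest-magnitude entry is positive. For large matrices with few
#' requested components a truncated SVD (irlba, internally seeded) is used;
#' the full decomposition otherwise.
#'
#' @param scaled Genes x cells matrix from [scale_genes()].
#' @param hvg_genes Genes to restrict to (default: all rows).
#' @param n_pcs Number of components.
#' @return List of class `pca_model`: `embeddings` (cells x n_pcs),
#'   `loadings` (genes x n_pcs, unit columns), `explained_variance`
#'   (per-PC, non-increasing), `total_variance`.
#' @export
run_pca <- function(scaled, hvg_genes = NULL, n_pcs = 20L) {
  if (!is.null(hvg_genes)) {
    missing <- setdiff(hvg_genes, rownames(scaled))
    if (length(missing))
      stop("run_pca: genes absent from matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    scaled <- scaled[hvg_genes, , drop = FALSE]
  }
  X <- t(as.matrix(scaled))                      # cells x genes
  n <- nrow(X)
  if (n_pcs > min(dim(X)))
    stop("run_pca: n_pcs exceeds min(#genes, #cells)")
  # rows of `scaled` are centered, so no further centering is needed
  big <- min(dim(X)) > 600 && n_pcs <= min(dim(X)) %/% 4
  if (big) {
    sv <- with_seed_(1L, irlba::irlba(X, nv = n_pcs, nu = n_pcs))
    d <- sv$d
  } else {
    sv <- svd(X)
    d <- sv$d[seq_len(min(length(sv$d), n_pcs))]
  }
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d[1], 0)
  rank <- sum(sv$d > tol)
  k <- min(n_pcs, length(d))
  if (n_pcs > rank) {
    warning("run_pca: n_pcs = ", n_pcs, " exceeds matrix rank ", rank,
            "; truncating")
    k <- max(rank, 1L)
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  d <- d[seq_len(k)]
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  emb <- U * rep(d, each = n)
  rownames(emb) <- colnames(scaled)
  colnames(emb) <- paste0("PC", seq_len(k))
  rownames(V) <- rownames(scaled)
  colnames(V) <- colnames(emb)
  total_var <- sum(scaled^2) / (n - 1)
  out <- list(embeddings = emb, loadings = V,
              explained_variance = d^2 / (n - 1),
              total_variance = total_var)
  class(out) <- "pca_model"
  out
}

#' Call outlier cells (candidate CTCs) in PC space
#'
#' Per tested PC, each cell's robust z is `|coord - median| / (1.4826 *
#' MAD)` over all cells; a cell is flagged when its maximum robust z across
#' the tested PCs reaches `z_threshold`. PCs with zero MAD are skipped with
#' a warning. This automates the visual identification of cells sitting far
#' from every clonal blood population in PCA space.
#'
#' @param pca A `pca_model`.
#' @param n_pcs_test Number of leading PCs to test.
#' @param z_threshold Robust-z flag threshold. In mixed-population blood the
#'   bulk robust-z tail reaches ~10-15 (cluster structure bleeds into the PC
#'   coordinate distributions, and UMI noise is heavier-tailed than
#'   Gaussian), while genuine rare-cell outliers sit several hundred MADs
#'   out; the default 30 is an order of magnitude below the latter and
#'   safely above the former.
#' @return Data frame per cell: `barcode`, `outlier_score`, `driving_pc`,
#'   `flagged`, sorted by decreasing score.
#' @export
call_outliers <- function(pca, n_pcs_test = 5L, z_threshold = 30) {
  emb <- pca$embeddings
  if (nrow(emb) < 3)
    stop("call_outliers: need at least 3 cells for a meaningful median/MAD")
  k <- min(n_pcs_test, ncol(emb))
  zs <- matrix(NA_real_, nrow(emb), k)
  skipped <- integer(0)
  for (j in seq_len(k)) {
    med <- stats::median(emb[, j])
    m <- stats::mad(emb[, j])    # 1.4826 * median(|x - median|)
    if (m == 0) {
      skipped <- c(skipped, j)
      next
    }
    zs[, j] <- abs(emb[, j] - med) / m
  }
  if (length(skipped))
    warning("call_outliers: zero MAD on PC(s) ",
            paste(skipped, collapse = ", "), "; skipped")
  if (all(is.na(zs))) {
    score <- rep(0, nrow(emb))
    driving <- rep(NA_integer_, nrow(emb))
  } else {
    score <- apply(zs, 1, function(r) if (all(is.na(r))) 0
                   else max(r, na.rm = TRUE))
    driving <- apply(zs, 1, function(r) if (all(is.na(r))) NA_integer_
                     else which.max(r))
  }
  out <- data.frame(barcode = rownames(emb), outlier_score = score,
                    driving_pc = as.integer(driving),
                    flagged = score >= z_threshold,
                    stringsAsFactors = FALSE)
  out[order(-out$outlier_score), ]
}

#' Ranked gene loadings of one principal component
#'
#' Genes sorted by signed loading on the chosen PC. When flagged outlier
#' barcodes are supplied, the component's orientation is chosen so the
#' outliers sit on the positive side, so the top of the table reads as the
#' outliers' program.
#'
#' @param pca A `pca_model`.
#' @param pc Component index.
#' @param top_n Rows to return (clamped to the gene count).
#' @param flagged Optional barcodes of flagged outliers used to orient the
#'   component.
#' @return Data frame: `gene`, `loading`, in decreasing loading order.
#' @export
loading_report <- function(pca, pc = 1L, top_n = 20L, flagged = NULL) {
  stopifnot(pc >= 1, pc <= ncol(pca$loadings))
  load <- pca$loadings[, pc]
  if (!is.null(flagged) && length(flagged)) {
    coords <- pca$embeddings[flagged, pc]
    if (mean(coords) < 0) load <- -load
  }
  ord <- order(-load, seq_along(load))
  n <- min(top_n, length(load))
  data.frame(gene = names(load)[ord][seq_len(n)],
             loading = unname(load[ord][seq_len(n)]),
             stringsAsFactors = FALSE)
}

#' Residual-based per-cell differential expression score
#'
#' With no replicates and heavy dropout, a formal per-cell test is not
#' available; the score of gene g is the mean scaled residual over the
#' target cells minus the mean over all other cells ("scaled fold-change").
#' This ranking is what feeds preranked GSEA.
#'
#' @param scaled Genes x cells scaled residual matrix.
#' @param target_cells Barcodes (or indices) of the target cells; must be a
#'   non-empty proper subset of the columns.
#' @return Data frame `gene`, `score`, sorted descending; ties broken by
#'   gene order.
#' @export
residual_de_score <- function(scaled, target_cells) {
  if (is.character(target_cells))
    target_cells <- match(target_cells, colnames(scaled))
  if (any(is.na(target_cells))) stop("residual_de_score: unknown barcodes")
  n <- ncol(scaled)
  if (!length(target_cells)) stop("residual_de_score: empty target set")
  if (length(unique(target_cells)) >= n)
    stop("residual_de_score: target set must be a proper subset of cells")
  tgt <- scaled[, target_cells, drop = FALSE]
  rest <- scaled[, -target_cells, drop = FALSE]
  score <- rowMeans(tgt) - rowMeans(rest)
  ord <- order(-score, seq_along(score))
  data.frame(gene = rownames(scaled)[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

#' Overlap of top expressed genes between two cell groups
#'
#' Per group, genes are ranked by mean log-normalized expression within the
#' group (ties at the boundary broken by gene order); the result is the
#' intersection of the two top-`n_top` lists and its fraction of `n_top`.
#'
#' @param lognorm Genes x cells matrix from [lognormalize()].
#' @param cells_a,cells_b Barcodes or indices of the two groups.
#' @param n_top Size of each top list.
#' @return List: `shared` (gene vector), `fraction`, `ties_at_boundary`
#'   (logical, whether rank `n_top` was tied).
#' @export
top_expressed_overlap <- function(lognorm, cells_a, cells_b, n_top = 100L) {
  stopifnot(n_top >= 1)
  top_of <- function(cells) {
    m <- rowMeans(lognorm[, cells, drop = FALSE])
    ord <- order(-m, seq_along(m))
    k <- min(n_top, length(m))
    tied <- k < length(m) && m[ord[k]] == m[ord[k + 1]]
    list(genes = rownames(lognorm)[ord[seq_len(k)]], tied = tied)
  }
  a <- top_of(cells_a)
  b <- top_of(cells_b)
  shared <- intersect(a$genes, b$genes)
  list(shared = shared, fraction = length(shared) / n_top,
       ties_at_boundary = a$tied || b$tied)
}
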