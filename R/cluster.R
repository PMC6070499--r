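# Robust-pass machinery for the non-outlier blood compartment (kNN graph,
# Louvain modularity clustering, tSNE, supervised CTC labeling) and the
# two-sample combined analysis (top-dispersion gene union, CCA, quantile
# alignment of the CCA subspaces).

# exact blockwise squared Euclidean distances; returns n x b block
dist2_block <- function(X, idx) {
  rs <- rowSums(X^2)
  d2 <- outer(rs, rs[idx], "+") - 2 * (X %*% t(X[idx, , drop = FALSE]))
  pmax(d2, 0)
}

#' Shared-nearest-neighbor kNN graph in PC space
#'
#' Each cell is connected to its k nearest Euclidean neighbors (exact,
#' brute-force distances); ties at the k-th distance are all included, and
#' exact coordinate duplicates are ordered by index. The directed lists are
#' symmetrized by union and each edge is weighted by the Jaccard overlap of
#' the two endpoints' neighbor sets.
#'
#' @param embeddings Cells x PCs coordinate matrix with rownames.
#' @param k Neighbors per cell (`k < #cells`).
#' @return An undirected weighted [igraph::graph] with vertex names.
#' @export
knn_graph <- function(embeddings, k = 30L) {
  X <- as.matrix(embeddings)
  n <- nrow(X)
  stopifnot(k >= 1, k < n)
  nbr <- vector("list", n)
  block <- max(1L, min(n, floor(2e7 / n)))
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1, n)
    d2 <- dist2_block(X, idx)
    for (jj in seq_along(idx)) {
      j <- idx[jj]
      d <- d2[, jj]
      d[j] <- Inf
      ord <- order(d, seq_len(n))
      kth <- d[ord[k]]
      # include all neighbors tied with the k-th distance
      keep <- which(d <= kth + 1e-12 * max(kth, 1))
      keep <- keep[order(d[keep], keep)]
      nbr[[j]] <- keep
    }
  }
  deg <- lengths(nbr)
  from <- rep.int(seq_len(n), deg)
  to <- unlist(nbr)
  # adjacency of directed kNN lists; shared-neighbor counts via tcrossprod
  A <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
  und <- (A + Matrix::t(A)) > 0
  shared <- Matrix::tcrossprod(A)
  edges <- Matrix::which(Matrix::triu(und, 1), arr.ind = TRUE)
  i <- edges[, 1]; j <- edges[, 2]
  sh <- shared[cbind(i, j)]
  w <- sh / (deg[i] + deg[j] - sh)
  g <- igraph::graph_from_edgelist(cbind(i, j), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w
  igraph::V(g)$name <- rownames(X)
  g
}

#' Louvain modularity clustering
#'
#' Greedy modularity optimization on a weighted graph, deterministic given
#' the seed; disconnected graphs cluster per component and singleton
#' communities are permitted.
#'
#' @param graph Weighted undirected [igraph::graph] (e.g. [knn_graph()]).
#' @param resolution Modularity resolution; larger gives more clusters.
#' @param seed RNG seed.
#' @return Data frame: `barcode`, `cluster` (factor).
#' @export
modularity_cluster <- function(graph, resolution = 0.8, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop("modularity_cluster: empty graph")
  nms <- igraph::V(graph)$name
  if (!is.null(nms) && !anyDuplicated(nms)) {
    # canonicalize vertex and edge order so the partition depends only on
    # the graph itself, not on barcode order
    el <- igraph::as_edgelist(graph, names = TRUE)
    w <- igraph::E(graph)$weight
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    o <- order(a, b)
    graph <- igraph::graph_from_data_frame(
      data.frame(from = a[o], to = b[o], weight = if (is.null(w)) 1
                 else w[o]),
      directed = FALSE, vertices = sort(nms))
  }
  comm <- with_seed_(seed,
    igraph::cluster_louvain(graph, resolution = resolution))
  out <- data.frame(barcode = igraph::V(graph)$name,
                    cluster = factor(igraph::membership(comm)),
                    stringsAsFactors = FALSE)
  if (!is.null(nms) && !anyDuplicated(nms))
    out <- out[match(nms, out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' tSNE embedding of PC coordinates (visualization only)
#'
#' Barnes-Hut tSNE on PC coordinates, deterministic given the seed. The
#' 2-D coordinates are for plots; clustering and outlier calling never use
#' them.
#'
#' @param pc_embeddings Cells x PCs matrix with rownames.
#' @param perplexity tSNE perplexity; must satisfy
#'   `3 * perplexity < #cells - 1`.
#' @param seed RNG seed.
#' @param ... Passed to [Rtsne::Rtsne()].
#' @return Cells x 2 coordinate matrix with barcodes as rownames.
#' @export
tsne_embed <- function(pc_embeddings, perplexity = 30, seed = 1L, ...) {
  X <- as.matrix(pc_embeddings)
  n <- nrow(X)
  if (perplexity >= (n - 1) / 3)
    stop("tsne_embed: perplexity ", perplexity, " too large for ", n,
         " cells; need perplexity < (#cells - 1)/3 — lower it (e.g. ",
         max(1, floor((n - 2) / 3)), ")")
  res <- with_seed_(seed,
    Rtsne::Rtsne(X, perplexity = perplexity, pca = FALSE,
                 check_duplicates = FALSE, ...))
  out <- res$Y
  rownames(out) <- rownames(X)
  colnames(out) <- c("tSNE1", "tSNE2")
  out
}

#' Supervised CTC labeling over a clustering
#'
#' Cells flagged by the outlier pass are labeled `"CTC"` regardless of
#' their graph cluster; all other labels are unchanged. Flagged barcodes
#' missing from the clustering (e.g. filtered out) are re-inserted with
#' label `"CTC"` and a warning.
#'
#' @param clusters Data frame `barcode`, `cluster` from
#'   [modularity_cluster()].
#' @param outlier_calls [call_outliers()] output (or a character vector of
#'   flagged barcodes).
#' @return Data frame: `barcode`, `cluster`, `label` (cluster as character,
#'   with `"CTC"` overrides).
#' @export
supervised_label <- function(clusters, outlier_calls) {
  flagged <- if (is.character(outlier_calls)) outlier_calls
             else outlier_calls$barcode[outlier_calls$flagged]
  out <- data.frame(barcode = clusters$barcode,
                    cluster = clusters$cluster,
                    label = as.character(clusters$cluster),
                    stringsAsFactors = FALSE)
  out$label[out$barcode %in% flagged] <- "CTC"
  missing <- setdiff(flagged, out$barcode)
  if (length(missing)) {
    warning("supervised_label: re-inserting ", length(missing),
            " flagged barcode(s) absent from the clustering")
    out <- rbind(out, data.frame(barcode = missing, cluster = NA,
                                 label = "CTC", stringsAsFactors = FALSE))
  }
  out
}

#' Union of per-dataset top-dispersion genes
#'
#' Per dataset, genes are ranked by the variance-to-mean ratio of
#' `exp(lognorm) - 1` (ties at the cutoff broken by gene order); the union
#' of the two top-`n_top` lists, restricted to genes present in both
#' datasets, is returned in dataset-1 gene order.
#'
#' @param lognorm_1,lognorm_2 Genes x cells matrices sharing a gene
#'   namespace.
#' @param n_top Genes taken from each dataset.
#' @return Character vector of genes.
#' @export
union_top_dispersion <- function(lognorm_1, lognorm_2, n_top = 2000L) {
  shared <- intersect(rownames(lognorm_1), rownames(lognorm_2))
  if (!length(shared)) stop("union_top_dispersion: no shared genes")
  top_of <- function(m) {
    m <- m[shared, , drop = FALSE]
    if (methods::is(m, "sparseMatrix")) {
      y <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
      y@x <- expm1(y@x)
    } else y <- expm1(m)
    y2 <- y
    if (methods::is(y2, "sparseMatrix")) y2@x <- y2@x^2 else y2 <- y2 * y2
    mu <- as.numeric(Matrix::rowMeans(y))
    vv <- (as.numeric(Matrix::rowSums(y2)) - ncol(y) * mu^2) / (ncol(y) - 1)
    disp <- ifelse(mu > 0, vv / mu, -Inf)
    ord <- order(-disp, seq_along(disp))
    shared[ord[seq_len(min(n_top, length(shared)))]]
  }
  genes <- union(top_of(lognorm_1), top_of(lognorm_2))
  shared[shared %in% genes]
}

#' Canonical correlation analysis of two datasets with quantile alignment
#'
#' Cell embeddings are the top left/right singular vectors of the
#' cross-product of the two gene-standardized matrices (standardization by
#' the robust capped scaling, cap 10). Canonical correlations are the
#' correlations of the paired gene-space images. The aligned embeddings
#' map each dataset-2 component onto dataset-1's empirical distribution by
#' a monotone per-component quantile map, which removes additive/scale
#' batch differences without reordering cells.
#'
#' @param x1,x2 Genes x cells log-normalized (or scaled) matrices.
#' @param genes Genes to use (e.g. [union_top_dispersion()] output).
#' @param n_cv Number of canonical vectors.
#' @param cap Standardization cap passed to [scale_genes()]; `NULL` skips
#'   re-standardization (inputs assumed already scaled).
#' @return List of class `cca_model`: `shared_genes`, `cv_embeddings_1`,
#'   `cv_embeddings_2`, `canonical_correlations`,
#'   `aligned_embeddings` (rbind of dataset-1 and quantile-aligned
#'   dataset-2 coordinates, with a `dataset` attribute).
#' @export
run_cca <- function(x1, x2, genes, n_cv = 20L, cap = 10) {
  miss <- setdiff(genes, intersect(rownames(x1), rownames(x2)))
  if (length(miss))
    stop("run_cca: genes absent from one dataset: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (n_cv > min(ncol(x1), ncol(x2)))
    stop("run_cca: n_cv exceeds the smaller cell count")
  s1 <- if (is.null(cap)) as.matrix(x1[genes, , drop = FALSE])
        else scale_genes(x1[genes, , drop = FALSE], cap = cap)
  s2 <- if (is.null(cap)) as.matrix(x2[genes, , drop = FALSE])
        else scale_genes(x2[genes, , drop = FALSE], cap = cap)
  K <- crossprod(s1, s2)                       # cells1 x cells2
  small <- min(dim(K)) <= 400 || n_cv > min(dim(K)) %/% 4
  sv <- if (small) svd(K, nu = n_cv, nv = n_cv)
        else with_seed_(1L, irlba::irlba(K, nv = n_cv, nu = n_cv))
  rank <- sum(sv$d > max(dim(K)) * .Machine$double.eps * sv$d[1])
  k <- min(n_cv, rank)
  if (k < n_cv)
    warning("run_cca: n_cv = ", n_cv, " exceeds rank ", rank, "; truncating")
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  rownames(U) <- colnames(x1)
  rownames(V) <- colnames(x2)
  colnames(U) <- colnames(V) <- paste0("CC", seq_len(k))
  ccor <- vapply(seq_len(k), function(j) {
    a <- s1 %*% U[, j]; b <- s2 %*% V[, j]
    if (sd(a) == 0 || sd(b) == 0) return(0)
    min(max(stats::cor(a, b), 0), 1)
  }, numeric(1))

  aligned2 <- V
  n2 <- nrow(V)
  if (n2 > 1) {
    for (j in seq_len(k)) {
      p <- (rank(V[, j], ties.method = "average") - 1) / (n2 - 1)
      aligned2[, j] <- stats::quantile(U[, j], probs = p, type = 7,
                                       names = FALSE)
    }
  }
  aligned <- rbind(U, aligned2)
  attr(aligned, "dataset") <- rep(c(1L, 2L), c(nrow(U), nrow(V)))
  out <- list(shared_genes = genes, cv_embeddings_1 = U,
              cv_embeddings_2 = V, canonical_correlations = ccor,
              aligned_embeddings = aligned)
  class(out) <- "cca_model"
  out
}
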