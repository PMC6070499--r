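# Per-cell QC, filtering, log-normalization, covariate regression, gene
# scaling and binned-dispersion HVG selection. Two parameterizations are
# used downstream: the outlier-sensitive pass (all genes, uncapped scaling,
# no HVG lower mean bound) and the robust pass (>=5-cell gene filter,
# capped scaling).

#' Per-cell quality control table
#'
#' Computes, per cell, the total UMIs (`n_umi`), the number of detected
#' genes (`n_gene`, count > 0) and the fraction of UMIs from mitochondrial
#' genes (`pct_mito`, 0-1), identified by the standard `MT-` symbol prefix.
#'
#' @param counts Sparse genes x cells count matrix with dimnames.
#' @return Data frame with rownames = barcodes and columns `barcode`,
#'   `n_umi`, `n_gene`, `pct_mito`.
#' @export
compute_qc <- function(counts) {
  if (is.null(dim(counts)) || ncol(counts) == 0)
    stop("compute_qc: empty matrix")
  n_umi <- Matrix::colSums(counts)
  n_gene <- Matrix::colSums(counts > 0)
  mito <- grepl("^MT-", rownames(counts))
  if (!any(mito)) {
    warning("compute_qc: no 'MT-' genes found; pct_mito set to 0")
    pct_mito <- rep(0, ncol(counts))
  } else {
    pct_mito <- Matrix::colSums(counts[mito, , drop = FALSE]) / n_umi
    pct_mito[n_umi == 0] <- 0
  }
  data.frame(barcode = colnames(counts), n_umi = as.numeric(n_umi),
             n_gene = as.integer(n_gene), pct_mito = as.numeric(pct_mito),
             row.names = colnames(counts), stringsAsFactors = FALSE)
}

#' Filter cells on detected-gene count
#'
#' Keeps exactly the cells with `n_gene > min_genes` (strict inequality);
#' the gene roster is unchanged.
#'
#' @param counts Sparse genes x cells matrix.
#' @param qc Matching [compute_qc()] table.
#' @param min_genes Strict lower bound on detected genes per cell.
#' @return Filtered matrix.
#' @export
filter_cells <- function(counts, qc, min_genes = 200L) {
  stopifnot(min_genes >= 0, nrow(qc) == ncol(counts))
  keep <- qc$n_gene > min_genes
  if (!any(keep)) stop("filter_cells: no cells pass min_genes = ", min_genes)
  counts[, keep, drop = FALSE]
}

#' Filter genes on the number of cells expressing them
#'
#' Retains genes detected (count > 0) in at least `min_cells` cells. The
#' outlier-sensitive pass uses `min_cells = 0` (all genes kept regardless of
#' how few cells express them); the robust pass drops genes expressed in
#' fewer than 5 cells.
#'
#' @param counts Sparse genes x cells matrix.
#' @param min_cells Minimum number of expressing cells.
#' @return Filtered matrix (identity when `min_cells = 0`).
#' @export
filter_genes <- function(counts, min_cells = 0L) {
  stopifnot(min_cells >= 0)
  if (min_cells == 0) return(counts)
  keep <- Matrix::rowSums(counts > 0) >= min_cells
  counts[keep, , drop = FALSE]
}

#' Library-size log-normalization
#'
#' `ln(1 + scale_factor * count / cell_total)` per entry; all-zero cells map
#' to all-zero columns. Sparsity is preserved.
#'
#' @param counts Sparse genes x cells matrix.
#' @param scale_factor Target library size (default 1e4).
#' @return Sparse genes x cells real matrix.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  stopifnot(scale_factor > 0)
  x <- methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
  totals <- Matrix::colSums(x)
  per_entry <- rep.int(totals, diff(x@p))
  x@x <- log1p(scale_factor * x@x / per_entry)
  x
}

#' Regress technical covariates out of log-normalized expression
#'
#' For each gene independently, ordinary least squares of expression on
#' `[intercept, n_umi, log1p(n_umi), pct_mito]`; the pure residuals are
#' returned (the fitted intercept is not re-added — downstream scaling
#' re-centers anyway). The depth effect on log-normalized values is curved
#' (deeper cells detect more genes but each detected count maps to a
#' smaller log value), so total expression enters both linearly and on the
#' log scale; the residuals are exactly orthogonal to both terms.
#' Constant genes come out as zero rows. Zero-variance covariates are
#' dropped with a warning (the intercept always stays).
#'
#' @param lognorm Genes x cells matrix from [lognormalize()].
#' @param qc [compute_qc()] table aligned with the columns.
#' @return Dense genes x cells residual matrix.
#' @export
regress_covariates <- function(lognorm, qc) {
  stopifnot(nrow(qc) == ncol(lognorm))
  covs <- cbind(n_umi = qc$n_umi, log_n_umi = log1p(qc$n_umi),
                pct_mito = qc$pct_mito)
  keep <- apply(covs, 2, function(v) stats::var(v) > 0)
  if (!all(keep))
    warning("regress_covariates: dropping zero-variance covariate(s): ",
            paste(colnames(covs)[!keep], collapse = ", "))
  covs <- covs[, keep, drop = FALSE]
  # center/scale covariates for numerical stability; residuals unchanged
  if (ncol(covs)) covs <- scale(covs)
  X <- cbind(intercept = rep(1, ncol(lognorm)), covs)
  XtXi <- solve(crossprod(X))
  YX <- as.matrix(lognorm %*% X)            # genes x p
  fitted <- YX %*% XtXi %*% t(X)            # genes x cells
  res <- as.matrix(lognorm) - fitted
  dimnames(res) <- dimnames(lognorm)
  res
}

#' Center and variance-standardize genes, with optional cap
#'
#' Per gene: subtract the mean, divide by the standard deviation; when
#' `cap = c`, clip the standardized values to `[-c, c]` afterwards. The
#' outlier-sensitive pass uses `cap = NULL` (no upper bound, so a single
#' extreme cell keeps its full leverage); the robust pass caps at 10.
#' Zero-variance genes become all-zero rows.
#'
#' @param x Genes x cells matrix (dense or sparse).
#' @param cap Positive clip value, or `NULL` for no clipping.
#' @return Dense genes x cells matrix of (optionally clipped) z-scores.
#' @export
scale_genes <- function(x, cap = NULL) {
  x <- as.matrix(x)
  n <- ncol(x)
  mu <- rowMeans(x)
  ss <- rowSums(x * x)
  sdv <- sqrt(pmax((ss - n * mu^2) / (n - 1), 0))
  out <- (x - mu) / sdv
  out[sdv == 0, ] <- 0
  if (!is.null(cap)) {
    stopifnot(cap > 0)
    out[out > cap] <- cap
    out[out < -cap] <- -cap
  }
  out
}

#' Binned-dispersion highly-variable-gene selection
#'
#' The dispersion statistic is the variance-to-mean ratio of the
#' de-logged expression `exp(lognorm) - 1`. Genes with any expression are
#' placed into `n_bins` equal-frequency bins of mean log-normalized
#' expression (ties broken by gene order), the dispersion is z-standardized
#' within each bin, and a gene is selected when its within-bin z is at
#' least `z_cutoff` and (if `min_mean` is given) its mean expression is at
#' least `min_mean`. The outlier-sensitive pass sets `min_mean = NULL`: no
#' lower expression limit, so the subtle signal of a rare-cell program is
#' not discarded.
#'
#' @param lognorm Genes x cells matrix from [lognormalize()].
#' @param n_bins Number of equal-frequency mean-expression bins.
#' @param z_cutoff Within-bin dispersion z-score cutoff.
#' @param min_mean Optional lower bound on mean log-normalized expression.
#' @return Data frame per gene: `gene`, `mean_expr`, `dispersion`, `bin`,
#'   `z_dispersion`, `selected`. Genes with zero expression get `bin = NA`
#'   and are never selected.
#' @export
select_hvg <- function(lognorm, n_bins = 30L, z_cutoff = 1, min_mean = NULL) {
  stopifnot(n_bins >= 1)
  n <- ncol(lognorm)
  mean_expr <- as.numeric(Matrix::rowMeans(lognorm))
  y <- lognorm
  if (methods::is(y, "sparseMatrix")) {
    y <- methods::as(methods::as(y, "dMatrix"), "CsparseMatrix")
    y@x <- expm1(y@x)
  } else {
    y <- expm1(y)
  }
  my <- as.numeric(Matrix::rowMeans(y))
  y2 <- y
  if (methods::is(y2, "sparseMatrix")) y2@x <- y2@x^2 else y2 <- y2 * y2
  ssq <- as.numeric(Matrix::rowSums(y2))
  vy <- (ssq - n * my^2) / (n - 1)
  dispersion <- ifelse(my > 0, vy / my, NA_real_)

  expressed <- which(my > 0)
  bin <- rep(NA_integer_, nrow(lognorm))
  z <- rep(NA_real_, nrow(lognorm))
  if (length(expressed)) {
    ord <- order(mean_expr[expressed], seq_along(expressed))
    ne <- length(expressed)
    b <- integer(ne)
    b[ord] <- as.integer(floor((seq_len(ne) - 1) * n_bins / ne)) + 1L
    bin[expressed] <- b
    for (k in unique(b)) {
      idx <- expressed[b == k]
      d <- dispersion[idx]
      s <- stats::sd(d)
      z[idx] <- if (length(idx) < 2 || !is.finite(s) || s == 0) 0
                else (d - mean(d)) / s
    }
  }
  selected <- !is.na(z) & z >= z_cutoff
  if (!is.null(min_mean)) selected <- selected & mean_expr >= min_mean
  data.frame(gene = rownames(lognorm), mean_expr = mean_expr,
             dispersion = dispersion, bin = bin, z_dispersion = z,
             selected = selected, row.names = rownames(lognorm),
             stringsAsFactors = FALSE)
}
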