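# Grouped differential expression and marker statistics: the bimodal
# (hurdle) likelihood-ratio test, AUC-based marker ranking, and
# Benjamini-Hochberg FDR.

# Bernoulli log-likelihood at the MLE, with 0*log(0) = 0
ll_bern <- function(k, n) {
  if (n == 0) return(0)
  p <- k / n
  t1 <- if (k > 0) k * log(p) else 0
  t2 <- if (k < n) (n - k) * log(1 - p) else 0
  t1 + t2
}

#' Bimodal (hurdle) likelihood-ratio test for single-cell DE
#'
#' Models each gene's log-normalized expression as a two-part (discrete and
#' continuous) process: a Bernoulli detection probability and a Normal on
#' the positive values, with the Normal variance pooled across groups
#' within a gene. The null fits pooled detection and mean; the alternative
#' fits them per group (two extra free parameters), so the deviance
#' `2 * (logL_alt - logL_null)` is referred to a chi-square with 2 df.
#' Genes undetected in both groups get p = 1. When fewer than two positive
#' values exist in total, the pooled variance is floored at 1e-6 (with a
#' warning) so the statistic stays finite.
#'
#' @param lognorm Genes x cells matrix from [lognormalize()].
#' @param group_a,group_b Disjoint, non-empty barcode or index sets.
#' @return Data frame per gene: `gene`, `statistic` (deviance), `p_value`,
#'   `fdr` (BH), `mean_diff` (group A minus group B mean log expression),
#'   `pct_in` / `pct_out` (detection fraction in A / B).
#' @export
bimod_lrt <- function(lognorm, group_a, group_b) {
  if (is.character(group_a)) group_a <- match(group_a, colnames(lognorm))
  if (is.character(group_b)) group_b <- match(group_b, colnames(lognorm))
  if (any(is.na(group_a)) || any(is.na(group_b)))
    stop("bimod_lrt: unknown barcodes")
  if (!length(group_a) || !length(group_b))
    stop("bimod_lrt: both groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("bimod_lrt: groups must be disjoint")
  A <- as.matrix(lognorm[, group_a, drop = FALSE])
  B <- as.matrix(lognorm[, group_b, drop = FALSE])
  na <- ncol(A); nb <- ncol(B)
  ng <- nrow(A)
  stat <- numeric(ng); pval <- numeric(ng)
  floored <- 0L
  for (g in seq_len(ng)) {
    xa <- A[g, ]; xb <- B[g, ]
    pa <- xa[xa > 0]; pb <- xb[xb > 0]
    ka <- length(pa); kb <- length(pb)
    if (ka + kb == 0) {
      stat[g] <- 0; pval[g] <- 1
      next
    }
    ll_disc_alt <- ll_bern(ka, na) + ll_bern(kb, nb)
    ll_disc_null <- ll_bern(ka + kb, na + nb)
    pos <- c(pa, pb)
    npos <- ka + kb
    # alternative: per-group means, pooled variance
    ss_alt <- 0
    if (ka > 0) ss_alt <- ss_alt + sum((pa - mean(pa))^2)
    if (kb > 0) ss_alt <- ss_alt + sum((pb - mean(pb))^2)
    ss_null <- sum((pos - mean(pos))^2)
    v_alt <- ss_alt / npos
    v_null <- ss_null / npos
    if (v_alt < 1e-6 || v_null < 1e-6) {
      floored <- floored + 1L
      v_alt <- max(v_alt, 1e-6)
      v_null <- max(v_null, 1e-6)
    }
    ll_cont_alt <- -npos / 2 * (log(2 * pi * v_alt) + ss_alt / (npos * v_alt))
    ll_cont_null <- -npos / 2 * (log(2 * pi * v_null) +
                                   ss_null / (npos * v_null))
    stat[g] <- 2 * ((ll_disc_alt + ll_cont_alt) -
                      (ll_disc_null + ll_cont_null))
    pval[g] <- stats::pchisq(stat[g], df = 2, lower.tail = FALSE)
  }
  if (floored > 0)
    warning("bimod_lrt: pooled variance floored at 1e-6 for ", floored,
            " gene(s) with fewer than two distinct positive values")
  data.frame(gene = rownames(lognorm), statistic = stat, p_value = pval,
             fdr = bh_fdr(pval), mean_diff = rowMeans(A) - rowMeans(B),
             pct_in = rowSums(A > 0) / na, pct_out = rowSums(B > 0) / nb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' AUC marker ranking, one cluster vs rest
#'
#' Per cluster and gene, the area under the ROC curve for separating
#' in-cluster from out-of-cluster cells: `P(expr_in > expr_out) + 0.5 *
#' P(tie)`, computed from midranks (so a gene constant everywhere scores
#' exactly 0.5). Genes are ranked by `|AUC - 0.5|` descending within each
#' cluster. Invariant under any strictly monotone transform of expression.
#'
#' @param lognorm Genes x cells matrix.
#' @param labels Cluster label per cell (length = #cells).
#' @return Data frame: `cluster`, `gene`, `auc`, `mean_diff`, `pct_in`,
#'   `pct_out`, `low_confidence` (TRUE for singleton clusters).
#' @export
auc_markers <- function(lognorm, labels) {
  stopifnot(length(labels) == ncol(lognorm))
  labels <- as.character(labels)
  clusters <- unique(labels)
  if (length(clusters) < 2) stop("auc_markers: need >= 2 clusters")
  x <- as.matrix(lognorm)
  n <- ncol(x)
  ranks <- matrix(0, nrow(x), n)
  for (g in seq_len(nrow(x))) ranks[g, ] <- rank(x[g, ])
  detect <- x > 0
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    inc <- labels == cl
    n1 <- sum(inc); n2 <- n - n1
    w <- rowSums(ranks[, inc, drop = FALSE])
    auc <- (w - n1 * (n1 + 1) / 2) / (n1 * n2)
    tab <- data.frame(
      cluster = cl, gene = rownames(x), auc = auc,
      mean_diff = rowMeans(x[, inc, drop = FALSE]) -
        rowMeans(x[, !inc, drop = FALSE]),
      pct_in = rowSums(detect[, inc, drop = FALSE]) / n1,
      pct_out = rowSums(detect[, !inc, drop = FALSE]) / n2,
      low_confidence = n1 < 2,
      row.names = NULL, stringsAsFactors = FALSE)
    out[[ci]] <- tab[order(-abs(tab$auc - 0.5), seq_len(nrow(tab))), ]
  }
  do.call(rbind, out)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjustment with monotonicity enforcement, order-preserving with
#' respect to the input. Non-finite p-values propagate as `NaN` with a
#' warning.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  bad <- !is.finite(p_values)
  if (any(bad)) {
    warning("bh_fdr: ", sum(bad), " non-finite p-value(s) propagated as NaN")
    out <- rep(NaN, length(p_values))
    out[!bad] <- stats::p.adjust(p_values[!bad], method = "BH")
    return(out)
  }
  if (any(p_values < 0 | p_values > 1))
    stop("bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
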