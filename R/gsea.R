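# Preranked gene-set enrichment analysis with a gene-permutation null.
# Only one "phenotype" (a single candidate CTC) exists per ranking, so
# phenotype permutation is undefined; the null permutes gene labels.

# Enrichment score of a set given sorted scores. `hit_pos` are positions of
# the set's genes in the ranking (1 = best). The weighted KS running sum
# increments by |score|^weight / sum(|score_hit|^weight) at hits and
# decrements by 1/(N - Nh) at misses; the extrema only occur adjacent to
# hits, so only hit positions need visiting.
es_stat <- function(abs_w, hit_pos, n) {
  hit_pos <- sort.int(hit_pos)
  nh <- length(hit_pos)
  wsum <- sum(abs_w[hit_pos])
  inc <- if (wsum > 0) abs_w[hit_pos] / wsum else rep(1 / nh, nh)
  cum_hit <- cumsum(inc)
  miss_step <- 1 / (n - nh)
  miss_before <- (hit_pos - seq_len(nh)) * miss_step
  dev_after <- cum_hit - miss_before            # just after each hit
  dev_before <- c(0, cum_hit[-nh]) - miss_before # just before each hit
  i_max <- which.max(dev_after)
  i_min <- which.min(dev_before)
  if (dev_after[i_max] >= -dev_before[i_min])
    list(es = dev_after[i_max], at = hit_pos[i_max], sign = 1)
  else
    list(es = dev_before[i_min], at = hit_pos[i_min], sign = -1)
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov preranked GSEA on a named score
#' vector (e.g., the scaled fold-changes of one candidate CTC vs all other
#' cells from [residual_de_score()]). The null distribution comes from
#' `n_perm` gene-label permutations; NES is the ES divided by the mean
#' same-sign permuted ES, the nominal p is the same-sign permutation tail
#' fraction, and the FDR is the standard same-sign NES-ratio estimator over
#' the whole collection, floored at `1/n_perm`.
#'
#' @param ranked_scores Named numeric vector; sorted internally in
#'   decreasing order (ties broken by input order).
#' @param sets Named list of gene vectors ([read_gmt()] /
#'   [emit_gene_sets()] output). Sets are restricted to genes present in
#'   the ranking; sets dropping below `min_size` genes are skipped with a
#'   warning.
#' @param weight Exponent on |score| for hit increments; 1 is classic
#'   preranked GSEA, 0 gives the unweighted KS statistic.
#' @param n_perm Number of gene-label permutations (< 100 draws a warning).
#' @param seed Permutation seed; identical seed gives identical p and FDR.
#' @param min_size Minimum post-restriction set size.
#' @return Data frame per scored set: `set`, `size`, `es`, `nes`,
#'   `nominal_p`, `fdr`, `leading_edge` (comma-joined genes up to the ES
#'   extremum, members of the prefix or suffix matching the ES sign).
#' @export
preranked_gsea <- function(ranked_scores, sets, weight = 1, n_perm = 1000L,
                           seed = 1L, min_size = 5L) {
  stopifnot(is.numeric(ranked_scores), !is.null(names(ranked_scores)))
  if (n_perm < 100) warning("preranked_gsea: n_perm < 100 is unreliable")
  ord <- order(-ranked_scores, seq_along(ranked_scores))
  scores <- ranked_scores[ord]
  genes <- names(scores)
  n <- length(genes)
  abs_w <- abs(scores)^weight

  restricted <- lapply(sets, function(s) intersect(unique(s), genes))
  sizes <- lengths(restricted)
  largest <- if (length(sizes)) max(sizes) else 0
  if (n < 2 * largest)
    stop("preranked_gsea: ranking must cover >= 2x the largest set")
  drop <- sizes < min_size
  if (any(drop))
    warning("preranked_gsea: skipping ", sum(drop),
            " set(s) below ", min_size, " genes after restriction: ",
            paste(names(sets)[drop], collapse = ", "))
  restricted <- restricted[!drop]
  if (!length(restricted))
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), nominal_p = numeric(0),
                      fdr = numeric(0), leading_edge = character(0),
                      stringsAsFactors = FALSE))

  obs <- lapply(restricted, function(s) es_stat(abs_w, match(s, genes), n))
  es <- vapply(obs, `[[`, numeric(1), "es")

  # permutation null: resample hit positions per distinct set size
  uniq_sizes <- sort(unique(lengths(restricted)))
  perm_by_size <- with_seed_(seed, {
    res <- lapply(uniq_sizes, function(sz) {
      vapply(seq_len(n_perm), function(i)
        es_stat(abs_w, sample.int(n, sz), n)$es, numeric(1))
    })
    names(res) <- as.character(uniq_sizes)
    res
  })

  norm_factor <- function(perm, sign_es) {
    same <- if (sign_es >= 0) perm[perm > 0] else -perm[perm < 0]
    if (!length(same)) return(NA_real_)
    mean(same)
  }
  nes <- numeric(length(es))
  pval <- numeric(length(es))
  perm_nes_all <- vector("list", length(es))
  for (i in seq_along(es)) {
    perm <- perm_by_size[[as.character(length(restricted[[i]]))]]
    f_pos <- norm_factor(perm, 1)
    f_neg <- norm_factor(perm, -1)
    f <- if (es[i] >= 0) f_pos else f_neg
    nes[i] <- if (is.na(f) || f == 0) NA_real_ else es[i] / f
    same <- if (es[i] >= 0) perm[perm > 0] else perm[perm < 0]
    pval[i] <- if (!length(same)) 1 / n_perm
               else max(sum(abs(same) >= abs(es[i])) / length(same),
                        1 / n_perm)
    # pooled normalized permutation NES for the FDR estimator
    pn <- rep(NA_real_, length(perm))
    if (!is.na(f_pos) && f_pos != 0) pn[perm > 0] <- perm[perm > 0] / f_pos
    if (!is.na(f_neg) && f_neg != 0) pn[perm < 0] <- perm[perm < 0] / f_neg
    perm_nes_all[[i]] <- pn[!is.na(pn)]
  }
  pooled <- unlist(perm_nes_all)
  fdr <- numeric(length(es))
  for (i in seq_along(es)) {
    if (is.na(nes[i])) { fdr[i] <- NA_real_; next }
    if (nes[i] >= 0) {
      num_pool <- pooled[pooled >= 0]
      num <- if (length(num_pool)) mean(num_pool >= nes[i]) else 0
      den_pool <- nes[!is.na(nes) & nes >= 0]
      den <- mean(den_pool >= nes[i])
    } else {
      num_pool <- pooled[pooled < 0]
      num <- if (length(num_pool)) mean(num_pool <= nes[i]) else 0
      den_pool <- nes[!is.na(nes) & nes < 0]
      den <- mean(den_pool <= nes[i])
    }
    fdr[i] <- max(min(1, num / max(den, .Machine$double.eps)), 1 / n_perm)
  }

  leading <- vapply(seq_along(es), function(i) {
    s <- restricted[[i]]
    pos <- match(s, genes)
    o <- obs[[i]]
    le <- if (o$sign >= 0) s[pos <= o$at] else s[pos >= o$at]
    paste(le, collapse = ",")
  }, character(1))

  data.frame(set = names(restricted), size = lengths(restricted),
             es = es, nes = nes, nominal_p = pval, fdr = fdr,
             leading_edge = leading, row.names = NULL,
             stringsAsFactors = FALSE)
}
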