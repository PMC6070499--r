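# Shared fixtures and independent brute-force oracles. Every oracle here is
# written as a straight loop (or closed form) independent of the package's
# vectorized implementations.

# small ground-truthed simulation used across test files
small_sim <- function(seed = 1, n_cells = 600, n_rare = 2, n_genes = 600,
                      ...) {
  generate_dataset(sim_config(n_cells = n_cells, n_rare = n_rare,
                              n_genes = n_genes, seed = seed, ...))
}

# tiny dense count matrix with MT- genes, hand-controllable
toy_counts <- function() {
  m <- matrix(
    c(3, 0, 2,
      1, 0, 5,
      0, 0, 1,
      1, 0, 0),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("GENE1", "GENE2", "MT-CO1", "MT-ND1"),
                    c("c1", "c2", "c3")))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# straight-loop QC recomputation over raw entries
oracle_qc <- function(counts) {
  m <- as.matrix(counts)
  out <- data.frame(barcode = colnames(m), n_umi = NA_real_,
                    n_gene = NA_integer_, pct_mito = NA_real_)
  for (j in seq_len(ncol(m))) {
    tot <- 0; ng <- 0L; mito <- 0
    for (i in seq_len(nrow(m))) {
      v <- m[i, j]
      tot <- tot + v
      if (v > 0) ng <- ng + 1L
      if (startsWith(rownames(m)[i], "MT-")) mito <- mito + v
    }
    out$n_umi[j] <- tot
    out$n_gene[j] <- ng
    out$pct_mito[j] <- if (tot > 0) mito / tot else 0
  }
  out
}

# straight-loop log-normalization
oracle_lognorm <- function(counts, sf = 1e4) {
  m <- as.matrix(counts)
  out <- m * 0
  for (j in seq_len(ncol(m))) {
    tot <- sum(m[, j])
    for (i in seq_len(nrow(m)))
      out[i, j] <- if (m[i, j] > 0) log(1 + sf * m[i, j] / tot) else 0
  }
  out
}

# per-gene OLS residuals by explicit normal equations
oracle_residuals <- function(lognorm, qc) {
  m <- as.matrix(lognorm)
  X <- cbind(1, scale(cbind(qc$n_umi, log1p(qc$n_umi), qc$pct_mito)))
  out <- m * 0
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    beta <- solve(t(X) %*% X, t(X) %*% y)
    out[i, ] <- y - as.numeric(X %*% beta)
  }
  out
}

# independent equal-frequency binning + within-bin z, straight loops
oracle_hvg_selected <- function(lognorm, n_bins = 30, z_cutoff = 1,
                                min_mean = NULL) {
  m <- as.matrix(lognorm)
  n <- ncol(m)
  mean_expr <- apply(m, 1, mean)
  y <- exp(m) - 1
  my <- apply(y, 1, mean)
  vy <- apply(y, 1, var)
  disp <- ifelse(my > 0, vy / my, NA)
  expressed <- which(my > 0)
  ord <- expressed[order(mean_expr[expressed], expressed)]
  sel <- logical(nrow(m))
  ne <- length(ord)
  # equal-frequency rule: the gene with (1-based) mean-expression rank i
  # falls in bin floor((i-1) * n_bins / ne) + 1
  bin_of <- integer(nrow(m))
  for (i in seq_len(ne)) bin_of[ord[i]] <- floor((i - 1) * n_bins / ne) + 1
  for (k in seq_len(n_bins)) {
    idx <- which(bin_of == k)
    if (!length(idx)) next
    d <- disp[idx]
    z <- if (length(idx) < 2 || sd(d) == 0 || !is.finite(sd(d)))
      rep(0, length(idx)) else (d - mean(d)) / sd(d)
    for (t in seq_along(idx)) {
      ok <- z[t] >= z_cutoff
      if (!is.null(min_mean)) ok <- ok && mean_expr[idx[t]] >= min_mean
      sel[idx[t]] <- ok
    }
  }
  rownames(m)[sel]
}

# AUC by explicit double loop over all in/out pairs
oracle_auc <- function(x, inc) {
  a <- x[inc]; b <- x[!inc]
  tot <- 0
  for (u in a) for (v in b)
    tot <- tot + (u > v) + 0.5 * (u == v)
  tot / (length(a) * length(b))
}

# hurdle LRT deviance by numeric maximum likelihood (optim over the
# continuous part; detection part closed form)
oracle_bimod_deviance <- function(xa, xb) {
  ll_bern <- function(k, n) {
    if (n == 0) return(0)
    p <- k / n
    (if (k > 0) k * log(p) else 0) + (if (k < n) (n - k) * log(1 - p) else 0)
  }
  pa <- xa[xa > 0]; pb <- xb[xb > 0]
  pos <- c(pa, pb)
  if (!length(pos)) return(0)
  nll_alt <- function(par) {
    mua <- par[1]; mub <- par[2]; lsig <- par[3]
    s2 <- exp(2 * lsig)
    -(sum(stats::dnorm(pa, mua, sqrt(s2), log = TRUE)) +
        sum(stats::dnorm(pb, mub, sqrt(s2), log = TRUE)))
  }
  nll_null <- function(par) {
    mu <- par[1]; s2 <- exp(2 * par[2])
    -sum(stats::dnorm(pos, mu, sqrt(s2), log = TRUE))
  }
  st <- c(mean(pos), mean(pos), log(max(sd(pos), 1e-2)))
  oa <- stats::optim(st, nll_alt, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-12))
  on <- stats::optim(st[c(1, 3)], nll_null, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-12))
  ll_disc <- (ll_bern(length(pa), length(xa)) +
                ll_bern(length(pb), length(xb))) -
    ll_bern(length(pos), length(xa) + length(xb))
  2 * ll_disc + 2 * (on$value - oa$value)
}

# GSEA running-sum ES by explicit walk over the full ranking
oracle_es <- function(scores, set, weight = 1) {
  ord <- order(-scores, seq_along(scores))
  genes <- names(scores)[ord]
  s <- abs(scores[ord])^weight
  hit <- genes %in% set
  nh <- sum(hit)
  wsum <- sum(s[hit])
  run <- 0; best <- 0
  for (i in seq_along(genes)) {
    run <- run + if (hit[i]) s[i] / wsum else -1 / (length(genes) - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# brute-force kNN neighbor lists (ties at the k-th distance all kept)
oracle_knn <- function(X, k) {
  n <- nrow(X)
  lapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    kth <- d[ord[k]]
    sort(which(d <= kth + 1e-12 * max(kth, 1)))
  })
}

# straight-loop NB sampler for per-cell totals under the generator's
# closed-form parameterization (library model x NB noise)
oracle_total_counts <- function(config, pop_profile, libsizes, mito_fracs,
                                mito_w) {
  totals <- numeric(length(libsizes))
  for (c in seq_along(libsizes)) {
    tot <- 0
    mus <- c(pop_profile * libsizes[c] * (1 - mito_fracs[c]),
             mito_w * libsizes[c] * mito_fracs[c])
    for (mu in mus)
      tot <- tot + stats::rnbinom(1, size = config$nb_dispersion, mu = mu)
    totals[c] <- tot
  }
  totals
}

expect_tsv_roundtrip <- function(df, ...) {
  path <- tempfile(fileext = ".tsv")
  write_result_tsv(df, path, ...)
  back <- read_result_tsv(path)
  expect_equal(back, df, ignore_attr = TRUE)
}
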