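# kNN graph, Louvain clustering, tSNE, supervised labels, top-dispersion
# union, CCA with quantile alignment

blob_data <- function(n_per = 60, d = 5, sep = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), ncol = d),
             matrix(rnorm(n_per * d, mean = sep), ncol = d))
  rownames(x) <- sprintf("c%03d", seq_len(2 * n_per))
  x
}

test_that("three equidistant points with k=1 symmetrize to a 3-cycle", {
  x <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  rownames(x) <- c("a", "b", "c")
  g <- knn_graph(x, k = 1)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(igraph::vcount(g), 3)
  expect_true(igraph::is_connected(g))
})

test_that("neighbor lists equal brute-force all-pairs sorting on a 100-cell
           fixture", {
  set.seed(9)
  x <- matrix(rnorm(100 * 4), ncol = 4,
              dimnames = list(sprintf("c%03d", 1:100), NULL))
  g <- knn_graph(x, k = 7)
  nb <- oracle_knn(x, 7)
  adj <- igraph::as_adj_list(g)
  for (i in seq_len(100)) {
    got <- sort(as.integer(adj[[i]]))
    exp_sym <- sort(union(nb[[i]], which(vapply(nb, function(s) i %in% s,
                                                logical(1)))))
    expect_identical(got, exp_sym)
  }
})

test_that("two well-separated blobs have zero cross-blob edges and perfect
           Louvain recovery", {
  x <- blob_data(n_per = 50, sep = 20, seed = 2)
  g <- knn_graph(x, k = 10)
  el <- igraph::as_edgelist(g, names = FALSE)
  side <- rep(1:2, each = 50)
  expect_true(all(side[el[, 1]] == side[el[, 2]]))

  cl <- modularity_cluster(g, resolution = 0.8, seed = 1)
  # with zero cross-blob edges every community is pure with respect to its
  # blob (Louvain may legitimately subdivide a blob)
  side <- setNames(rep(1:2, each = 50), rownames(x))
  purity <- tapply(side[cl$barcode], cl$cluster,
                   function(v) length(unique(v)))
  expect_true(all(purity == 1))
  expect_gte(nlevels(cl$cluster), 2)
})

test_that("two disconnected cliques cluster as exactly the cliques", {
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(5))
  igraph::V(g)$name <- paste0("v", 1:11)
  igraph::E(g)$weight <- 1
  cl <- modularity_cluster(g, seed = 1)
  expect_equal(nlevels(cl$cluster), 2)
  expect_equal(length(unique(cl$cluster[1:6])), 1)
  expect_equal(length(unique(cl$cluster[7:11])), 1)
})

test_that("modularity clustering is deterministic given the seed and
           invariant to barcode order", {
  x <- blob_data(n_per = 40, sep = 8, seed = 3)
  g <- knn_graph(x, k = 8)
  a <- modularity_cluster(g, seed = 5)
  b <- modularity_cluster(g, seed = 5)
  expect_identical(a, b)

  perm <- sample(nrow(x))
  g2 <- knn_graph(x[perm, ], k = 8)
  c2 <- modularity_cluster(g2, seed = 5)
  m1 <- as.integer(a$cluster)[match(c2$barcode, a$barcode)]
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(m1, as.integer(c2$cluster)), 1)
})

test_that("clustering the synthetic blood compartment recovers the truth
           populations and beats the truth partition's modularity margin", {
  sim <- generate_dataset(sim_config(n_cells = 1200, n_rare = 0,
                                     n_genes = 1200, seed = 6))
  res <- run_robust_pass(sim$counts, config = pipeline_config(seed = 6, min_genes = 100),
                         run_tsne = FALSE)
  truth <- sim$truth$population[match(res$clusters$barcode,
                                      sim$truth$barcode)]
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(truth, as.integer(res$clusters$cluster))
  expect_gte(ari, 0.8)

  memb <- as.integer(res$clusters$cluster)
  mod_found <- igraph::modularity(res$graph, memb,
                                  weights = igraph::E(res$graph)$weight)
  mod_truth <- igraph::modularity(res$graph, as.integer(factor(truth)),
                                  weights = igraph::E(res$graph)$weight)
  expect_gte(mod_found, mod_truth - 0.02)
})

test_that("tsne is deterministic under a seed, rejects tiny inputs, and
           separates distant blobs", {
  x <- blob_data(n_per = 60, sep = 20, seed = 4)
  a <- tsne_embed(x, perplexity = 10, seed = 3, max_iter = 250)
  b <- tsne_embed(x, perplexity = 10, seed = 3, max_iter = 250)
  expect_identical(a, b)
  expect_error(tsne_embed(x[1:2, ], perplexity = 10), "perplexity")

  lab <- rep(1:2, each = 60)
  d <- as.matrix(dist(a))
  sil <- vapply(seq_len(nrow(a)), function(i) {
    own <- mean(d[i, lab == lab[i]][-1])
    oth <- mean(d[i, lab != lab[i]])
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("supervised labeling overrides exactly the flagged barcodes and
           re-inserts missing ones", {
  clusters <- data.frame(barcode = paste0("c", 1:6),
                         cluster = factor(rep(1:2, 3)))
  calls <- data.frame(barcode = paste0("c", c(2, 5, 9)),
                      flagged = c(TRUE, TRUE, TRUE))
  expect_warning(lab <- supervised_label(clusters, calls), "re-inserting")
  expect_equal(lab$label[lab$barcode == "c2"], "CTC")
  expect_equal(lab$label[lab$barcode == "c5"], "CTC")
  expect_equal(sum(lab$label == "CTC"), 3)
  expect_true("c9" %in% lab$barcode)
  # zero flagged: identity on labels
  same <- supervised_label(clusters, character(0))
  expect_equal(same$label, as.character(clusters$cluster))
})

test_that("union_top_dispersion: identity, disjoint bound, and brute-force
           equality", {
  sim <- small_sim(seed = 7, n_cells = 150, n_rare = 1, n_genes = 300)
  ln <- lognormalize(sim$counts)
  expect_length(union_top_dispersion(ln, ln, n_top = 50), 50)

  half1 <- ln[1:150, ]; half2 <- ln[151:300, ]
  expect_error(union_top_dispersion(half1, half2), "shared")

  ln2 <- lognormalize(small_sim(seed = 8, n_cells = 150, n_rare = 1,
                                n_genes = 300)$counts)
  got <- union_top_dispersion(ln, ln2, n_top = 40)
  disp_of <- function(m) {
    y <- exp(as.matrix(m)) - 1
    apply(y, 1, function(v) if (mean(v) > 0) var(v) / mean(v) else -Inf)
  }
  top <- function(m) {
    d <- disp_of(m)
    names(sort(-rank(d, ties.method = "first"))[1:40])
  }
  d1 <- disp_of(ln); d2 <- disp_of(ln2)
  o1 <- rownames(ln)[order(-d1, seq_along(d1))][1:40]
  o2 <- rownames(ln2)[order(-d2, seq_along(d2))][1:40]
  expect_setequal(got, union(o1, o2))
  expect_lte(length(got), 80)
})

test_that("CCA of a dataset with itself gives unit leading correlation and
           identity alignment", {
  sim <- small_sim(seed = 9, n_cells = 200, n_rare = 1, n_genes = 300)
  ln <- lognormalize(sim$counts)
  genes <- union_top_dispersion(ln, ln, n_top = 150)
  cca <- run_cca(ln, ln, genes, n_cv = 5)
  expect_equal(cca$canonical_correlations[1], 1, tolerance = 1e-8)
  n <- ncol(ln)
  aligned2 <- cca$aligned_embeddings[(n + 1):(2 * n), ]
  expect_equal(aligned2, cca$cv_embeddings_1, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("independent random matrices stay below the permutation null's
           95th percentile for the leading correlation", {
  set.seed(10)
  mk <- function(seed) {
    set.seed(seed)
    m <- matrix(rpois(300 * 80, 2), nrow = 300,
                dimnames = list(paste0("g", 1:300), paste0("c", seed, 1:80)))
    lognormalize(Matrix::Matrix(m, sparse = TRUE))
  }
  x1 <- mk(1); x2 <- mk(2)
  genes <- paste0("g", 1:300)
  obs <- run_cca(x1, x2, genes, n_cv = 2)$canonical_correlations[1]
  perm <- vapply(1:20, function(i) {
    set.seed(100 + i)
    x2p <- x2[, sample(ncol(x2))]
    colnames(x2p) <- colnames(x2)
    run_cca(x1, x2p, genes, n_cv = 2)$canonical_correlations[1]
  }, numeric(1))
  # column permutation preserves the null (independent) structure, so the
  # observed leading correlation should look like a draw from it
  expect_lte(obs, quantile(perm, 0.95) + 0.05)
})

test_that("alignment is monotone per component and never reorders cells", {
  sim1 <- small_sim(seed = 11, n_cells = 150, n_rare = 1, n_genes = 300)
  sim2 <- small_sim(seed = 12, n_cells = 120, n_rare = 1, n_genes = 300,
                    libsize_lognormal_params = c(meanlog = 7.8, sdlog = 0.6))
  ln1 <- lognormalize(sim1$counts); ln2 <- lognormalize(sim2$counts)
  genes <- union_top_dispersion(ln1, ln2, n_top = 150)
  cca <- run_cca(ln1, ln2, genes, n_cv = 4)
  n1 <- ncol(ln1)
  raw2 <- cca$cv_embeddings_2
  al2 <- cca$aligned_embeddings[(n1 + 1):(n1 + ncol(ln2)), ]
  expect_identical(rownames(al2), rownames(raw2))
  for (j in seq_len(ncol(raw2))) {
    o <- order(raw2[, j])
    expect_true(all(diff(al2[o, j]) >= -1e-12))
  }
})

test_that("cross-dataset population centroids shrink after CCA alignment", {
  sim1 <- generate_dataset(sim_config(n_cells = 700, n_rare = 2,
                                      n_genes = 800, seed = 13))
  sim2 <- generate_dataset(sim_config(
    n_cells = 500, n_rare = 1, n_genes = 800, seed = 14,
    libsize_lognormal_params = c(meanlog = 7.6, sdlog = 0.5)))
  ln1 <- lognormalize(sim1$counts); ln2 <- lognormalize(sim2$counts)
  genes <- union_top_dispersion(ln1, ln2, n_top = 600)
  cca <- run_cca(ln1, ln2, genes, n_cv = 10)
  n1 <- ncol(ln1)
  e1 <- cca$cv_embeddings_1
  raw2 <- cca$cv_embeddings_2
  al2 <- cca$aligned_embeddings[(n1 + 1):(n1 + ncol(ln2)), ]
  pops <- setdiff(intersect(sim1$truth$population, sim2$truth$population),
                  "RARE")
  cent <- function(emb, truth, p)
    colMeans(emb[truth$barcode[truth$population == p], , drop = FALSE])
  shrunk <- vapply(pops, function(p) {
    pre <- sqrt(sum((cent(e1, sim1$truth, p) -
                       cent(raw2, sim2$truth, p))^2))
    post <- sqrt(sum((cent(e1, sim1$truth, p) -
                        cent(al2, sim2$truth, p))^2))
    post < pre
  }, logical(1))
  expect_true(all(shrunk))
})
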