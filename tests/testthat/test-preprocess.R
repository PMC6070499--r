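# QC, filtering, normalization, covariate regression, scaling, HVG selection

test_that("compute_qc arithmetic on a hand-checked cell and edge cases", {
  counts <- toy_counts()
  qc <- compute_qc(counts)
  # c1: counts GENE1=3, GENE2=1, MT-ND1=1 -> n_umi 5, n_gene 3, mito 1/5
  expect_equal(qc["c1", "n_umi"], 5)
  expect_equal(qc["c1", "n_gene"], 3L)
  expect_equal(qc["c1", "pct_mito"], 0.2)
  # all-zero cell
  expect_equal(unlist(qc["c2", c("n_umi", "n_gene", "pct_mito")],
                      use.names = FALSE), c(0, 0, 0))

  nomito <- counts[1:2, ]
  expect_warning(qc2 <- compute_qc(nomito), "MT-")
  expect_true(all(qc2$pct_mito == 0))
  expect_error(compute_qc(counts[, 0]), "empty")
})

test_that("compute_qc equals a straight-loop recomputation on a fixture", {
  sim <- small_sim(seed = 1, n_cells = 80, n_rare = 1, n_genes = 200)
  got <- compute_qc(sim$counts)
  exp <- oracle_qc(sim$counts)
  expect_equal(got$n_umi, exp$n_umi)
  expect_equal(got$n_gene, exp$n_gene)
  expect_equal(got$pct_mito, exp$pct_mito, tolerance = 1e-12)
})

test_that("filter_cells keeps exactly cells above the strict bound", {
  sim <- small_sim(seed = 2, n_cells = 100, n_rare = 0, n_genes = 300)
  qc <- compute_qc(sim$counts)
  thr <- as.integer(median(qc$n_gene))
  kept <- filter_cells(sim$counts, qc, min_genes = thr)
  expect_setequal(colnames(kept), qc$barcode[qc$n_gene > thr])
  # boundary: a cell with exactly min_genes detected genes is dropped
  expect_false(any(qc$n_gene[match(colnames(kept), qc$barcode)] == thr))
  expect_identical(rownames(kept), rownames(sim$counts))
  # min_genes = 0 keeps every cell with at least one detected gene
  all0 <- filter_cells(sim$counts, qc, min_genes = 0)
  expect_setequal(colnames(all0), qc$barcode[qc$n_gene > 0])
})

test_that("filter_cells erroring when nothing survives", {
  counts <- toy_counts()
  qc <- compute_qc(counts)
  expect_error(filter_cells(counts, qc, min_genes = 10), "no cells")
})

test_that("filter_genes honors the detected-cell threshold and min_cells=0
           identity", {
  sim <- small_sim(seed = 3, n_cells = 60, n_rare = 0, n_genes = 300)
  m <- sim$counts
  expect_identical(filter_genes(m, 0), m)
  kept <- filter_genes(m, 5)
  ncells <- Matrix::rowSums(m > 0)
  expect_setequal(rownames(kept), rownames(m)[ncells >= 5])
  # boundary: detected in exactly 5 cells is kept, 4 is dropped
  if (any(ncells == 5)) expect_true(rownames(m)[ncells == 5][1] %in%
                                      rownames(kept))
  if (any(ncells == 4)) expect_false(rownames(m)[ncells == 4][1] %in%
                                       rownames(kept))
})

test_that("lognormalize matches the closed form and a loop oracle", {
  counts <- toy_counts()
  ln <- lognormalize(counts, scale_factor = 1e4)
  expect_equal(ln["GENE1", "c1"], log(1 + 1e4 * 3 / 5))
  expect_true(all(ln[, "c2"] == 0))   # all-zero cell stays all-zero
  # closed form: total 100, count 10, sf 1e4 -> ln(1001)
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(10, 90),
                            dims = c(2, 1))
  dimnames(m) <- list(c("A", "B"), "c")
  expect_equal(lognormalize(m)["A", "c"], log(1001), tolerance = 1e-12)

  sim <- small_sim(seed = 5, n_cells = 50, n_rare = 1, n_genes = 200)
  expect_equal(as.matrix(lognormalize(sim$counts)),
               oracle_lognorm(sim$counts), tolerance = 1e-10)
})

test_that("regress_covariates produces exact-fit zeros, degenerate-design
           centering, and matches the normal-equations oracle", {
  sim <- small_sim(seed = 6, n_cells = 120, n_rare = 1, n_genes = 250)
  qc <- compute_qc(sim$counts)
  ln <- lognormalize(sim$counts)

  # gene perfectly linear in n_umi -> zero residuals
  fake <- rbind(ln[1:49, ], lin = 2 + 0.3 * qc$n_umi)
  res <- regress_covariates(fake, qc)
  expect_lt(max(abs(res["lin", ])), 1e-8)

  # zero-variance covariates -> residuals are just centered expression
  qc0 <- qc; qc0$n_umi <- 1000; qc0$pct_mito <- 0.05
  expect_warning(res0 <- regress_covariates(ln[1:20, ], qc0),
                 "zero-variance")
  expect_equal(res0, t(scale(t(as.matrix(ln[1:20, ])), scale = FALSE)),
               ignore_attr = TRUE, tolerance = 1e-10)

  # 50-gene fixture vs closed-form normal equations
  got <- regress_covariates(ln[1:50, ], qc)
  expect_equal(got, oracle_residuals(ln[1:50, ], qc), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("residuals are orthogonal to the technical covariates", {
  sim <- small_sim(seed = 7, n_cells = 150, n_rare = 1, n_genes = 300)
  qc <- compute_qc(sim$counts)
  res <- regress_covariates(lognormalize(sim$counts), qc)
  keep <- apply(res, 1, sd) > 0
  cors_umi <- abs(cor(t(res[keep, ]), qc$n_umi))
  cors_mito <- abs(cor(t(res[keep, ]), qc$pct_mito))
  expect_lt(max(cors_umi), 1e-6)
  expect_lt(max(cors_mito), 1e-6)
})

test_that("scale_genes centers, standardizes, caps, zeroes constants, and is
           idempotent when uncapped", {
  sim <- small_sim(seed = 8, n_cells = 100, n_rare = 1, n_genes = 200)
  x <- as.matrix(lognormalize(sim$counts))
  x <- rbind(x, konst = rep(4, ncol(x)))
  s <- scale_genes(x)
  nonconst <- apply(x, 1, sd) > 0
  expect_lt(max(abs(rowMeans(s[nonconst, ]))), 1e-8)
  expect_lt(max(abs(apply(s[nonconst, ], 1, var) - 1)), 1e-6)
  expect_true(all(s["konst", ] == 0))
  # idempotence
  expect_equal(scale_genes(s), s, tolerance = 1e-10)
  # capping clips exactly; uncapped keeps extreme leverage
  z <- matrix(c(rep(0, 199), 14), nrow = 1,
              dimnames = list("g", NULL))
  zs <- scale_genes(z)
  expect_gt(max(zs), 13)           # uncapped value stays extreme
  expect_equal(max(scale_genes(z, cap = 10)), 10)
  expect_equal(min(scale_genes(z, cap = 10)), max(-10, min(zs)))
})

test_that("select_hvg matches an independent straight-loop binning oracle
           and its within-bin z has mean zero", {
  sim <- small_sim(seed = 9, n_cells = 200, n_rare = 1, n_genes = 400)
  ln <- lognormalize(sim$counts)
  hvg <- select_hvg(ln, n_bins = 30, z_cutoff = 1)
  expect_setequal(hvg$gene[hvg$selected], oracle_hvg_selected(ln))
  for (b in unique(na.omit(hvg$bin))) {
    zb <- hvg$z_dispersion[!is.na(hvg$bin) & hvg$bin == b]
    if (length(zb) >= 2 && any(zb != 0)) expect_lt(abs(mean(zb)), 1e-8)
  }
  # zero-expression genes are unbinned and never selected
  expect_true(all(is.na(hvg$bin[hvg$mean_expr == 0])))
  expect_false(any(hvg$selected[hvg$mean_expr == 0]))
})

test_that("select_hvg degenerate inputs: identical genes select nothing,
           an extreme dispersion outlier is always selected", {
  m <- matrix(rep(c(0, 1, 2, 0), 25), nrow = 5, ncol = 20, byrow = TRUE)
  rownames(m) <- paste0("g", 1:5); colnames(m) <- paste0("c", 1:20)
  hvg <- select_hvg(Matrix::Matrix(m, sparse = TRUE), n_bins = 2,
                    z_cutoff = 0.5)
  expect_false(any(hvg$selected))

  sim <- small_sim(seed = 10, n_cells = 150, n_rare = 0, n_genes = 300)
  ln <- as.matrix(lognormalize(sim$counts))
  spike <- rep(0, ncol(ln)); spike[1:3] <- 8
  ln2 <- rbind(ln, SPIKE = spike)
  hvg2 <- select_hvg(ln2, n_bins = 10, z_cutoff = 1)
  expect_true(hvg2["SPIKE", "selected"])
})

test_that("the HVG lower mean bound discards the rare program the
           no-lower-limit setting retains", {
  # gene count kept at the default so the bin granularity (genes per
  # equal-frequency bin) matches the study conditions
  sim <- generate_dataset(sim_config(n_cells = 1500, n_rare = 2,
                                     n_genes = 3000, seed = 12))
  ln <- lognormalize(sim$counts)
  free <- select_hvg(ln, min_mean = NULL)
  bound <- select_hvg(ln, min_mean = 0.1)
  rp <- sim$programs$RARE
  expect_gte(mean(rp %in% free$gene[free$selected]), 0.8)
  expect_lt(mean(rp %in% bound$gene[bound$selected]), 0.3)
})
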