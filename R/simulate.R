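# Synthetic droplet scRNA-seq of CD45-depleted blood with spiked
# hepatocyte-like rare cells. Counts are gene-wise negative binomial with
# cell-specific library sizes; dropout arises naturally from low means.

# Hepatocyte program members observed across both patients' candidate CTCs,
# plus recurrently up-regulated HCC driver-like genes.
HEPATOCYTE_CORE_GENES <- c(
  "ALB", "TTR", "FABP1", "APOH", "FGB", "APOA2", "GSTA1", "SEPP1",
  "APOC1", "HPD", "ORM1", "HULC", "IGF2", "SPINK1", "SPP1"
)

MITO_GENES <- c(
  "MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5",
  "MT-CO1", "MT-CO2", "MT-CO3", "MT-CYB"
)

#' Simulation configuration for synthetic blood with spiked rare cells
#'
#' Builds and validates the parameter set of [generate_dataset()]. Defaults
#' emulate a CD45-depleted blood droplet run: ~5,000 cells across six blood
#' populations, per-cell library sizes log-normal around ~3,000 UMIs
#' (spanning roughly 1,000-28,000), a beta-distributed mitochondrial
#' fraction near 5%, and a handful of spiked rare cells carrying a
#' hepatocyte program (ALB, TTR, FABP1, ...) that is essentially absent from
#' the blood background.
#'
#' @param n_cells Number of background blood cells.
#' @param n_rare Number of spiked rare (hepatocyte-like) cells, added on top
#'   of `n_cells`.
#' @param n_genes Total genes in the matrix (includes population programs,
#'   the hepatocyte program, pan-leukocyte genes and `MT-` genes).
#' @param cluster_props Named fractions per blood population; must sum to 1.
#' @param program_size Marker genes per population program (also the size of
#'   the hepatocyte program: the named core genes padded with synthetic
#'   `HEPSIM` genes).
#' @param pop_log2fc log2 fold-elevation of a population's program genes
#'   within that population.
#' @param rare_log2fc log2 effect size of the rare-cell hepatic program; the
#'   per-gene weight in rare cells is `0.13 * 2^rare_log2fc` against a
#'   near-zero blood background, so the in/out fold exceeds
#'   `2^(rare_log2fc - 1)` for any setting.
#' @param libsize_lognormal_params `c(meanlog, sdlog)` of per-cell library
#'   size (total UMIs).
#' @param nb_dispersion Negative-binomial size (inverse-dispersion) shared
#'   by all genes.
#' @param mito_fraction_beta_params `c(a, b)` of the per-cell mitochondrial
#'   UMI fraction.
#' @param seed RNG seed for cell-level draws (library sizes, mito fractions,
#'   population assignment, counts).
#' @param gene_seed RNG seed for the gene model (baseline abundances, decoy
#'   draws); keep it fixed across samples that must share a gene universe.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 200, n_rare = 1, n_genes = 400)
#' sim <- generate_dataset(cfg)
#' dim(sim$counts)
sim_config <- function(n_cells = 5000L,
                       n_rare = 3L,
                       n_genes = 3000L,
                       cluster_props = c(T = 0.35, B = 0.12, NK = 0.10,
                                         monocyte = 0.30, pDC = 0.03,
                                         RBC = 0.10),
                       program_size = 20L,
                       pop_log2fc = 1.5,
                       rare_log2fc = 6,
                       libsize_lognormal_params = c(meanlog = 8.0, sdlog = 0.5),
                       nb_dispersion = 5,
                       mito_fraction_beta_params = c(a = 2.5, b = 47.5),
                       seed = 1L,
                       gene_seed = 20180801L) {
  cfg <- list(n_cells = as.integer(n_cells), n_rare = as.integer(n_rare),
              n_genes = as.integer(n_genes), cluster_props = cluster_props,
              program_size = as.integer(program_size),
              pop_log2fc = pop_log2fc, rare_log2fc = rare_log2fc,
              libsize_lognormal_params = libsize_lognormal_params,
              nb_dispersion = nb_dispersion,
              mito_fraction_beta_params = mito_fraction_beta_params,
              seed = as.integer(seed), gene_seed = as.integer(gene_seed))
  num <- unlist(cfg[c("cluster_props", "pop_log2fc", "rare_log2fc",
                      "libsize_lognormal_params", "nb_dispersion",
                      "mito_fraction_beta_params")])
  if (any(!is.finite(num))) stop("sim_config: non-finite parameters")
  if (cfg$n_cells < 0 || cfg$n_rare < 0 || cfg$n_genes < 0 ||
      cfg$program_size < 0)
    stop("sim_config: counts must be >= 0")
  if (cfg$n_rare > cfg$n_cells && cfg$n_cells > 0)
    stop("sim_config: n_rare exceeds n_cells")
  if (cfg$n_rare > 0 && cfg$n_cells == 0)
    stop("sim_config: n_rare exceeds n_cells")
  if (is.null(names(cfg$cluster_props)) || any(names(cfg$cluster_props) == ""))
    stop("sim_config: cluster_props must be named")
  if (abs(sum(cfg$cluster_props) - 1) > 1e-12)
    stop("sim_config: cluster_props must sum to 1")
  if (cfg$nb_dispersion <= 0) stop("sim_config: nb_dispersion must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

# Gene universe shared by all samples drawn from the same gene_seed:
# symbols, baseline relative abundances, program memberships.
build_gene_model <- function(config) {
  pops <- names(config$cluster_props)
  psz <- config$program_size
  hep <- if (psz >= length(HEPATOCYTE_CORE_GENES)) {
    c(HEPATOCYTE_CORE_GENES,
      sprintf("HEPSIM%03d", seq_len(psz - length(HEPATOCYTE_CORE_GENES))))
  } else {
    HEPATOCYTE_CORE_GENES[seq_len(max(psz, 1L))]
  }
  leuk <- c("PTPRC", sprintf("LEUK%02d", 1:9))
  prog <- lapply(pops, function(p) sprintf("%s.PRG%03d", p, seq_len(psz)))
  names(prog) <- pops
  reserved <- c(unlist(prog, use.names = FALSE), hep, leuk, MITO_GENES)
  n_fill <- config$n_genes - length(reserved)
  if (n_fill < 0)
    stop("sim_config: n_genes too small for the configured programs (need >= ",
         length(reserved), ")")
  fill <- sprintf("GENE%05d", seq_len(n_fill))
  symbols <- c(unlist(prog, use.names = FALSE), hep, leuk, fill, MITO_GENES)

  base <- with_seed_(config$gene_seed, {
    # heavy-tailed abundances, floored so every background gene is seen in
    # a few dozen cells: droplet matrices are cell-called and gene-filtered
    # upstream, so genes private to 1-3 cells are not part of the
    # background; the hepatocyte program is the only near-zero class
    pmax(stats::rgamma(length(symbols), shape = 0.25, rate = 1), 0.0015)
  })
  names(base) <- symbols
  base[unlist(prog, use.names = FALSE)] <- 0.5
  base[hep] <- 0            # hepatic genes are absent in blood
  base[leuk] <- 3.0         # pan-leukocyte housekeeping-level expression
  base[MITO_GENES] <- 1.0   # relative weights within the mito block only

  list(symbols = symbols, base = base, programs = prog, hepatocyte = hep,
       leukocyte = leuk, mito = MITO_GENES,
       is_mito = symbols %in% MITO_GENES)
}

# Per-population expected relative profile over non-mito genes (sums to 1).
population_profiles <- function(model, config) {
  pops <- names(config$cluster_props)
  nonmito <- !model$is_mito
  profs <- lapply(pops, function(p) {
    w <- model$base
    w[model$programs[[p]]] <- w[model$programs[[p]]] * 2^config$pop_log2fc
    w <- w[nonmito]
    w / sum(w)
  })
  names(profs) <- pops
  w <- model$base
  w[model$hepatocyte] <- 0.13 * 2^config$rare_log2fc
  w[model$leukocyte] <- w[model$leukocyte] / 2  # emulate CD45-low phenotype
  w <- w[nonmito]
  profs$RARE <- w / sum(w)
  profs
}

#' Generate a ground-truthed synthetic spiked-CTC dataset
#'
#' Draws a sparse gene-by-cell UMI count matrix of blood populations with
#' `n_rare` spiked hepatocyte-like cells, together with a per-cell truth
#' table. Counts are negative binomial with mean `L_c * p_c(g)`, where `L_c`
#' is a log-normal library size and `p_c` mixes the cell's population profile
#' with a block of `MT-` genes at the cell's beta-distributed mitochondrial
#' fraction, so the expected per-cell total equals `L_c` and per-cell QC
#' covariates are non-trivial. Identical `config` (including seeds) gives
#' bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `ctc_sim`: `counts` (dgCMatrix, genes x cells),
#'   `truth` (data.frame: `barcode`, `population`, with `RARE` rows for the
#'   spiked cells), `programs` (named list of per-population program genes,
#'   including `RARE`), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  model <- build_gene_model(config)
  n_total <- config$n_cells + config$n_rare
  if (n_total == 0) {
    counts <- Matrix::sparseMatrix(i = integer(), j = integer(), x = integer(),
                                   dims = c(config$n_genes, 0))
    rownames(counts) <- model$symbols
    colnames(counts) <- character(0)
    truth <- data.frame(barcode = character(0), population = character(0),
                        stringsAsFactors = FALSE)
    programs <- c(model$programs, list(RARE = model$hepatocyte))
    out <- list(counts = counts, truth = truth, programs = programs,
                config = config)
    class(out) <- "ctc_sim"
    return(out)
  }

  pops <- names(config$cluster_props)
  profs <- population_profiles(model, config)
  meanlog <- config$libsize_lognormal_params[[1]]
  sdlog <- config$libsize_lognormal_params[[2]]
  a <- config$mito_fraction_beta_params[[1]]
  b <- config$mito_fraction_beta_params[[2]]
  mito_w <- model$base[model$mito] / sum(model$base[model$mito])
  nonmito <- !model$is_mito

  dense <- with_seed_(config$seed, {
    # deterministic draw order: assignment, library sizes, mito fractions,
    # then counts population-block by population-block
    n_per <- diff(round(cumsum(c(0, config$cluster_props)) * config$n_cells))
    n_per[length(n_per)] <- config$n_cells - sum(n_per[-length(n_per)])
    pop_of <- sample(rep(pops, times = n_per))
    pop_of <- c(pop_of, rep("RARE", config$n_rare))
    L <- stats::rlnorm(n_total, meanlog, sdlog)
    f <- stats::rbeta(n_total, a, b)
    m <- matrix(0, nrow = config$n_genes, ncol = n_total)
    for (p in c(pops, "RARE")) {
      idx <- which(pop_of == p)
      if (!length(idx)) next
      block <- matrix(0, nrow = config$n_genes, ncol = length(idx))
      block[nonmito, ] <- outer(profs[[p]], L[idx] * (1 - f[idx]))
      block[!nonmito, ] <- outer(mito_w, L[idx] * f[idx])
      m[, idx] <- stats::rnbinom(length(block), size = config$nb_dispersion,
                                 mu = block)
    }
    attr(m, "pop_of") <- pop_of
    m
  })

  pop_of <- attr(dense, "pop_of")
  attr(dense, "pop_of") <- NULL
  barcodes <- sprintf("BC%06d", seq_len(n_total))
  counts <- methods::as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
  rownames(counts) <- model$symbols
  colnames(counts) <- barcodes
  truth <- data.frame(barcode = barcodes, population = pop_of,
                      stringsAsFactors = FALSE)
  programs <- c(model$programs, list(RARE = model$hepatocyte))
  out <- list(counts = counts, truth = truth, programs = programs,
              config = config)
  class(out) <- "ctc_sim"
  out
}

#' Emit per-population gene sets (plus decoys) for GSEA testing
#'
#' One gene set per population program of a simulated dataset, plus
#' `n_decoys` decoy sets of genes sampled uniformly from the gene universe.
#' Programs with fewer than 5 genes are omitted with a warning (GMT sets
#' below that size are not meaningful to score).
#'
#' @param x A `ctc_sim` from [generate_dataset()], or a named list of
#'   program gene vectors.
#' @param gene_universe Symbols decoys are drawn from; defaults to the
#'   simulation's gene roster.
#' @param n_decoys Number of decoy sets.
#' @param decoy_size Genes per decoy set; defaults to the median program size.
#' @param seed Seed for decoy sampling.
#' @return Named list of character vectors (a gene set collection).
#' @export
emit_gene_sets <- function(x, gene_universe = NULL, n_decoys = 20L,
                           decoy_size = NULL, seed = 1L) {
  if (inherits(x, "ctc_sim")) {
    programs <- x$programs
    if (is.null(gene_universe)) gene_universe <- rownames(x$counts)
  } else {
    programs <- x
  }
  if (!length(programs)) stop("emit_gene_sets: no population programs")
  keep <- vapply(programs, length, integer(1)) >= 5
  if (any(!keep))
    warning("emit_gene_sets: omitting sets with < 5 genes: ",
            paste(names(programs)[!keep], collapse = ", "))
  sets <- programs[keep]
  names(sets) <- paste0(names(sets), "_program")
  if (n_decoys > 0) {
    if (is.null(gene_universe))
      stop("emit_gene_sets: gene_universe required for decoy sets")
    if (is.null(decoy_size))
      decoy_size <- max(5L, as.integer(stats::median(lengths(sets))))
    decoys <- with_seed_(seed, lapply(seq_len(n_decoys), function(i)
      sample(gene_universe, decoy_size)))
    names(decoys) <- sprintf("DECOY%02d", seq_len(n_decoys))
    sets <- c(sets, decoys)
  }
  sets
}

#' Write a simulated dataset as a 10X-style fixture directory
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `truth.tsv` and
#' `sets.gmt` into `dir`.
#'
#' @param sim A `ctc_sim`.
#' @param dir Output directory (created if needed).
#' @param force Overwrite an existing non-empty directory.
#' @param ... Passed to [emit_gene_sets()].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, force = FALSE, ...) {
  stopifnot(inherits(sim, "ctc_sim"))
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("write_dataset: ", dir, " is non-empty (use force = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mtx_triplet(sim$counts, dir)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(emit_gene_sets(sim, ...), file.path(dir, "sets.gmt"))
  invisible(dir)
}
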