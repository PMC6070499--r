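# Readers/writers for the standard formats the pipeline touches:
# Matrix Market gene x cell triplets (10X convention), GMT gene sets,
# and headered TSV result tables.

# Duplicate labels get ".1", ".2", ... suffixes; keeps keys unique
# without dropping data.
dedup_labels <- function(x) {
  if (!anyDuplicated(x)) return(x)
  make.unique(x, sep = ".")
}

#' Read a 10X-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx`, `genes.tsv` (gene_id TAB gene_symbol, or a single
#' symbol column) and `barcodes.tsv`. The matrix is returned oriented genes
#' x cells regardless of the on-disk orientation, inferred from the label
#' counts; 1-based Matrix Market indices become R indices. Entries are kept
#' sparse throughout (never densified).
#'
#' @param dir_path Directory holding the three files.
#' @return A `dgCMatrix` with gene symbols as rownames (de-duplicated with
#'   `.1`, `.2`, ... suffixes) and barcodes as colnames; gene ids, when
#'   present, are attached as `attr(, "gene_ids")`.
#' @export
read_mtx_triplet <- function(dir_path) {
  paths <- file.path(dir_path, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  names(paths) <- basename(paths)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("read_mtx_triplet: missing ", paste(names(paths)[missing],
                                             collapse = ", "))
  m <- Matrix::readMM(paths[["matrix.mtx"]])
  if (any(m@x != round(m@x)))
    stop("read_mtx_triplet: non-integer entries in matrix.mtx")
  if (any(m@x < 0))
    stop("read_mtx_triplet: negative entries in matrix.mtx")
  genes <- utils::read.delim(paths[["genes.tsv"]], header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(paths[["barcodes.tsv"]], header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  symbols <- if (ncol(genes) >= 2) genes[[2]] else genes[[1]]
  gene_ids <- genes[[1]]

  if (nrow(m) == length(symbols) && ncol(m) == length(barcodes)) {
    # on-disk already genes x cells
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(symbols)) {
    m <- Matrix::t(m)
  } else if (nrow(m) == length(symbols)) {
    stop("read_mtx_triplet: barcodes.tsv has ", length(barcodes),
         " labels but matrix.mtx has ", ncol(m), " columns")
  } else {
    stop("read_mtx_triplet: genes.tsv has ", length(symbols),
         " labels but matrix.mtx is ", nrow(m), " x ", ncol(m))
  }
  m <- methods::as(m, "CsparseMatrix")
  rownames(m) <- dedup_labels(symbols)
  colnames(m) <- dedup_labels(barcodes)
  attr(m, "gene_ids") <- gene_ids
  m
}

#' Write a count matrix as a 10X-style Matrix Market triplet
#'
#' @param counts Sparse genes x cells matrix with dimnames.
#' @param dir_path Output directory (created if needed).
#' @param gene_ids Optional ids for the first `genes.tsv` column; defaults
#'   to the gene symbols.
#' @return `dir_path`, invisibly.
#' @export
write_mtx_triplet <- function(counts, dir_path, gene_ids = NULL) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts@x < 0)) stop("write_mtx_triplet: negative counts")
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(counts, "dMatrix"), "TsparseMatrix")
  # writeMM emits "real" for double storage; counts are integers, so write
  # the coordinate file directly with an integer field declaration
  mtx <- file.path(dir_path, "matrix.mtx")
  con <- file(mtx, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x)) {
    ord <- order(m@j, m@i)
    writeLines(sprintf("%d %d %d", m@i[ord] + 1L, m@j[ord] + 1L,
                       as.integer(m@x[ord])), con)
  }
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  utils::write.table(data.frame(gene_ids, rownames(counts)),
                     file.path(dir_path, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

#' Read a GMT gene-set collection
#'
#' Lines are `set_name TAB description TAB gene...`. Duplicate genes within
#' a set are collapsed (first occurrence kept); lines with fewer than three
#' fields are skipped with a warning.
#'
#' @param path GMT file.
#' @return Named list of character vectors; empty file gives an empty list.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(list(), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    warning("read_gmt: skipping ", sum(short), " line(s) with < 3 fields")
    fields <- fields[!short]
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names(sets)))
    stop("read_gmt: duplicate set names in ", path)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional per-set description column; defaults to "na".
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  stopifnot(length(descriptions) == length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as headered TSV
#'
#' First line is a `#` comment naming the producing operation and the
#' resolved-config fingerprint, then a standard header row.
#'
#' @param df Data frame.
#' @param path Output file.
#' @param producer Name of the producing operation.
#' @param config Optional resolved pipeline config; fingerprinted into the
#'   comment line.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, producer = "ctcseek",
                             config = NULL) {
  hash <- if (is.null(config)) "none" else config_hash(config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# producer=%s config_hash=%s", producer, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV written by [write_result_tsv()]
#' @param path File path.
#' @return Data frame.
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
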