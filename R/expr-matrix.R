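#' Genes-by-cells expression matrix with per-cell metadata
#'
#' Thin container pairing a genes x cells value matrix (UMI counts or TPM)
#' with a per-cell metadata tibble. The two QC covariates used throughout —
#' `genes_detected` (genes with any signal in the cell) and `mapped_fraction`
#' — are computed from the values when not supplied.
#'
#' @param values Numeric matrix or `Matrix::dgCMatrix`, genes in rows, cells
#'   in columns, with unique dimnames.
#' @param metadata Tibble with one row per cell; must contain `cell_id`
#'   matching `colnames(values)`. Extra columns (condition, mouse, timepoint)
#'   are carried along untouched.
#' @param units `"counts"` or `"TPM"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, metadata = NULL, units = c("counts", "TPM")) {
  units <- match.arg(units)
  check_that(!is.null(rownames(values)) && !is.null(colnames(values)),
             "values must have gene rownames and cell colnames")
  check_that(!anyDuplicated(rownames(values)) &&
               !anyDuplicated(colnames(values)), "gene and cell ids must be unique")
  check_that(min(values) >= 0, "expression values must be non-negative")
  if (is.null(metadata)) metadata <- tibble(cell_id = colnames(values))
  metadata <- as_tibble(metadata)
  check_that("cell_id" %in% names(metadata) &&
               setequal(metadata$cell_id, colnames(values)) &&
               nrow(metadata) == ncol(values),
             "metadata must have one row per cell keyed by cell_id")
  metadata <- metadata[match(colnames(values), metadata$cell_id), ]
  if (!"genes_detected" %in% names(metadata))
    metadata$genes_detected <- Matrix::colSums(values > 0)
  if (!"mapped_fraction" %in% names(metadata))
    metadata$mapped_fraction <- 1
  check_that(all(metadata$mapped_fraction >= 0 & metadata$mapped_fraction <= 1),
             "mapped_fraction must lie in [0, 1]")
  structure(list(values = values, metadata = metadata, units = units),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values), x$units))
  cat("  metadata: ", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or cell ids
#'
#' @param m An [expr_matrix()].
#' @param genes,cells Character ids to keep (`NULL` keeps all).
#' @return An [expr_matrix()].
#' @export
em_subset <- function(m, genes = NULL, cells = NULL) {
  genes <- genes %||% rownames(m$values)
  cells <- cells %||% colnames(m$values)
  check_that(all(genes %in% rownames(m$values)), "unknown gene ids")
  check_that(all(cells %in% colnames(m$values)), "unknown cell ids")
  v <- m$values[genes, cells, drop = FALSE]
  md <- m$metadata[match(cells, m$metadata$cell_id), ]
  out <- expr_matrix(v, md, units = m$units)
  # keep precomputed covariates from the parent rather than recomputing on
  # the gene subset
  out$metadata <- md
  out
}

#' Per-cell metadata as a tibble
#' @param m An [expr_matrix()].
#' @return A tibble, one row per cell.
#' @export
cell_metadata <- function(m) m$metadata

#' Convert a count matrix to TPM
#'
#' Transcript-per-million normalisation with all effective gene lengths
#' equal: each cell is scaled to a total of 1e6. Length correction is
#' irrelevant to every downstream statistic used here (detection, log-scale
#' group contrasts), so lengths are not modelled.
#'
#' @param m An [expr_matrix()] of counts.
#' @return An [expr_matrix()] in TPM units.
#' @export
counts_to_tpm <- function(m) {
  check_that(m$units == "counts", "input must be counts")
  tot <- Matrix::colSums(m$values)
  check_that(all(tot > 0), "every cell needs at least one count")
  v <- sweep(as.matrix(m$values), 2, tot, "/") * 1e6
  out <- expr_matrix(v, m$metadata, units = "TPM")
  out$metadata <- m$metadata
  out
}

#' Write an expression matrix as MatrixMarket + TSV + CSV
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `metadata.csv` into
#' `dir` (the 10x-style plain-text layout).
#'
#' @param m An [expr_matrix()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_expr_mtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- methods::as(methods::as(Matrix::Matrix(m$values, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(v, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$values), file.path(dir, "genes.tsv"))
  writeLines(colnames(m$values), file.path(dir, "barcodes.tsv"))
  utils::write.csv(m$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  writeLines(m$units, file.path(dir, "units.txt"))
  invisible(dir)
}

#' Read an expression matrix written by [write_expr_mtx()]
#' @param dir Directory containing the files.
#' @return An [expr_matrix()].
#' @export
read_expr_mtx <- function(dir) {
  v <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(v) <- readLines(file.path(dir, "genes.tsv"))
  colnames(v) <- readLines(file.path(dir, "barcodes.tsv"))
  md <- as_tibble(utils::read.csv(file.path(dir, "metadata.csv")))
  units <- readLines(file.path(dir, "units.txt"))[1]
  expr_matrix(v, md, units = units)
}
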