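#' Construct an expression matrix container
#'
#' @param counts Sparse gene x barcode matrix of UMI-collapsed molecule
#'   counts (`dgCMatrix`).
#' @param reads Optional parallel sparse matrix of raw read support.
#' @return An object of class `expression_matrix`.
#' @noRd
new_expression_matrix <- function(counts, reads = NULL) {
  counts <- methods::as(counts, "CsparseMatrix")
  if (!is.null(reads)) {
    reads <- methods::as(reads, "CsparseMatrix")
    stopifnot(identical(dim(counts), dim(reads)))
  }
  structure(list(counts = counts, reads = reads),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "barcodes;", sum(x$counts), "molecules",
      if (!is.null(x$reads)) paste0("(", sum(x$reads), " reads)"), "\n")
  invisible(x)
}

#' UMI-collapsed quantification of tagged reads
#'
#' Each read's barcode is replaced through the whitelist's repair map;
#' reads whose barcode cannot be assigned are dropped. For every
#' (gene, assigned barcode) cell, `counts` holds the number of distinct
#' UMI sequences observed (molecules) and `reads` the raw read support.
#' UMI collapse is exact sequence identity — no UMI error correction is
#' attempted, so two molecules that drew the same UMI by chance merge into
#' one (a documented slight undercount).
#'
#' @param reads Tagged reads (data.frame with `barcode`, `umi`, `gene`).
#'   The `barcode` column holds observed (possibly error-bearing)
#'   barcodes.
#' @param whitelist A [repair_barcodes()]-completed whitelist.
#' @param genes Optional gene universe for the row set (rows for genes
#'   never observed are retained as all-zero); defaults to the genes seen
#'   in `reads`, sorted.
#' @return An `expression_matrix` whose columns are the whitelist entries
#'   in rank order (all retained, even if empty).
#' @export
count_molecules <- function(reads, whitelist, genes = NULL) {
  stopifnot(inherits(whitelist, "whitelist"),
            all(c("barcode", "umi", "gene") %in% names(reads)))
  entries <- whitelist$entries
  dt <- data.table::data.table(
    barcode = whitelist$repair_map[reads$barcode],
    umi = reads$umi,
    gene = reads$gene
  )
  dt <- dt[!is.na(dt$barcode)]
  if (is.null(genes)) genes <- sort(unique(dt$gene))
  umi <- NULL  # data.table NSE
  cell <- dt[, list(n_umi = data.table::uniqueN(umi), n_reads = .N),
             by = c("gene", "barcode")]
  i <- match(cell$gene, genes)
  j <- match(cell$barcode, entries)
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = cell$n_umi,
    dims = c(length(genes), length(entries)),
    dimnames = list(genes, entries)
  )
  readm <- Matrix::sparseMatrix(
    i = i, j = j, x = cell$n_reads,
    dims = c(length(genes), length(entries)),
    dimnames = list(genes, entries)
  )
  new_expression_matrix(counts, readm)
}

#' Number of expressed genes per barcode
#'
#' A gene counts as expressed in a barcode iff its support reaches
#' `min_reads_per_gene`, measured on read support when available
#' (`unit = "reads"`, the default) or on molecule counts
#' (`unit = "transcripts"`).
#'
#' @param matrix An `expression_matrix`.
#' @param min_reads_per_gene Minimum support. Default 1.
#' @param unit `"reads"` or `"transcripts"`.
#' @return Named integer vector over barcodes.
#' @export
genes_per_barcode <- function(matrix, min_reads_per_gene = 1L,
                              unit = c("reads", "transcripts")) {
  unit <- match.arg(unit)
  m <- if (unit == "reads" && !is.null(matrix$reads)) matrix$reads
       else matrix$counts
  Matrix::colSums(m >= min_reads_per_gene)
}

#' Apply the per-barcode expression filters
#'
#' Removes barcodes expressing fewer than `min_genes_per_barcode` genes,
#' where a gene is expressed iff its support is at least
#' `min_reads_per_gene` (defaults 200 and 1: the "min. 1 read per gene,
#' min. 200 genes per nuclei" cutoffs). Gene rows are retained, possibly
#' all-zero, so filtered matrices stay alignable by gene set. The
#' operation is idempotent.
#'
#' @param matrix An `expression_matrix`.
#' @param min_reads_per_gene Support needed for a gene to count as
#'   expressed. Default 1.
#' @param min_genes_per_barcode Minimum expressed genes per barcode.
#'   Default 200.
#' @param unit Support measure for the expressed-gene test; `"reads"`
#'   (default) or `"transcripts"`.
#' @return The filtered `expression_matrix`.
#' @export
apply_barcode_filters <- function(matrix, min_reads_per_gene = 1L,
                                  min_genes_per_barcode = 200L,
                                  unit = c("reads", "transcripts")) {
  if (min_reads_per_gene < 0 || min_genes_per_barcode < 0) {
    stop("filter thresholds must be non-negative")
  }
  unit <- match.arg(unit)
  if (unit == "reads" && min_reads_per_gene > 1L && is.null(matrix$reads)) {
    stop("read support unavailable: matrix has no `reads` component")
  }
  ng <- genes_per_barcode(matrix, min_reads_per_gene, unit)
  keep <- ng >= min_genes_per_barcode
  new_expression_matrix(
    matrix$counts[, keep, drop = FALSE],
    if (!is.null(matrix$reads)) matrix$reads[, keep, drop = FALSE]
  )
}

#' Write an expression matrix as a MatrixMarket triplet
#'
#' Writes `matrix.mtx` (UMI counts), `features.tsv` (one gene per line)
#' and `barcodes.tsv` (one barcode per line); read support, when present,
#' goes to `read_support.mtx`.
#'
#' @param matrix An `expression_matrix`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_matrix_dir <- function(matrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(matrix$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(matrix$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(matrix$counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(matrix$reads)) {
    Matrix::writeMM(matrix$reads, file.path(dir, "read_support.mtx"))
  }
  invisible(dir)
}

#' Read an expression matrix from a MatrixMarket triplet directory
#'
#' @param dir Directory written by [write_matrix_dir()].
#' @return An `expression_matrix`.
#' @export
read_matrix_dir <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  dimnames(counts) <- list(readLines(file.path(dir, "features.tsv")),
                           readLines(file.path(dir, "barcodes.tsv")))
  reads <- NULL
  rp <- file.path(dir, "read_support.mtx")
  if (file.exists(rp)) {
    reads <- methods::as(Matrix::readMM(rp), "CsparseMatrix")
    dimnames(reads) <- dimnames(counts)
  }
  new_expression_matrix(counts, reads)
}
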