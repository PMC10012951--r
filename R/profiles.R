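#' Read-region QC fractions
#'
#' Fraction of mapped reads falling in exonic, intronic, intergenic and
#' mitochondrial regions (each read counted once; mitochondrial is its
#' own exclusive category). Nuclei libraries typically show a much larger
#' intronic fraction than whole cells, reflecting unspliced nuclear RNA.
#'
#' @param reads Tagged reads (data.frame with a `region` column).
#' @return An object of class `region_summary`: list with `n_mapped` and
#'   `fractions` (named over the four categories, summing to 1).
#' @export
region_fractions <- function(reads) {
  if (NROW(reads) == 0L) stop("empty read collection")
  stopifnot("region" %in% names(reads))
  bad <- setdiff(unique(reads$region), region_levels())
  if (length(bad)) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  }
  tab <- table(factor(reads$region, levels = region_levels()))
  n <- sum(tab)
  structure(
    list(n_mapped = as.integer(n),
         fractions = stats::setNames(as.numeric(tab) / n, region_levels())),
    class = "region_summary"
  )
}

#' @export
print.region_summary <- function(x, ...) {
  cat("region_summary over", x$n_mapped, "mapped reads:\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Per-gene mean log-transformed expression
#'
#' For each gene, the mean over barcodes of `log(count + 1)` (natural
#' log; zeros included in the mean). The log base does not affect Pearson
#' correlations downstream (affine invariance).
#'
#' @param matrix An `expression_matrix` with at least one barcode.
#' @return Named numeric vector over genes.
#' @export
mean_log_expression <- function(matrix) {
  m <- matrix$counts
  if (ncol(m) == 0L) stop("matrix has no barcodes")
  v <- Matrix::rowSums(log1p(m)) / ncol(m)
  stats::setNames(as.numeric(v), rownames(m))
}

#' Pair two per-gene vectors over a common gene set
#'
#' @noRd
pair_gene_vectors <- function(means_a, means_b,
                              pairing = c("union", "intersection")) {
  pairing <- match.arg(pairing)
  if (is.null(names(means_a)) || is.null(names(means_b))) {
    if (length(means_a) != length(means_b)) {
      stop("unnamed vectors must have equal length")
    }
    return(list(a = as.numeric(means_a), b = as.numeric(means_b),
                genes = paste0("g", seq_along(means_a))))
  }
  genes <- if (pairing == "union") {
    union(names(means_a), names(means_b))
  } else {
    intersect(names(means_a), names(means_b))
  }
  a <- stats::setNames(numeric(length(genes)), genes)
  b <- a
  a[intersect(genes, names(means_a))] <-
    means_a[intersect(genes, names(means_a))]
  b[intersect(genes, names(means_b))] <-
    means_b[intersect(genes, names(means_b))]
  list(a = as.numeric(a), b = as.numeric(b), genes = genes)
}

#' Pearson concordance between two expression profiles
#'
#' Pearson correlation between paired per-gene mean log expressions, with
#' the two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. Genes are paired by name over the union of
#' the two gene sets with absent genes as 0 (or the intersection, by
#' choice); unnamed vectors are paired positionally. P-values below
#' 2.2e-16 are reported as `"< 2.2e-16"` in the summary string.
#'
#' @param means_a,means_b Per-gene vectors (e.g. from
#'   [mean_log_expression()]).
#' @param pairing `"union"` (absent genes count 0; default) or
#'   `"intersection"`.
#' @return An object of class `concordance`: list with `n_genes`, `r`,
#'   `p_value`, `p_report` (formatted), and the paired vectors
#'   `per_gene_means_a`, `per_gene_means_b` (named by gene).
#' @export
pearson_concordance <- function(means_a, means_b,
                                pairing = c("union", "intersection")) {
  pr <- pair_gene_vectors(means_a, means_b, match.arg(pairing))
  n <- length(pr$a)
  if (n < 3L) stop("need at least 3 paired genes for a p-value")
  if (stats::sd(pr$a) == 0 || stats::sd(pr$b) == 0) {
    stop("constant vector: correlation undefined")
  }
  da <- pr$a - mean(pr$a)
  db <- pr$b - mean(pr$b)
  r <- sum(da * db) / sqrt(sum(da^2) * sum(db^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  p_floor <- max(p, .Machine$double.xmin)
  structure(
    list(
      n_genes = n, r = r, p_value = p_floor,
      p_report = if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 3),
      per_gene_means_a = stats::setNames(pr$a, pr$genes),
      per_gene_means_b = stats::setNames(pr$b, pr$genes)
    ),
    class = "concordance"
  )
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance over %d genes: R = %.4f, p %s\n",
              x$n_genes, x$r,
              if (startsWith(x$p_report, "<")) x$p_report
              else paste("=", x$p_report)))
  invisible(x)
}

#' Genes deviating between two expression profiles
#'
#' A declared stand-in for per-gene differential expression: genes whose
#' mean log expression differs by at least `min_abs_diff` between the two
#' profiles, ranked by absolute difference. Highlights transcripts
#' enriched in one fraction but not the other (e.g. nuclear lncRNAs vs
#' mitochondrial transcripts).
#'
#' @param means_a,means_b Per-gene vectors, paired as in
#'   [pearson_concordance()].
#' @param min_abs_diff Non-negative threshold on `|mean_a - mean_b|`.
#' @param pairing `"union"` or `"intersection"`.
#' @return Data.frame with `gene`, `mean_a`, `mean_b`, `abs_diff`, sorted
#'   by `abs_diff` descending.
#' @export
deviating_genes <- function(means_a, means_b, min_abs_diff,
                            pairing = c("union", "intersection")) {
  if (min_abs_diff < 0) stop("`min_abs_diff` must be non-negative")
  pr <- pair_gene_vectors(means_a, means_b, match.arg(pairing))
  d <- abs(pr$a - pr$b)
  keep <- d >= min_abs_diff
  out <- data.frame(
    gene = pr$genes[keep],
    mean_a = pr$a[keep],
    mean_b = pr$b[keep],
    abs_diff = d[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$abs_diff, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
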