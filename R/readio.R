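#' Parse the DroNc-seq read-1 structure
#'
#' Read 1 of a DroNc-seq library carries, in order, a 12 nt bead barcode,
#' an 8 nt UMI, a single anchor base that must be A, C or G (the "V" base
#' preceding the poly-T stretch) and then poly-T out to the 26th cycle.
#' A read is structurally valid iff it is at least
#' `barcode_length + umi_length + 1 + polyt_window` bases long, carries no
#' `N` in the barcode or UMI, has anchor in `{A, C, G}`, and at least
#' `min_polyt` of the `polyt_window` bases after the anchor are `T`.
#'
#' The function is total: every input sequence yields exactly one row,
#' either valid or carrying one reject reason. When several defects are
#' present the reported reason follows the fixed precedence
#' `TOO_SHORT`, `AMBIGUOUS_BASE`, `BAD_ANCHOR`, `BAD_POLYT`.
#'
#' @param sequences Character vector of read-1 sequences over
#'   `{A,C,G,T,N}`.
#' @param barcode_length,umi_length Segment widths; defaults 12 and 8.
#' @param min_polyt Minimum number of `T` bases required in the window
#'   after the anchor. Default 4 of 5, tolerating one sequencing error in
#'   the observable poly-T stretch of a 26-cycle read.
#' @param polyt_window Number of bases inspected after the anchor.
#' @return A data.frame with one row per sequence: `barcode`, `umi`,
#'   `anchor`, `valid`, and `reject_reason` (`NA` when valid, otherwise
#'   one of `TOO_SHORT`, `AMBIGUOUS_BASE`, `BAD_ANCHOR`, `BAD_POLYT`).
#' @export
parse_read1 <- function(sequences, barcode_length = 12L, umi_length = 8L,
                        min_polyt = 4L, polyt_window = 5L) {
  sequences <- as.character(sequences)
  bl <- as.integer(barcode_length)
  ul <- as.integer(umi_length)
  need <- bl + ul + 1L + as.integer(polyt_window)
  len <- nchar(sequences)

  barcode <- substr(sequences, 1L, bl)
  umi <- substr(sequences, bl + 1L, bl + ul)
  anchor <- substr(sequences, bl + ul + 1L, bl + ul + 1L)
  tail5 <- substr(sequences, bl + ul + 2L, bl + ul + 1L + polyt_window)
  n_t <- nchar(tail5) - nchar(gsub("T", "", tail5, fixed = TRUE))

  reason <- rep(NA_character_, length(sequences))
  reason[n_t < min_polyt] <- "BAD_POLYT"
  reason[!anchor %in% c("A", "C", "G")] <- "BAD_ANCHOR"
  reason[grepl("N", barcode, fixed = TRUE) |
           grepl("N", umi, fixed = TRUE)] <- "AMBIGUOUS_BASE"
  reason[len < need] <- "TOO_SHORT"

  data.frame(
    barcode = barcode, umi = umi, anchor = anchor,
    valid = is.na(reason), reject_reason = reason,
    stringsAsFactors = FALSE
  )
}

reject_reasons <- function() {
  c("TOO_SHORT", "AMBIGUOUS_BASE", "BAD_ANCHOR", "BAD_POLYT")
}

#' Read a tagged-read table
#'
#' The tagged-read TSV is the hand-off format between alignment/annotation
#' (or the simulator) and quantification: one row per sequenced molecule
#' observation with its barcode, UMI, gene, genome of origin and genomic
#' region. The header must contain `barcode`, `umi`, `gene`, `genome` and
#' `region` (`species` is accepted as an alias for `genome`; extra columns
#' are carried along). Region labels must be one of `exonic`, `intronic`,
#' `intergenic`, `mitochondrial`.
#'
#' @param path Path to a TSV file (plain or gzip).
#' @return A data.frame of tagged reads in file order.
#' @export
load_tagged_reads <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  str_cols <- intersect(c("barcode", "umi", "gene", "genome", "species",
                          "region"), header)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = stats::setNames(
                            rep("character", length(str_cols)), str_cols),
                          data.table = FALSE, showProgress = FALSE)
  if ("species" %in% names(dt) && !"genome" %in% names(dt)) {
    names(dt)[names(dt) == "species"] <- "genome"
  }
  required <- c("barcode", "umi", "gene", "genome", "region")
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    stop("tagged-read file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(dt)) {
    bad <- which(!dt$region %in% region_levels())
    if (length(bad)) {
      stop("unknown region label ", dQuote(dt$region[bad[1]]),
           " at row ", bad[1], "; expected one of: ",
           paste(region_levels(), collapse = ", "))
    }
  }
  dt
}

#' Write a tagged-read table
#'
#' @param reads Data.frame with at least the columns `barcode`, `umi`,
#'   `gene`, `genome`, `region`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_tagged_reads <- function(reads, path) {
  stopifnot(all(c("barcode", "umi", "gene", "genome", "region") %in%
                  names(reads)))
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter a paired FASTQ by read-1 structure
#'
#' Keeps only read pairs whose read 1 passes [parse_read1()]; the
#' surviving pairs are written to `out_dir` as
#' `filtered_R1.fastq.gz` / `filtered_R2.fastq.gz`. Counts are conserved:
#' `kept + sum(rejected) == input pairs`.
#'
#' @param fastq1,fastq2 Paths to the read-1 and read-2 FASTQ files
#'   (plain or gzip). Must contain the same number of records.
#' @param out_dir Output directory for the filtered pair.
#' @param ... Passed to [parse_read1()] (e.g. `min_polyt`).
#' @return A list with `kept` (integer), `rejected` (named integer vector
#'   over the four reject reasons) and `paths` of the written files.
#' @export
filter_fastq <- function(fastq1, fastq2, out_dir, ...) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readBStringSet(fastq2, format = "fastq",
                                   with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    stop("paired FASTQ record counts differ: ", length(r1), " vs ",
         length(r2))
  }
  parsed <- parse_read1(as.character(r1), ...)
  keep <- parsed$valid
  rejected <- table(factor(parsed$reject_reason, levels = reject_reasons()))
  rejected <- stats::setNames(as.integer(rejected), names(rejected))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(r1 = file.path(out_dir, "filtered_R1.fastq.gz"),
             r2 = file.path(out_dir, "filtered_R2.fastq.gz"))
  Biostrings::writeXStringSet(r1[keep], paths[["r1"]], format = "fastq",
                              compress = TRUE,
                              qualities = S4Vectors::mcols(r1)$qualities[keep])
  Biostrings::writeXStringSet(r2[keep], paths[["r2"]], format = "fastq",
                              compress = TRUE,
                              qualities = S4Vectors::mcols(r2)$qualities[keep])
  list(kept = sum(keep), rejected = rejected, paths = paths)
}
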