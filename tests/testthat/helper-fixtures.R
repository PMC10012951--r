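# Small in-code fixtures shared across test files.

# A canonical well-formed read 1: 12-mer barcode, 8-mer UMI, anchor, polyT.
make_read1 <- function(barcode = strrep("A", 12), umi = strrep("C", 8),
                       anchor = "G", tail = "TTTTT") {
  paste0(barcode, umi, anchor, tail)
}

# Tagged-read table builder with sensible defaults.
make_reads <- function(barcode, gene, umi = NULL, genome = "human",
                       region = "exonic") {
  n <- max(length(barcode), length(gene), length(umi))
  if (is.null(umi)) umi <- sprintf("%08d", seq_len(n))
  data.frame(barcode = rep_len(barcode, n), umi = rep_len(umi, n),
             gene = rep_len(gene, n), genome = rep_len(genome, n),
             region = rep_len(region, n), stringsAsFactors = FALSE)
}

# A completed whitelist mapping each entry to itself.
identity_whitelist <- function(entries) {
  cand <- data.frame(barcode = entries,
                     n_reads = seq_along(entries),
                     n_genes = seq_along(entries))
  wl <- build_whitelist(cand, length(entries))
  repair_barcodes(entries, wl)
}

# Brute-force all-pairs Hamming repair: the independent oracle against
# which the neighborhood-enumeration implementation is checked.
brute_force_repair <- function(raw, entries, max_distance) {
  raw_m <- do.call(rbind, strsplit(raw, "", fixed = TRUE))
  ent_m <- do.call(rbind, strsplit(entries, "", fixed = TRUE))
  vapply(seq_along(raw), function(i) {
    d <- colSums(t(ent_m) != raw_m[i, ])
    m <- min(d)
    if (m > max_distance) return(NA_character_)
    hits <- which(d == m)
    if (length(hits) == 1L) entries[hits] else NA_character_
  }, character(1))
}

random_barcodes <- function(n, width = 12L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
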