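#' Hamming distance between equal-length strings
#'
#' Vectorized over pairs with the usual recycling; symmetric and zero iff
#' the strings are equal.
#'
#' @param a,b Character vectors of equal-length strings.
#' @return Integer vector of mismatch counts.
#' @export
hamming_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop("Hamming distance requires equal-length strings")
  }
  if (n == 0L) return(integer(0))
  vapply(seq_len(n), function(i) {
    sum(charToRaw(a[i]) != charToRaw(b[i]))
  }, integer(1))
}

#' Per-barcode read and gene tallies
#'
#' For every raw barcode, counts the supporting reads and the number of
#' genes with at least `min_reads_per_gene` reads — the quantities the
#' candidate filter and ranking operate on.
#'
#' @param reads Tagged reads (data.frame with `barcode` and `gene`).
#' @param min_reads_per_gene Read support needed for a gene to count as
#'   expressed in a barcode. Default 1.
#' @return A data.frame with `barcode`, `n_reads`, `n_genes`.
#' @export
barcode_stats <- function(reads, min_reads_per_gene = 1L) {
  stopifnot(all(c("barcode", "gene") %in% names(reads)),
            min_reads_per_gene >= 1L)
  dt <- data.table::as.data.table(reads[, c("barcode", "gene")])
  per_gene <- dt[, list(n = .N), by = c("barcode", "gene")]
  out <- per_gene[, list(n_reads = sum(n),
                         n_genes = sum(n >= min_reads_per_gene)),
                  by = "barcode"]
  data.table::setDF(out)
  out
}

#' Select candidate barcodes for whitelisting
#'
#' Candidates are barcodes expressing at least `min_genes` genes
#' (default 150); they are ranked descending either by genes expressed or
#' by total read counts. Ties are broken by the other key descending, then
#' by barcode lexicographically, so the ranking is deterministic.
#'
#' @param stats Output of [barcode_stats()].
#' @param min_genes Candidate floor on genes expressed. Default 150.
#' @param mode Ranking key: `"by_genes"` or `"by_reads"`.
#' @return The qualifying rows of `stats`, in rank order.
#' @export
candidate_barcodes <- function(stats, min_genes = 150L,
                               mode = c("by_genes", "by_reads")) {
  mode <- match.arg(mode)
  stopifnot(all(c("barcode", "n_reads", "n_genes") %in% names(stats)))
  keep <- stats[stats$n_genes >= min_genes, , drop = FALSE]
  ord <- if (mode == "by_genes") {
    order(-keep$n_genes, -keep$n_reads, keep$barcode)
  } else {
    order(-keep$n_reads, -keep$n_genes, keep$barcode)
  }
  out <- keep[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a barcode whitelist from ranked candidates
#'
#' Takes the top `n_expected` candidates (fewer if the candidate list is
#' shorter) — the expected number of nuclei drives how deep the ranking is
#' cut. The repair map starts as the identity on the whitelist entries.
#'
#' @param candidates Ranked candidates from [candidate_barcodes()].
#' @param n_expected Theoretical number of nuclei expected.
#' @param mode Ranking mode recorded on the whitelist.
#' @param max_distance Maximum Hamming distance used later by
#'   [repair_barcodes()]; recorded here. Default 2 (the "H2" tag).
#' @return An object of class `whitelist`: list with `entries` (rank
#'   order), `ranking_mode`, `max_distance` and `repair_map` (named
#'   character vector, raw -> assigned, `NA` meaning unassigned).
#' @export
build_whitelist <- function(candidates, n_expected,
                            mode = c("by_genes", "by_reads"),
                            max_distance = 2L) {
  mode <- match.arg(mode)
  if (!is.numeric(n_expected) || length(n_expected) != 1L || n_expected <= 0) {
    stop("`n_expected` must be a positive integer")
  }
  entries <- utils::head(candidates$barcode, n_expected)
  structure(
    list(
      entries = entries,
      ranking_mode = mode,
      max_distance = as.integer(max_distance),
      repair_map = stats::setNames(entries, entries)
    ),
    class = "whitelist"
  )
}

#' Enumerate the Hamming ball of radius <= 2 around each whitelist entry
#'
#' Returns a data.table (neighbor, entry, dist) covering distances 0..d.
#' @noRd
hamming_ball <- function(entries, max_distance) {
  width <- nchar(entries[1])
  bases <- c("A", "C", "G", "T")
  chars <- lapply(seq_len(width),
                  function(p) substr(entries, p, p))
  out <- list(data.table::data.table(neighbor = entries, entry = entries,
                                     dist = 0L))
  if (max_distance >= 1L) {
    for (p in seq_len(width)) {
      left <- substr(entries, 1L, p - 1L)
      right <- substr(entries, p + 1L, width)
      for (b in bases) {
        hit <- chars[[p]] != b
        if (!any(hit)) next
        out[[length(out) + 1L]] <- data.table::data.table(
          neighbor = paste0(left[hit], b, right[hit]),
          entry = entries[hit], dist = 1L
        )
      }
    }
  }
  if (max_distance >= 2L) {
    for (p in seq_len(width - 1L)) {
      for (q in seq((p + 1L), width)) {
        s1 <- substr(entries, 1L, p - 1L)
        s2 <- substr(entries, p + 1L, q - 1L)
        s3 <- substr(entries, q + 1L, width)
        for (b1 in bases) {
          hit1 <- chars[[p]] != b1
          if (!any(hit1)) next
          for (b2 in bases) {
            hit <- hit1 & chars[[q]] != b2
            if (!any(hit)) next
            out[[length(out) + 1L]] <- data.table::data.table(
              neighbor = paste0(s1[hit], b1, s2[hit], b2, s3[hit]),
              entry = entries[hit], dist = 2L
            )
          }
        }
      }
    }
  }
  data.table::rbindlist(out)
}

#' Repair raw barcodes against a whitelist (H2 correction)
#'
#' A raw barcode already on the whitelist maps to itself. A non-whitelisted
#' barcode maps to the unique nearest whitelist entry within
#' `max_distance` substitutions; if two or more entries tie at the minimal
#' qualifying distance the barcode is left unassigned (no molecule is
#' fabricated by an arbitrary choice), and barcodes farther than
#' `max_distance` from every entry are unassigned. The result is
#' deterministic and independent of input order.
#'
#' Implemented by enumerating the Hamming ball around each whitelist entry
#' and hashing it, which is equivalent to (and tested against) the
#' brute-force all-pairs scan.
#'
#' @param raw_barcodes Character vector of observed barcodes (duplicates
#'   allowed; the map is computed per unique barcode).
#' @param whitelist A [build_whitelist()] object.
#' @param max_distance Maximum substitutions allowed; default the
#'   whitelist's recorded `max_distance` (2, i.e. "H2"). Supported values
#'   0, 1, 2.
#' @return The whitelist with `repair_map` completed over the unique raw
#'   barcodes, plus a `repair_summary` element: named integer vector with
#'   `n_raw`, `n_exact`, `n_repaired`, `n_tied`, `n_unassigned` (ties
#'   included in `n_unassigned`), counted over unique raw barcodes.
#' @export
repair_barcodes <- function(raw_barcodes, whitelist,
                            max_distance = whitelist$max_distance) {
  stopifnot(inherits(whitelist, "whitelist"))
  max_distance <- as.integer(max_distance)
  if (max_distance < 0L || max_distance > 2L) {
    stop("`max_distance` must be 0, 1 or 2")
  }
  raw <- unique(as.character(raw_barcodes))
  entries <- whitelist$entries
  if (length(entries) && length(raw) &&
      any(nchar(raw) != nchar(entries[1]))) {
    stop("raw barcodes and whitelist entries must have equal length")
  }
  assigned <- rep(NA_character_, length(raw))
  names(assigned) <- raw
  n_tied <- 0L
  if (length(entries) && length(raw)) {
    ball <- hamming_ball(entries, max_distance)
    # sort so each neighbor's first row carries its minimal distance; a
    # second row at the same distance marks a tie between distinct entries
    data.table::setorder(ball, neighbor, dist, entry)
    i1 <- which(!duplicated(ball$neighbor))
    i2 <- i1 + 1L
    ok2 <- i2 <= nrow(ball)
    tied <- ok2 & ball$neighbor[pmin(i2, nrow(ball))] == ball$neighbor[i1] &
      ball$dist[pmin(i2, nrow(ball))] == ball$dist[i1]
    best_entry <- ball$entry[i1]
    best_entry[tied] <- NA_character_
    idx <- match(raw, ball$neighbor[i1])
    found <- !is.na(idx)
    assigned[found] <- best_entry[idx[found]]
    n_tied <- sum(tied[idx[found]])
  }
  is_wl <- raw %in% entries
  summary <- c(
    n_raw = length(raw),
    n_exact = sum(is_wl),
    n_repaired = sum(!is.na(assigned) & !is_wl),
    n_tied = n_tied,
    n_unassigned = sum(is.na(assigned))
  )
  whitelist$repair_map <- assigned
  whitelist$max_distance <- max_distance
  whitelist$repair_summary <- summary
  whitelist
}
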