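#' Simulation parameters for droplet nucleus encapsulation
#'
#' Bundles and validates every knob of the synthetic droplet generator.
#' Droplet occupancy follows the Poisson-limiting loading regime used by
#' Drop-seq/DroNc-seq: nuclei are diluted so that only a small fraction of
#' droplets (default 5%) contain any nucleus at all, which fixes the
#' per-droplet Poisson mean at `lambda = -log(1 - occupancy)`.
#'
#' @param n_droplets Number of droplets (beads) to simulate.
#' @param occupancy Fraction of droplets containing at least one nucleus,
#'   in `[0, 1)`. Default 0.05 ("nuclei in 5% of droplets").
#' @param species_proportions Named numeric pair `(human, murine)` summing
#'   to 1; the species of each encapsulated nucleus is drawn independently
#'   from it. Default 1:1.
#' @param n_genes_per_species Size of each species' (disjoint) gene panel.
#' @param molecules_per_nucleus_mean Location of the per-nucleus molecule
#'   count distribution on the natural scale (log-normal; counts are
#'   rounded up to at least 1).
#' @param molecules_per_nucleus_sigma Log-scale standard deviation of the
#'   molecule count distribution; 0 gives a fixed count.
#' @param reads_per_molecule_mean Poisson mean of sequenced reads per
#'   molecule; every molecule emits at least one read.
#' @param barcode_length,umi_length Lengths of the bead barcode and UMI
#'   segments of read 1. Defaults 12 and 8 (DroNc-seq read-1 layout).
#' @param barcode_error_rate Per-base substitution probability applied to
#'   the barcode segment of read 1.
#' @param region_probs Named probabilities over the four read-region
#'   categories (`exonic`, `intronic`, `intergenic`, `mitochondrial`)
#'   from which each read's region label is drawn.
#' @param seed Integer seed governing all randomness of a simulation.
#'
#' @return An object of class `sim_params` (a validated list).
#' @seealso [simulate_encapsulation()], [synthesize_reads()]
#' @export
sim_params <- function(n_droplets,
                       occupancy = 0.05,
                       species_proportions = c(human = 0.5, murine = 0.5),
                       n_genes_per_species = 1000L,
                       molecules_per_nucleus_mean = 400,
                       molecules_per_nucleus_sigma = 0.35,
                       reads_per_molecule_mean = 1,
                       barcode_length = 12L,
                       umi_length = 8L,
                       barcode_error_rate = 0.001,
                       region_probs = c(exonic = 0.34, intronic = 0.37,
                                        intergenic = 0.28, mitochondrial = 0.01),
                       seed = 1L) {
  n_droplets <- as.integer(n_droplets)
  stopifnot(length(n_droplets) == 1L, n_droplets >= 1L)
  if (!is.numeric(occupancy) || length(occupancy) != 1L ||
      occupancy < 0 || occupancy >= 1) {
    stop("`occupancy` must lie in [0, 1); got ", occupancy)
  }
  if (length(species_proportions) != 2L ||
      abs(sum(species_proportions) - 1) > 1e-12 ||
      any(species_proportions < 0)) {
    stop("`species_proportions` must be two non-negative values summing to 1")
  }
  if (is.null(names(species_proportions))) {
    names(species_proportions) <- c("human", "murine")
  }
  stopifnot(
    n_genes_per_species >= 1L,
    molecules_per_nucleus_mean > 0,
    molecules_per_nucleus_sigma >= 0,
    reads_per_molecule_mean > 0,
    barcode_length >= 1L, umi_length >= 1L,
    barcode_error_rate >= 0, barcode_error_rate <= 1
  )
  region_probs <- region_probs / sum(region_probs)
  if (!setequal(names(region_probs), region_levels())) {
    stop("`region_probs` must be named with: ",
         paste(region_levels(), collapse = ", "))
  }
  structure(
    list(
      n_droplets = n_droplets,
      occupancy = occupancy,
      species_proportions = species_proportions,
      n_genes_per_species = as.integer(n_genes_per_species),
      molecules_per_nucleus_mean = molecules_per_nucleus_mean,
      molecules_per_nucleus_sigma = molecules_per_nucleus_sigma,
      reads_per_molecule_mean = reads_per_molecule_mean,
      barcode_length = as.integer(barcode_length),
      umi_length = as.integer(umi_length),
      barcode_error_rate = barcode_error_rate,
      region_probs = region_probs[region_levels()],
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

region_levels <- function() c("exonic", "intronic", "intergenic", "mitochondrial")

species_levels <- function() c("human", "murine")

#' Droplet occupancy to Poisson loading mean
#'
#' Under Poisson loading the probability that a droplet is occupied is
#' `1 - exp(-lambda)`, so a stated occupancy fixes
#' `lambda = -log(1 - occupancy)`.
#'
#' @param occupancy Fraction of occupied droplets, in `[0, 1)`.
#' @return The per-droplet Poisson mean `lambda`.
#' @export
occupancy_to_lambda <- function(occupancy) {
  if (any(!is.finite(occupancy)) || any(occupancy < 0) || any(occupancy >= 1)) {
    stop("`occupancy` must lie in [0, 1)")
  }
  -log1p(-occupancy)
}

#' Random DNA barcodes, unique across droplets
#'
#' One bead barcode per droplet; duplicates are redrawn until all are
#' distinct (collisions between beads are out of scope of the model).
#' @noRd
random_unique_barcodes <- function(n, width) {
  bc <- random_kmers(n, width)
  repeat {
    dup <- duplicated(bc)
    if (!any(dup)) break
    bc[dup] <- random_kmers(sum(dup), width)
  }
  bc
}

random_kmers <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n, ncol = width)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate Poisson encapsulation of nuclei into droplets
#'
#' Each droplet receives `Poisson(lambda)` nuclei with
#' `lambda = -log(1 - occupancy)`, so the occupied fraction equals the
#' requested occupancy; each nucleus's species is drawn independently from
#' `species_proportions`. Deterministic for a fixed `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return A data.frame of droplet ground truth with one row per droplet:
#'   `droplet_id`, `barcode` (unique per droplet), `nucleus_count`,
#'   `species` (list column, one label per nucleus), `is_doublet`
#'   (`nucleus_count >= 2`) and `is_cross_species` (at least two distinct
#'   species present).
#' @export
simulate_encapsulation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  lambda <- occupancy_to_lambda(params$occupancy)
  n <- params$n_droplets
  counts <- if (lambda == 0) integer(n) else stats::rpois(n, lambda)
  barcodes <- random_unique_barcodes(n, params$barcode_length)
  sp <- sample(names(params$species_proportions),
               size = sum(counts), replace = TRUE,
               prob = params$species_proportions)
  species <- split(sp, rep.int(seq_len(n), counts))
  species_col <- vector("list", n)
  species_col[as.integer(names(species))] <- species
  empty <- lengths(species_col) == 0L & counts == 0L
  species_col[empty] <- list(character(0))
  cross <- vapply(species_col, function(s) length(unique(s)) >= 2L, logical(1))
  out <- data.frame(
    droplet_id = seq_len(n),
    barcode = barcodes,
    nucleus_count = counts,
    is_doublet = counts >= 2L,
    is_cross_species = cross,
    stringsAsFactors = FALSE
  )
  out$species <- species_col
  out
}

#' Disjoint gene panels for the two species
#'
#' Gene identifiers are prefixed by species (`HS-`/`MM-`) so that the
#' panels are disjoint and a gene's genome of origin is recoverable from
#' its name.
#'
#' @param params A [sim_params()] object.
#' @return Named list with character vectors `human` and `murine`.
#' @export
gene_panels <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  ng <- params$n_genes_per_species
  list(
    human = sprintf("HS-g%05d", seq_len(ng)),
    murine = sprintf("MM-g%05d", seq_len(ng))
  )
}

#' Synthesize sequencing reads from encapsulated droplets
#'
#' For every nucleus a molecule count is drawn log-normal (rounded up, at
#' least 1); each molecule receives a random UMI and a gene from its
#' species' panel, and emits `max(1, Poisson(reads_per_molecule_mean))`
#' reads. Read 1 is `barcode + UMI + anchor (A/C/G) + poly-T` padded to
#' `barcode_length + umi_length + 6` cycles (26 with the defaults);
#' i.i.d. per-base substitutions at `barcode_error_rate` are applied to
#' the barcode segment only. Read 2 carries the gene identifier as a
#' synthetic pre-aligned payload. The truth table records the error-free
#' barcode alongside the observed (possibly substituted) one, so the
#' downstream pipeline can run directly off the table when the FASTQ
#' strings themselves are not needed.
#'
#' @param droplets Droplet truth from [simulate_encapsulation()].
#' @param params The same [sim_params()] object.
#' @param emit_fastq If `FALSE`, skip building the read-1/read-2 strings
#'   (the tagged truth table is still complete); useful for large
#'   parameter-recovery simulations.
#' @return A list of class `sim_reads`: `truth` (data.frame with one row
#'   per read: `droplet_id`, `molecule` (index of the molecule the read
#'   came from), `barcode`, `observed_barcode`, `umi`, `gene`, `genome`,
#'   `region`), `read1`, `read2`, `read_ids` (character vectors, `NULL`
#'   when `emit_fastq = FALSE`), and `params`.
#' @export
synthesize_reads <- function(droplets, params, emit_fastq = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (nrow(droplets) == 0L) stop("`droplets` is empty")
  panels <- gene_panels(params)
  if (any(lengths(panels) == 0L)) stop("empty gene panel")
  set.seed(params$seed + 1L)

  occ <- droplets[droplets$nucleus_count > 0L, , drop = FALSE]
  nuc_barcode <- rep(occ$barcode, occ$nucleus_count)
  nuc_droplet <- rep(occ$droplet_id, occ$nucleus_count)
  nuc_species <- unlist(occ$species, use.names = FALSE)
  n_nuc <- length(nuc_barcode)
  if (n_nuc == 0L) stop("no occupied droplets to synthesize reads from")

  mol_n <- pmax(1L, as.integer(ceiling(stats::rlnorm(
    n_nuc,
    meanlog = log(params$molecules_per_nucleus_mean),
    sdlog = params$molecules_per_nucleus_sigma
  ))))
  n_mol <- sum(mol_n)
  mol_species <- rep(nuc_species, mol_n)
  mol_barcode <- rep(nuc_barcode, mol_n)
  mol_droplet <- rep(nuc_droplet, mol_n)
  mol_umi <- random_kmers(n_mol, params$umi_length)
  mol_gene <- character(n_mol)
  for (sp in species_levels()) {
    idx <- mol_species == sp
    mol_gene[idx] <- sample(panels[[sp]], sum(idx), replace = TRUE)
  }

  reads_n <- pmax(1L, stats::rpois(n_mol, params$reads_per_molecule_mean))
  ridx <- rep.int(seq_len(n_mol), reads_n)
  n_reads <- length(ridx)
  truth <- data.frame(
    droplet_id = mol_droplet[ridx],
    molecule = ridx,
    barcode = mol_barcode[ridx],
    umi = mol_umi[ridx],
    gene = mol_gene[ridx],
    genome = mol_species[ridx],
    region = sample(names(params$region_probs), n_reads, replace = TRUE,
                    prob = params$region_probs),
    stringsAsFactors = FALSE
  )
  truth$observed_barcode <- substitute_bases(truth$barcode,
                                             params$barcode_error_rate,
                                             params$barcode_length)

  read1 <- read2 <- read_ids <- NULL
  if (emit_fastq) {
    anchor <- sample(c("A", "C", "G"), n_reads, replace = TRUE)
    tail_len <- 26L - params$barcode_length - params$umi_length - 1L
    polyt <- strrep("T", max(tail_len, 0L))
    read1 <- paste0(truth$observed_barcode, truth$umi, anchor, polyt)
    read2 <- truth$gene
    read_ids <- sprintf("read%08d", seq_len(n_reads))
  }
  structure(
    list(truth = truth, read1 = read1, read2 = read2,
         read_ids = read_ids, params = params),
    class = "sim_reads"
  )
}

#' Apply i.i.d. per-base substitutions to fixed-width barcodes
#'
#' The number of substituted positions per barcode is Binomial(width, rate);
#' only barcodes with at least one hit are touched, and each hit position is
#' replaced by one of the three other bases uniformly.
#' @noRd
substitute_bases <- function(barcodes, rate, width) {
  if (rate == 0 || length(barcodes) == 0L) return(barcodes)
  k <- stats::rbinom(length(barcodes), width, rate)
  hit <- which(k > 0L)
  if (length(hit) == 0L) return(barcodes)
  out <- barcodes
  for (i in hit) {
    pos <- sample.int(width, k[i])
    chars <- strsplit(out[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    out[i] <- paste(chars, collapse = "")
  }
  out
}

#' Write a simulation to disk (FASTQ pair, truth table, params echo)
#'
#' Emits gzip FASTQ with 4-line records and constant Phred+33 qualities,
#' the tagged-read truth table as TSV (columns `droplet_id`, `barcode`,
#' `observed_barcode`, `umi`, `gene`, `species`, `region`) and a key-value
#' echo of the simulation parameters.
#'
#' @param sim A `sim_reads` object from [synthesize_reads()] with
#'   `emit_fastq = TRUE`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_reads"))
  if (is.null(sim$read1)) {
    stop("`sim` was synthesized with emit_fastq = FALSE; no reads to write")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    r1 = file.path(dir, "R1.fastq.gz"),
    r2 = file.path(dir, "R2.fastq.gz"),
    truth = file.path(dir, "truth.tsv"),
    params = file.path(dir, "params.txt")
  )
  r1 <- Biostrings::DNAStringSet(sim$read1)
  names(r1) <- sim$read_ids
  Biostrings::writeXStringSet(r1, paths[["r1"]], format = "fastq",
                              compress = TRUE)
  r2 <- Biostrings::BStringSet(sim$read2)
  names(r2) <- sim$read_ids
  Biostrings::writeXStringSet(r2, paths[["r2"]], format = "fastq",
                              compress = TRUE)
  truth <- sim$truth
  names(truth)[names(truth) == "genome"] <- "species"
  truth <- truth[, c("droplet_id", "barcode", "observed_barcode",
                     "umi", "gene", "species", "region")]
  utils::write.table(truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p <- sim$params
  kv <- vapply(p, function(x) paste(format(x, digits = 15), collapse = ","),
               character(1))
  writeLines(paste0(names(kv), "=", kv), paths[["params"]])
  invisible(paths)
}
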