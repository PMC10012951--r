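#' Pipeline configuration
#'
#' Collects every stage's parameters with defaults at the protocol's
#' stated values: 5% droplet occupancy, 1:1 species mix, 150-gene
#' candidate floor, Hamming repair distance 2, min 1 read per gene and
#' min 200 genes per barcode, 95% species threshold.
#'
#' @param n_droplets Number of droplets to simulate.
#' @param occupancy Droplet occupancy; default 0.05.
#' @param species_proportions Two-species mix; default 1:1.
#' @param n_genes_per_species,molecules_per_nucleus_mean,molecules_per_nucleus_sigma,reads_per_molecule_mean,barcode_error_rate,region_probs
#'   Passed to [sim_params()].
#' @param min_genes_candidate Candidate floor on genes expressed
#'   (default 150).
#' @param ranking_mode Whitelist ranking, `"by_genes"` or `"by_reads"`.
#' @param n_expected Expected nuclei; default
#'   `round(n_droplets * occupancy)`.
#' @param max_distance Barcode repair distance (default 2, "H2").
#' @param min_reads_per_gene,min_genes_per_barcode Per-barcode expression
#'   filters (defaults 1 and 200).
#' @param filter_unit Support measure for the expressed-gene test
#'   (`"reads"` default, or `"transcripts"`).
#' @param species_threshold Strict species-majority fraction
#'   (default 0.95).
#' @param classify_unit `"transcripts"` (default) or `"reads"`.
#' @param min_polyt Poly-T rule for read-1 validation (default 4 of 5).
#' @param emit_fastq Synthesize and parse actual read strings (`TRUE`,
#'   default) or run from the tagged table directly (faster at large
#'   scale).
#' @param seed Master seed governing all randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_droplets = 20000L,
                            occupancy = 0.05,
                            species_proportions = c(human = 0.5,
                                                    murine = 0.5),
                            n_genes_per_species = 1000L,
                            molecules_per_nucleus_mean = 400,
                            molecules_per_nucleus_sigma = 0.35,
                            reads_per_molecule_mean = 1,
                            barcode_error_rate = 0.001,
                            region_probs = c(exonic = 0.34,
                                             intronic = 0.37,
                                             intergenic = 0.28,
                                             mitochondrial = 0.01),
                            min_genes_candidate = 150L,
                            ranking_mode = "by_genes",
                            n_expected = NULL,
                            max_distance = 2L,
                            min_reads_per_gene = 1L,
                            min_genes_per_barcode = 200L,
                            filter_unit = "reads",
                            species_threshold = 0.95,
                            classify_unit = "transcripts",
                            min_polyt = 4L,
                            emit_fastq = TRUE,
                            seed = 1L) {
  if (is.null(n_expected)) n_expected <- max(1L, round(n_droplets * occupancy))
  cfg <- list(
    n_droplets = as.integer(n_droplets), occupancy = occupancy,
    species_proportions = species_proportions,
    n_genes_per_species = as.integer(n_genes_per_species),
    molecules_per_nucleus_mean = molecules_per_nucleus_mean,
    molecules_per_nucleus_sigma = molecules_per_nucleus_sigma,
    reads_per_molecule_mean = reads_per_molecule_mean,
    barcode_error_rate = barcode_error_rate,
    region_probs = region_probs,
    min_genes_candidate = as.integer(min_genes_candidate),
    ranking_mode = ranking_mode,
    n_expected = as.integer(n_expected),
    max_distance = as.integer(max_distance),
    min_reads_per_gene = as.integer(min_reads_per_gene),
    min_genes_per_barcode = as.integer(min_genes_per_barcode),
    filter_unit = filter_unit,
    species_threshold = species_threshold,
    classify_unit = classify_unit,
    min_polyt = as.integer(min_polyt),
    emit_fastq = isTRUE(emit_fastq),
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

sim_params_from_config <- function(config) {
  sim_params(
    n_droplets = config$n_droplets,
    occupancy = config$occupancy,
    species_proportions = config$species_proportions,
    n_genes_per_species = config$n_genes_per_species,
    molecules_per_nucleus_mean = config$molecules_per_nucleus_mean,
    molecules_per_nucleus_sigma = config$molecules_per_nucleus_sigma,
    reads_per_molecule_mean = config$reads_per_molecule_mean,
    barcode_error_rate = config$barcode_error_rate,
    region_probs = config$region_probs,
    seed = config$seed
  )
}

#' Run the full synthetic pipeline
#'
#' Simulates droplet encapsulation and reads, validates read-1 structure,
#' builds and repairs the barcode whitelist, quantifies UMI-collapsed
#' expression, applies the per-barcode filters, classifies species,
#' estimates the doublet rate and summarizes read regions. All artifacts
#' are optionally written to `out_dir`; the run report (stage counts,
#' conservation identities, config echo, seed, package version) is
#' returned and, when `out_dir` is given, serialized as `report.json`.
#' Identical config and seed yield identical reports.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `run_report` with elements `report` (the
#'   serializable summary), plus the in-memory objects `droplets`,
#'   `reads` (tagged, post-filter), `whitelist`, `matrix`, `filtered`,
#'   `calls`, `estimate`, `regions`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  params <- sim_params_from_config(config)
  droplets <- simulate_encapsulation(params)
  sim <- synthesize_reads(droplets, params, emit_fastq = config$emit_fastq)
  n_input <- nrow(sim$truth)

  if (config$emit_fastq) {
    parsed <- parse_read1(sim$read1, barcode_length = params$barcode_length,
                          umi_length = params$umi_length,
                          min_polyt = config$min_polyt)
    keep <- parsed$valid
    rejected <- table(factor(parsed$reject_reason,
                             levels = reject_reasons()))
    rejected <- stats::setNames(as.integer(rejected), reject_reasons())
    reads <- data.frame(
      barcode = parsed$barcode[keep],
      umi = parsed$umi[keep],
      gene = sim$read2[keep],
      genome = sim$truth$genome[keep],
      region = sim$truth$region[keep],
      stringsAsFactors = FALSE
    )
  } else {
    rejected <- stats::setNames(integer(4), reject_reasons())
    reads <- data.frame(
      barcode = sim$truth$observed_barcode,
      umi = sim$truth$umi,
      gene = sim$truth$gene,
      genome = sim$truth$genome,
      region = sim$truth$region,
      stringsAsFactors = FALSE
    )
  }
  n_kept <- nrow(reads)

  stats <- barcode_stats(reads, config$min_reads_per_gene)
  candidates <- candidate_barcodes(stats, config$min_genes_candidate,
                                   config$ranking_mode)
  wl <- build_whitelist(candidates, config$n_expected, config$ranking_mode,
                        config$max_distance)
  wl <- repair_barcodes(reads$barcode, wl)
  assigned <- !is.na(wl$repair_map[reads$barcode])
  n_assigned_reads <- sum(assigned)

  panels <- gene_panels(params)
  mat <- count_molecules(reads, wl, genes = c(panels$human, panels$murine))
  filtered <- apply_barcode_filters(mat, config$min_reads_per_gene,
                                    config$min_genes_per_barcode,
                                    config$filter_unit)
  halves <- split_by_genome(filtered)
  calls <- classify_species(halves$human, halves$murine,
                            threshold = config$species_threshold,
                            unit = config$classify_unit)
  estimate <- estimate_doublet_rate(calls, config$species_proportions)
  regions <- region_fractions(reads)

  report <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("droncqc")),
    seed = config$seed,
    reads = list(
      input = n_input, kept = n_kept,
      rejected = as.list(rejected),
      assigned = n_assigned_reads,
      unassigned_after_repair = n_kept - n_assigned_reads
    ),
    barcodes = list(
      observed = nrow(stats),
      candidates = nrow(candidates),
      whitelist_size = length(wl$entries),
      repair = as.list(wl$repair_summary)
    ),
    matrix = list(
      barcodes_pre_filter = ncol(mat$counts),
      barcodes_post_filter = ncol(filtered$counts),
      total_umis = sum(mat$counts),
      total_reads = sum(mat$reads)
    ),
    species = list(
      n_human = sum(calls$label == "human"),
      n_murine = sum(calls$label == "murine"),
      n_mixed = sum(calls$label == "mixed"),
      threshold = attr(calls, "threshold")
    ),
    doublet_estimate = list(
      n_total = estimate$n_total, n_mixed = estimate$n_mixed,
      correction_factor = estimate$correction_factor,
      doublet_rate = estimate$doublet_rate,
      doublet_rate_percent = estimate$doublet_rate_percent
    ),
    regions = as.list(regions$fractions),
    config = config[setdiff(names(config), "region_probs")]
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (config$emit_fastq) write_simulation(sim, file.path(out_dir, "sim"))
    write_tagged_reads(reads, file.path(out_dir, "tagged_reads.tsv"))
    writeLines(wl$entries, file.path(out_dir, "whitelist.txt"))
    rm_tab <- data.frame(raw = names(wl$repair_map),
                         assigned = ifelse(is.na(wl$repair_map), "-",
                                           wl$repair_map))
    utils::write.table(rm_tab, file.path(out_dir, "repair_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_dir(filtered, file.path(out_dir, "matrix_filtered"))
    write_barnyard(calls, estimate, file.path(out_dir, "barnyard"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    list(report = report, droplets = droplets, reads = reads,
         whitelist = wl, matrix = mat, filtered = filtered,
         calls = calls, estimate = estimate, regions = regions),
    class = "run_report"
  )
}

#' Run a barnyard mixing experiment and estimate the doublet rate
#'
#' Convenience wrapper for the species-mixing design: runs the pipeline,
#' classifies barcodes, estimates the corrected doublet rate, and joins
#' the species calls back to the droplet ground truth so the estimate can
#' be compared with the true doublet fraction among classified barcodes.
#'
#' @param config A [pipeline_config()] with both species present.
#' @return List with `estimate` (a `doublet_estimate`), `calls`,
#'   `scatter` (data.frame `barcode`, `n_human`, `n_murine`, `label` for
#'   Fig-4-style plotting), `truth` (per classified barcode:
#'   `is_doublet`, `is_cross_species`), `truth_doublet_fraction`,
#'   `truth_cross_fraction`, and the full `run`.
#' @export
barnyard_experiment <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (any(config$species_proportions <= 0)) {
    stop("barnyard experiment requires both species present in the mix")
  }
  run <- run_pipeline(config)
  calls <- run$calls
  idx <- match(calls$barcode, run$droplets$barcode)
  truth <- data.frame(
    barcode = calls$barcode,
    is_doublet = run$droplets$is_doublet[idx],
    is_cross_species = run$droplets$is_cross_species[idx],
    stringsAsFactors = FALSE
  )
  known <- !is.na(truth$is_doublet)
  list(
    estimate = run$estimate,
    calls = calls,
    scatter = calls[, c("barcode", "n_human", "n_murine", "label")],
    truth = truth,
    truth_doublet_fraction = mean(truth$is_doublet[known]),
    truth_cross_fraction = mean(truth$is_cross_species[known]),
    run = run
  )
}
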