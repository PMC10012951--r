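test_that("occupancy zero yields only empty droplets", {
  p <- sim_params(n_droplets = 500, occupancy = 0, seed = 11)
  d <- simulate_encapsulation(p)
  expect_equal(nrow(d), 500)
  expect_true(all(d$nucleus_count == 0))
  expect_false(any(d$is_doublet))
  expect_false(any(d$is_cross_species))
})

test_that("occupancy maps to the Poisson loading mean in closed form", {
  expect_equal(occupancy_to_lambda(0.05), -log(0.95), tolerance = 1e-12)
  expect_equal(round(occupancy_to_lambda(0.05), 6), 0.051293)
  expect_equal(occupancy_to_lambda(0), 0)
  expect_error(sim_params(100, occupancy = 1), "occupancy")
  expect_error(occupancy_to_lambda(1.2), "occupancy")
})

test_that("droplet truth respects its structural invariants", {
  p <- sim_params(n_droplets = 20000, occupancy = 0.1, seed = 3)
  d <- simulate_encapsulation(p)
  expect_false(any(duplicated(d$barcode)))
  expect_true(all(nchar(d$barcode) == 12))
  expect_true(all(d$is_doublet == (d$nucleus_count >= 2)))
  # cross-species implies doublet
  expect_true(all(d$is_doublet[d$is_cross_species]))
  expect_equal(lengths(d$species), d$nucleus_count)
})

test_that("empirical occupancy and doublet fraction match Poisson theory", {
  p <- sim_params(n_droplets = 1e5, occupancy = 0.05, seed = 42)
  d <- simulate_encapsulation(p)
  occ <- mean(d$nucleus_count >= 1)
  se <- sqrt(0.05 * 0.95 / 1e5)
  expect_lt(abs(occ - 0.05), 2.58 * se)  # binomial 99% CI

  lam <- occupancy_to_lambda(0.05)
  expected_df <- (1 - exp(-lam) - lam * exp(-lam)) / (1 - exp(-lam))
  expect_equal(round(expected_df, 6), 0.025427)
  occupied <- d[d$nucleus_count >= 1, ]
  df <- mean(occupied$nucleus_count >= 2)
  se_df <- sqrt(expected_df * (1 - expected_df) / nrow(occupied))
  expect_lt(abs(df - expected_df), 3 * se_df)
})

test_that("cross-species doublets occur at 2pq of all doublets", {
  p <- sim_params(n_droplets = 2e5, occupancy = 0.1,
                  species_proportions = c(human = 0.7, murine = 0.3),
                  seed = 8)
  d <- simulate_encapsulation(p)
  doublets <- d[d$nucleus_count == 2L, ]
  frac <- mean(doublets$is_cross_species)
  expected <- 2 * 0.7 * 0.3
  se <- sqrt(expected * (1 - expected) / nrow(doublets))
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("read-1 records have the 26-cycle layout and honest truth", {
  p <- sim_params(n_droplets = 400, occupancy = 0.2,
                  molecules_per_nucleus_mean = 20,
                  barcode_error_rate = 0, seed = 5)
  d <- simulate_encapsulation(p)
  sim <- synthesize_reads(d, p)
  expect_true(all(nchar(sim$read1) == 26))
  # no-noise case: observed barcode equals truth barcode on every read
  expect_identical(sim$truth$observed_barcode, sim$truth$barcode)
  expect_identical(substr(sim$read1, 1, 12), sim$truth$barcode)
  expect_identical(substr(sim$read1, 13, 20), sim$truth$umi)
  expect_true(all(substr(sim$read1, 21, 21) %in% c("A", "C", "G")))
  expect_true(all(substr(sim$read1, 22, 26) == "TTTTT"))
  # genes drawn from the correct species panel
  panels <- gene_panels(p)
  hs <- sim$truth$genome == "human"
  expect_true(all(sim$truth$gene[hs] %in% panels$human))
  expect_true(all(sim$truth$gene[!hs] %in% panels$murine))
})

test_that("barcode substitution rate matches the binomial closed form", {
  p <- sim_params(n_droplets = 20000, occupancy = 0.2,
                  molecules_per_nucleus_mean = 30,
                  barcode_error_rate = 0.01, seed = 9)
  d <- simulate_encapsulation(p)
  sim <- synthesize_reads(d, p, emit_fastq = FALSE)
  n <- nrow(sim$truth)
  expect_gte(n, 1e5)
  frac <- mean(sim$truth$observed_barcode != sim$truth$barcode)
  expected <- 1 - 0.99^12
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("same seed reproduces byte-identical FASTQ output", {
  p <- sim_params(n_droplets = 300, occupancy = 0.1,
                  molecules_per_nucleus_mean = 10, seed = 21)
  run_once <- function(dir) {
    d <- simulate_encapsulation(p)
    write_simulation(synthesize_reads(d, p), dir)
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- run_once(d1); p2 <- run_once(d2)
  for (f in c("r1", "r2")) {
    b1 <- readLines(gzfile(p1[[f]]))
    b2 <- readLines(gzfile(p2[[f]]))
    expect_identical(b1, b2)
  }
  expect_identical(readLines(p1[["truth"]]), readLines(p2[["truth"]]))
})

test_that("simulation rejects degenerate parameters", {
  expect_error(sim_params(100, species_proportions = c(0.6, 0.6)),
               "sum")
  p <- sim_params(100, n_genes_per_species = 1, seed = 2)
  expect_error(sim_params(100, n_genes_per_species = 0), "n_genes")
  d <- simulate_encapsulation(sim_params(100, occupancy = 0, seed = 1))
  expect_error(synthesize_reads(d, sim_params(100, occupancy = 0, seed = 1)),
               "occupied")
})
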