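test_that("hamming_distance counts mismatching positions", {
  expect_equal(hamming_distance("AAAA", "AAAA"), 0L)
  expect_equal(hamming_distance("AAAA", "AAAT"), 1L)
  expect_equal(hamming_distance("ACGT", "TGCA"), 4L)
  # symmetric, vectorized
  expect_equal(hamming_distance(c("AC", "GG"), c("CA", "GG")), c(2L, 0L))
  expect_equal(hamming_distance("ACGT", "AGGT"),
               hamming_distance("AGGT", "ACGT"))
  expect_error(hamming_distance("AAA", "AAAA"), "equal-length")
})

test_that("barcode_stats tallies reads and expressed genes", {
  reads <- make_reads(
    barcode = c("B1", "B1", "B1", "B2"),
    gene = c("g1", "g1", "g2", "g3")
  )
  st <- barcode_stats(reads)
  st <- st[order(st$barcode), ]
  expect_equal(st$n_reads, c(3L, 1L))
  expect_equal(st$n_genes, c(2L, 1L))
  # with a 2-read support floor only g1 counts for B1
  st2 <- barcode_stats(reads, min_reads_per_gene = 2)
  expect_equal(st2$n_genes[st2$barcode == "B1"], 1L)
  expect_equal(st2$n_genes[st2$barcode == "B2"], 0L)
})

test_that("candidate floor is 150 genes, inclusive", {
  st <- data.frame(barcode = c("B149", "B150", "B151"),
                   n_reads = c(999L, 10L, 10L),
                   n_genes = c(149L, 150L, 151L))
  cand <- candidate_barcodes(st)
  expect_setequal(cand$barcode, c("B150", "B151"))
  expect_false("B149" %in% cand$barcode)
})

test_that("candidate ranking follows the mode with deterministic ties", {
  st <- data.frame(barcode = c("BBB", "AAA", "CCC"),
                   n_reads = c(99L, 10L, 99L),
                   n_genes = c(200L, 300L, 200L))
  expect_equal(candidate_barcodes(st, mode = "by_genes")$barcode,
               c("AAA", "BBB", "CCC"))
  expect_equal(candidate_barcodes(st, mode = "by_reads")$barcode,
               c("BBB", "CCC", "AAA"))
})

test_that("build_whitelist truncates to the expected cell count", {
  cand <- data.frame(barcode = random_barcodes(500),
                     n_reads = 500:1, n_genes = 500:1)
  wl <- build_whitelist(cand, 250)
  expect_length(wl$entries, 250)
  expect_equal(wl$entries, cand$barcode[1:250])
  # identity initialization
  expect_equal(unname(wl$repair_map[wl$entries]), wl$entries)
  # short candidate list
  expect_length(build_whitelist(cand[1:100, ], 250)$entries, 100)
  expect_error(build_whitelist(cand, 0), "positive")
})

test_that("repair maps exact, near and ambiguous barcodes per the H2 rule", {
  entries <- c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "GGGGGGGGGGGG")
  wl <- build_whitelist(
    data.frame(barcode = entries, n_reads = 3:1, n_genes = 3:1), 3
  )
  raw <- c(
    "AAAAAAAAAAAA",  # exact -> itself
    "AAAAAAAAAATT",  # distance 2 from one entry -> repaired
    "AAAAAAAATTTT",  # distance 4 from everything -> unassigned
    "ACGTACGTACGT"   # far from everything -> unassigned
  )
  wl <- repair_barcodes(raw, wl)
  m <- wl$repair_map
  expect_equal(unname(m[raw[1]]), entries[1])
  expect_equal(unname(m[raw[2]]), entries[1])
  expect_true(is.na(m[raw[3]]))
  expect_true(is.na(m[raw[4]]))
  expect_equal(unname(wl$repair_summary[c("n_exact", "n_repaired",
                                          "n_unassigned")]),
               c(1L, 1L, 2L))
})

test_that("ties at the minimal distance are left unassigned", {
  entries <- c("AAAAAAAAAAAA", "AAAAAAAAAACC")
  wl <- build_whitelist(
    data.frame(barcode = entries, n_reads = 2:1, n_genes = 2:1), 2
  )
  # distance 1 from both entries
  wl <- repair_barcodes("AAAAAAAAAAAC", wl)
  expect_true(is.na(wl$repair_map[["AAAAAAAAAAAC"]]))
  expect_equal(unname(wl$repair_summary[["n_tied"]]), 1L)
  # whitelisted entries map to themselves even when mutually close
  wl2 <- repair_barcodes(entries, build_whitelist(
    data.frame(barcode = entries, n_reads = 2:1, n_genes = 2:1), 2
  ))
  expect_equal(unname(wl2$repair_map[entries]), entries)
})

test_that("nearest entry wins over farther qualifying entries", {
  entries <- c("AAAAAAAAAAAA", "AAAAAAAAAAGG")
  wl <- build_whitelist(
    data.frame(barcode = entries, n_reads = 2:1, n_genes = 2:1), 2
  )
  # distance 1 from the first entry, distance 2 from the second (not a tie)
  wl <- repair_barcodes("AAAAAAAAAAAT", wl)
  expect_equal(unname(wl$repair_map[["AAAAAAAAAAAT"]]), entries[1])
})

test_that("repair agrees with the brute-force all-pairs oracle", {
  set.seed(77)
  for (i in 1:12) {
    n_wl <- sample(5:60, 1)
    entries <- unique(random_barcodes(n_wl))
    # mix of exact entries, mutated entries (forced near-misses) and noise
    mut <- vapply(sample(entries, 40, replace = TRUE), function(b) {
      k <- sample(0:3, 1)
      if (k > 0) {
        pos <- sample(12, k)
        ch <- strsplit(b, "")[[1]]
        for (p in pos) ch[p] <- sample(c("A", "C", "G", "T"), 1)
        b <- paste(ch, collapse = "")
      }
      b
    }, character(1), USE.NAMES = FALSE)
    raw <- unique(c(sample(entries, 5), mut, random_barcodes(40)))
    for (d in 0:2) {
      wl <- build_whitelist(
        data.frame(barcode = entries, n_reads = seq_along(entries),
                   n_genes = seq_along(entries)),
        length(entries)
      )
      got <- repair_barcodes(raw, wl, max_distance = d)$repair_map[raw]
      want <- brute_force_repair(raw, entries, d)
      expect_equal(unname(got), want)
    }
  }
})

test_that("all repairs stay within the distance bound", {
  set.seed(101)
  entries <- unique(random_barcodes(80))
  wl <- build_whitelist(
    data.frame(barcode = entries, n_reads = seq_along(entries),
               n_genes = seq_along(entries)),
    length(entries)
  )
  raw <- unique(random_barcodes(3000))
  wl <- repair_barcodes(raw, wl)
  m <- wl$repair_map
  ok <- !is.na(m)
  expect_true(all(hamming_distance(names(m)[ok], m[ok]) <= 2))
})

test_that("simulated barcode errors are repaired back to truth", {
  # modest whitelist so the true barcodes are well separated: with many
  # more random 12-mers, chance near-neighbors introduce tie losses
  # beyond Monte-Carlo error
  p <- sim_params(n_droplets = 2000, occupancy = 0.1,
                  molecules_per_nucleus_mean = 50,
                  barcode_error_rate = 0.01, seed = 13)
  d <- simulate_encapsulation(p)
  sim <- synthesize_reads(d, p, emit_fastq = FALSE)
  truth <- sim$truth
  true_bcs <- unique(truth$barcode)
  wl <- build_whitelist(
    data.frame(barcode = true_bcs, n_reads = seq_along(true_bcs),
               n_genes = seq_along(true_bcs)),
    length(true_bcs)
  )
  wl <- repair_barcodes(truth$observed_barcode, wl)
  assigned <- wl$repair_map[truth$observed_barcode]
  err <- truth$observed_barcode != truth$barcode
  # error-bearing reads recovered to their truth barcode at least as often
  # as reads carry <= 2 substitutions (some extra recovery can occur only
  # by a wrong assignment, checked next)
  n_sub <- hamming_distance(truth$observed_barcode[err], truth$barcode[err])
  recovered <- !is.na(assigned[err]) & assigned[err] == truth$barcode[err]
  p_le2 <- mean(n_sub <= 2)
  se <- sqrt(p_le2 * (1 - p_le2) / sum(err))
  expect_gte(mean(recovered), p_le2 - 3 * se)
  # assignments that disagree with truth are rare
  wrong <- !is.na(assigned) & assigned != truth$barcode
  expect_lt(mean(wrong), 0.001)
})
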