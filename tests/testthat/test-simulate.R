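# The ground-truthed synthetic data generator.

test_that("simulated genome sequence is deterministic with controlled masking", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chrom_length = 100000,
                    n_sites = 10, repeat_fraction = 0.1, n_genes = 5,
                    with_sequence = TRUE)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$sequences, g2$sequences)

  chars <- strsplit(g1$sequences[["chr1"]], "")[[1]]
  frac <- mean(chars %in% c("a", "c", "g", "t"))
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.12)

  cfg0 <- sim_config(seed = 3, n_chromosomes = 1, chrom_length = 50000,
                     n_sites = 5, repeat_fraction = 0, n_genes = 3,
                     with_sequence = TRUE)
  g0 <- simulate_genome(cfg0)
  expect_false(grepl("[acgt]", g0$sequences[["chr1"]]))
})

test_that("planted landscape honours class fractions, spacing and motifs", {
  cfg <- sim_config(seed = 7, n_chromosomes = 1, chrom_length = 400000,
                    n_sites = 100,
                    class_fractions = c(shared = 1, a_only = 0, b_only = 0),
                    motif_prob = c(shared = 1, a_only = 1, b_only = 0),
                    n_genes = 5, with_sequence = TRUE)
  g <- simulate_genome(cfg)
  land <- simulate_binding_landscape(cfg, g$genome, g$sequences)
  expect_equal(unique(land$truth$class), "shared")
  expect_true(all(diff(land$truth$center) >= cfg$min_spacing))

  # embed probability 1: every shared site's 200-bp window contains a hit
  seqs <- fetch_site_sequences(land$truth, land$sequences, width = 200)
  p <- composite_ebox_gata()
  hit <- vapply(seqs$seq, function(s) nrow(scan_sequence(s, p)) > 0,
                logical(1))
  expect_true(all(hit))

  empty <- simulate_binding_landscape(
    sim_config(seed = 7, n_sites = 0, n_genes = 5), g$genome)
  expect_equal(nrow(empty$truth), 0)

  tiny <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 10000,
                     n_sites = 100, n_genes = 0)
  expect_error(simulate_binding_landscape(tiny, simulate_genome(tiny)$genome),
               "too small")
})

test_that("unenriched factor coverage is statistically identical to IgG", {
  hits <- 0
  for (s in 1:20) {
    cfg <- sim_config(seed = s, n_chromosomes = 1, chrom_length = 200000,
                      n_sites = 20, enrichment = 0, n_genes = 5)
    g <- simulate_genome(cfg)
    land <- simulate_binding_landscape(cfg, g$genome)
    a <- simulate_coverage(land$truth, cfg, g$genome, "A")
    igg <- simulate_coverage(land$truth, cfg, g$genome, "IgG")
    pt <- stats::poisson.test(c(nrow(a), nrow(igg)))
    if (pt$p.value >= 0.01) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("site reads concentrate at the planted center without background", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1, chrom_length = 100000,
                    n_sites = 1, background_rate = 0, enrichment = 50,
                    class_fractions = c(shared = 1, a_only = 0, b_only = 0),
                    n_genes = 0)
  g <- simulate_genome(cfg)
  land <- simulate_binding_landscape(cfg, g$genome)
  reads <- simulate_coverage(land$truth, cfg, g$genome, "A")
  centers <- (reads$start + reads$end) / 2
  expect_true(all(abs(centers - land$truth$center) <=
                    4 * cfg$site_read_sd + cfg$read_length / 2))
  igg <- simulate_coverage(land$truth, cfg, g$genome, "IgG")
  expect_equal(nrow(igg), 0)
})

test_that("total simulated read counts match the configured moments", {
  cfg <- sim_config(seed = 13, n_chromosomes = 1, chrom_length = 1e6,
                    n_sites = 50, enrichment = 30, background_rate = 2,
                    nb_dispersion = 0.2, n_genes = 5)
  g <- simulate_genome(cfg)
  land <- simulate_binding_landscape(cfg, g$genome)
  reads <- simulate_coverage(land$truth, cfg, g$genome, "A")
  n_bound <- sum(land$truth$enrich_a > 0)
  expected <- 1000 * cfg$background_rate + n_bound * cfg$enrichment
  # background bins are NB, site counts Poisson
  sd_total <- sqrt(1000 * (cfg$background_rate +
                             cfg$nb_dispersion * cfg$background_rate^2) +
                     n_bound * cfg$enrichment)
  expect_lt(abs(nrow(reads) - expected), 3 * sd_total)
})

test_that("caller outputs degrade as configured", {
  base <- list(seed = 17, n_chromosomes = 1, chrom_length = 500000,
               n_sites = 100, n_genes = 0)
  # noiseless limit: all callers agree exactly and recover the true sites
  cfg <- do.call(sim_config, c(base, list(caller_sensitivity = 1,
                                          caller_jitter_sd = 0,
                                          caller_fp_rate = 0)))
  g <- simulate_genome(cfg)
  land <- simulate_binding_landscape(cfg, g$genome)
  callers <- simulate_caller_outputs(land$truth, cfg, g$genome, "A")
  expect_equal(callers[[1]]$start, callers[[2]]$start)
  expect_equal(callers[[2]]$end, callers[[3]]$end)
  summed <- sum_binary_tracks(lapply(callers, binarize_occupancy, genome = g$genome))
  regions <- call_consensus_regions(summed)
  bound <- land$truth[land$truth$enrich_a > 0, ]
  expect_equal(nrow(regions), nrow(bound))
  expect_true(all(abs((regions$start + regions$end) / 2 - bound$center) <= 1))

  # zero sensitivity: empty caller files, no consensus
  cfg0 <- do.call(sim_config, c(base, list(caller_sensitivity = 0,
                                           caller_fp_rate = 0)))
  land0 <- simulate_binding_landscape(cfg0, g$genome)
  callers0 <- simulate_caller_outputs(land0$truth, cfg0, g$genome, "A")
  expect_true(all(vapply(callers0, nrow, integer(1)) == 0))
})

test_that("two-of-three caller consensus rate matches the binomial form", {
  # with per-caller sensitivity p, P(>=2 of 3) = 3p^2(1-p) + p^3
  p <- 0.9
  rates <- vapply(1:8, function(s) {
    cfg <- sim_config(seed = s, n_chromosomes = 1, chrom_length = 2e6,
                      n_sites = 300, caller_sensitivity = p,
                      caller_fp_rate = 0, n_genes = 0)
    g <- simulate_genome(cfg)
    land <- simulate_binding_landscape(cfg, g$genome)
    callers <- simulate_caller_outputs(land$truth, cfg, g$genome, "A")
    summed <- sum_binary_tracks(lapply(callers, binarize_occupancy,
                                       genome = g$genome))
    regions <- call_consensus_regions(summed)
    bound <- land$truth[land$truth$enrich_a > 0, , drop = FALSE]
    windows <- tibble::tibble(chrom = bound$chrom,
                              start = bound$center - 200L,
                              end = bound$center + 200L)
    mean(vapply(seq_len(nrow(windows)), function(i) {
      any(regions$chrom == windows$chrom[i] &
            regions$start < windows$end[i] & regions$end > windows$start[i])
    }, logical(1)))
  }, numeric(1))
  expect_lt(abs(mean(rates) - (3 * p^2 * (1 - p) + p^3)), 0.02)
})

test_that("gene annotation simulation is non-overlapping and balanced", {
  strands <- integer(0)
  for (s in 1:20) {
    cfg <- sim_config(seed = s, n_chromosomes = 1, chrom_length = 1e6,
                      n_sites = 10, n_genes = 50)
    genes <- simulate_gene_annotation(cfg, simulate_genome(cfg)$genome)
    expect_equal(nrow(genes), 50)
    g_sorted <- genes[order(genes$start), ]
    expect_true(all(diff(g_sorted$start) >= (g_sorted$end - g_sorted$start)[-50]))
    strands <- c(strands, sum(genes$strand == "+"))
  }
  # strand balance within the binomial 99% interval for 1000 draws
  expect_true(abs(sum(strands) - 500) < qnorm(0.995) * sqrt(1000 * 0.25))
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 1e6,
                    n_sites = 10, n_genes = 50)
  expect_identical(simulate_gene_annotation(cfg, genome_index("chr1", 1e6)),
                   simulate_gene_annotation(cfg, genome_index("chr1", 1e6)))
})

test_that("datasets are pure functions of the config and round-trip truth", {
  cfg <- sim_config(seed = 23, n_chromosomes = 2, chrom_length = 100000,
                    n_sites = 30, n_genes = 10, with_sequence = TRUE)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$reads$A, d2$reads$A)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$callers$B, d2$callers$B)

  dir <- withr::local_tempdir()
  write_sim_dataset(d1, dir)
  back <- read_truth(file.path(dir, "truth.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(d1$truth))
  fa <- file.path(dir, "genome.fa")
  expect_true(file.exists(fa))
  reread <- fetch_site_sequences(d1$truth[1:3, ], fa, width = 50)
  direct <- fetch_site_sequences(d1$truth[1:3, ], d1$sequences, width = 50)
  expect_equal(reread$seq, direct$seq)
})
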