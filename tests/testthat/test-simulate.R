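test_that("simulated reads are conserved and reproducible", {
  g <- flat_genome(chrom_length = 2e6, n_het = 100, seed = 1)
  cfg <- sim_config(n_droplets = 500, total_reads = 5e4, seed = 9)
  sim <- simulate_amplification(g, NULL, cfg)

  expect_equal(nrow(sim$reads) + sim$n_unmapped, cfg$total_reads)
  expect_equal(sim$mapping_rate, nrow(sim$reads) / cfg$total_reads)
  expect_true(sim$mapping_rate >= 0 && sim$mapping_rate <= 1)
  expect_equal(sum(sim$window_counts), nrow(sim$reads))
  expect_lte(sum(sim$window_counts), cfg$total_reads)

  sim2 <- simulate_amplification(g, NULL, cfg)
  expect_identical(sim$window_counts, sim2$window_counts)
  expect_identical(sim$allele_depths, sim2$allele_depths)
  sim3 <- simulate_amplification(g, NULL,
                                 sim_config(n_droplets = 500,
                                            total_reads = 5e4, seed = 10))
  expect_false(identical(sim$window_counts, sim3$window_counts))
})

test_that("total fragment loss yields zero counts with a warning", {
  g <- flat_genome(chrom_length = 1e6)
  cfg <- sim_config(n_droplets = 100, fragment_loss_prob = 1,
                    total_reads = 1e4, seed = 2)
  expect_warning(sim <- simulate_amplification(g, NULL, cfg), "no template")
  expect_equal(sim$mapping_rate, 0)
  expect_true(all(sim$window_counts == 0))
  expect_equal(sim$n_unmapped, cfg$total_reads) # background absorbs all reads
})

test_that("the unbiased one-pot limit gives near-uniform counts", {
  g <- flat_genome(chrom_length = 5e6, seed = 3)
  cfg <- sim_config(n_droplets = 1, tube_bias_sigma = 0,
                    within_droplet_cv = 0, gc_bias_coefficients = c(0, 0),
                    fragment_loss_prob = 0, empty_droplet_background = 0,
                    total_reads = 5e5, seed = 4)
  sim <- simulate_amplification(g, NULL, cfg)
  expect_equal(sim$mapping_rate, 1)
  # multinomial-uniform: per-window CV close to sqrt(1/mean)
  m <- mean(sim$window_counts)
  expect_equal(sd(sim$window_counts) / m, sqrt(1 / m), tolerance = 0.25)
  expect_lt(lorenz_curve(sim$window_counts)$gini, 0.05)
})

test_that("haplotype depths are conserved and consistent with read pileups", {
  g <- flat_genome(chrom_length = 1e6, n_het = 50, seed = 5)
  cfg <- sim_config(n_droplets = 200, total_reads = 2e5, seed = 6)
  sim <- simulate_amplification(g, NULL, cfg)
  ad <- sim$allele_depths
  expect_true(all(ad$ref_depth + ad$alt_depth <= nrow(sim$reads)))
  # brute-force pileup at the 5 deepest sites
  top <- head(order(-(ad$ref_depth + ad$alt_depth)), 5)
  for (i in top) {
    cover <- sim$reads$chrom == ad$chrom[i] &
      sim$reads$start <= ad$pos[i] - 1 &
      sim$reads$start + cfg$read_length >= ad$pos[i]
    expect_equal(sum(cover & sim$reads$hap == "A"), ad$ref_depth[i])
    expect_equal(sum(cover & sim$reads$hap == "B"), ad$alt_depth[i])
  }
})

test_that("bulk simulation recovers copy-number ratios within sampling error", {
  g <- flat_genome(chrom_length = 1e7, n_het = 100, seed = 7)
  tp <- truth_profile(data.frame(chrom = "chr1", start = 0, end = 4e6,
                                 cn = 3L), baseline_ploidy = 2L)
  bulk <- simulate_bulk(g, tp, total_reads = 4e5, seed = 8)
  expect_equal(bulk$mapping_rate, 1)
  cnw <- truth_cn_windows(tp, g)
  ratio <- mean(bulk$window_counts[cnw == 3]) /
    mean(bulk$window_counts[cnw == 2])
  expect_equal(ratio, 1.5, tolerance = 0.05)
  expect_lt(lorenz_curve(bulk$window_counts[cnw == 2])$gini, 0.05)
  expect_identical(bulk$window_counts,
                   simulate_bulk(g, tp, total_reads = 4e5,
                                 seed = 8)$window_counts)
  # both alleles present at well-covered het sites in unamplified material
  gd <- flat_genome(chrom_length = 2e6, n_het = 300, seed = 9)
  deep_bulk <- simulate_bulk(gd, NULL, total_reads = 6e5, seed = 10)
  ad <- deep_bulk$allele_depths
  deep <- ad$ref_depth + ad$alt_depth >= 20
  expect_gt(sum(deep), 200)
  expect_true(all(ad$ref_depth[deep] >= 1 & ad$alt_depth[deep] >= 1))
})

test_that("emulsion evenness beats one-pot bias at matched depth", {
  g <- flat_genome(chrom_length = 4e6, seed = 20)
  wins <- 0
  for (s in 1:3) {
    em <- simulate_amplification(g, NULL,
                                 sim_config(n_droplets = 1200,
                                            total_reads = 1e5, seed = s))
    tb <- simulate_amplification(g, NULL,
                                 sim_config(n_droplets = 1,
                                            total_reads = 1e5, seed = s))
    wins <- wins + (lorenz_curve(em$window_counts)$gini <
                      lorenz_curve(tb$window_counts)$gini)
  }
  expect_gte(wins, 2)
})
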