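test_that("heterozygous-site calling applies inclusive MAF and depth gates", {
  tab <- allele_table("chr1", c(100, 200, 300),
                      ref_depth = c(27, 4, 100), alt_depth = c(3, 4, 0))
  sc <- call_het_sites(tab, 0.05, 5)    # single-cell thresholds
  bk <- call_het_sites(tab, 0.20, 30)   # unamplified-bulk thresholds
  # 27/3: MAF 10%, depth 30 -> het for the cell, not for bulk
  expect_true(100 %in% sc$pos)
  expect_false(100 %in% bk$pos)
  # 4/4: balanced but depth 8 -> fails the bulk depth gate only
  expect_true(200 %in% sc$pos)
  expect_false(200 %in% bk$pos)
  # 100/0: MAF zero is never heterozygous
  expect_false(300 %in% sc$pos)
  # exact boundary inclusivity: depth 5 with MAF exactly 5% (19/1 fails, 95/5)
  edge <- allele_table("chr1", c(1, 2), ref_depth = c(95, 4),
                       alt_depth = c(5, 1))
  called <- call_het_sites(edge, 0.05, 5)
  expect_equal(called$pos, c(1, 2))
})

test_that("bulk-threshold calls nest inside single-cell calls", {
  set.seed(61)
  for (i in 1:20) {
    n <- 200
    tab <- allele_table("chr1", seq_len(n),
                        ref_depth = rpois(n, 20), alt_depth = rpois(n, 6))
    sc <- call_het_sites(tab, 0.05, 5)$pos
    bk <- call_het_sites(tab, 0.20, 30)$pos
    expect_true(all(bk %in% sc))
  }
})

test_that("allele-dropout rate counts single-allele sites among covered ones", {
  bulk_het <- data.frame(chrom = "chr1", pos = seq(10, 100, by = 10))
  # 10 bulk het sites; cell shows one allele only at two of them
  rd <- rep(10L, 10); ad <- rep(8L, 10)
  ad[3] <- 0L; rd[7] <- 0L; ad[7] <- 12L
  cell <- allele_table("chr1", bulk_het$pos, ref_depth = rd, alt_depth = ad)
  rep1 <- ado_rate(cell, bulk_het, depth_cutoffs = 5)
  expect_equal(rep1$by_cutoff$n_covered, 10)
  expect_equal(rep1$by_cutoff$ado_rate, 0.2)

  # all sites showing both alleles -> zero dropout
  clean <- allele_table("chr1", bulk_het$pos, ref_depth = 10, alt_depth = 10)
  expect_equal(ado_rate(clean, bulk_het, 5)$by_cutoff$ado_rate, 0)

  # sites outside bulk_het never enter the computation
  extra <- allele_table("chr1", c(bulk_het$pos, 500, 600),
                        ref_depth = c(rd, 50L, 0L), alt_depth = c(ad, 0L, 50L))
  expect_equal(ado_rate(extra, bulk_het, 5)$by_cutoff$ado_rate, 0.2)

  # bulk sites absent from the cell table count as uncovered depth 0
  rep2 <- ado_rate(cell[1:5, ], bulk_het, depth_cutoffs = 5)
  expect_equal(rep2$by_cutoff$n_covered, 5)

  expect_error(ado_rate(cell, bulk_het[0, ], 5), "empty")
  expect_error(ado_rate(cell, bulk_het, depth_cutoffs = 1000), "covered")
})

test_that("the alt-evidence threshold and diploid mask are honoured", {
  bulk_het <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400))
  cell <- allele_table("chr1", bulk_het$pos,
                       ref_depth = c(10L, 10L, 10L, 10L),
                       alt_depth = c(1L, 2L, 0L, 5L))
  # any minor-allele read rescues a site at the default threshold
  expect_equal(ado_rate(cell, bulk_het, 5)$by_cutoff$ado_rate, 0.25)
  # requiring 2 supporting reads drops the pos-100 site too
  expect_equal(ado_rate(cell, bulk_het, 5,
                        alt_evidence_min = 2)$by_cutoff$ado_rate, 0.5)
  # restricting to a diploid mask removes sites outside it
  mask <- data.frame(chrom = "chr1", start = 150, end = 450)
  rep_m <- ado_rate(cell, bulk_het, 5, mask = mask)
  expect_equal(rep_m$n_bulk_het, 3)
  expect_equal(rep_m$by_cutoff$ado_rate, 1 / 3)
})

test_that("coverage breadth is exact and non-increasing in the cutoff", {
  targets <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40))
  cell <- allele_table("chr1", c(20, 30, 40),
                       ref_depth = c(3L, 20L, 60L), alt_depth = c(2L, 10L, 40L))
  cb <- coverage_breadth(cell, targets, depth_cutoffs = c(1, 10))
  expect_equal(cb$breadth, c(0.75, 0.5))
  expect_equal(coverage_breadth(cell, targets, 0)$breadth, 1)
  ladder <- coverage_breadth(cell, targets, c(0, 1, 5, 10, 31, 1000))$breadth
  expect_true(all(diff(ladder) <= 0))
})

test_that("simulated allele dropout matches the loss model exactly at zero loss", {
  g <- make_genome(n_chrom = 1, chrom_length = 2e6, window = 1e4,
                   low_map_frac = 0, n_het_sites = 1500, seed = 62)
  # idealized saturation regime: equal within-droplet shares, so only
  # physical fragment loss can silence an allele
  cfg <- sim_config(n_droplets = 600, tube_bias_sigma = 0,
                    empty_droplet_background = 0,
                    fragment_loss_prob = 0, total_reads = 1e6, seed = 63)
  sim <- simulate_amplification(g, NULL, cfg)
  bulk <- simulate_bulk(g, NULL, total_reads = 6e5, seed = 64)
  bh <- call_het_sites(bulk$allele_depths, 0.20, 30)
  rep0 <- ado_rate(sim$allele_depths, bh, depth_cutoffs = 5)
  expect_equal(rep0$by_cutoff$ado_rate, 0)
})
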