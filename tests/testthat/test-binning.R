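test_that("uniform mappability gives exact equal bins and size scaling", {
  g <- flat_genome(chrom_length = 1e6)
  bs <- build_dynamic_bins(g, 5e4)
  expect_equal(nrow(bs$bins), 20)
  expect_true(all(bs$bins$end - bs$bins$start == 5e4))
  expect_true(all(bs$bins$mappable == 5e4))
  big <- build_dynamic_bins(g, 1e6)
  expect_equal(nrow(big$bins), 1)
  g2 <- flat_genome(chrom_length = 1e7)
  expect_equal(nrow(build_dynamic_bins(g2, 5e4)$bins),
               20 * nrow(build_dynamic_bins(g2, 1e6)$bins))
})

test_that("bins widen to hold equal mappable content in low-mappability regions", {
  # three-region toy track: 60 kb mappable, 60 kb half-mappable, 60 kb mappable
  win <- data.frame(chrom = "chrA", start = (0:179) * 1e3,
                    end = (1:180) * 1e3, gc = 0.5,
                    mappability = rep(c(1, 0.5, 1), each = 60))
  bs <- build_dynamic_bins(win, 6e3)
  # quota = 6 kb x mean mappability (5/6) = 5 kb of mappable content per bin
  expect_equal(nrow(bs$bins), 30)
  expect_true(all(abs(bs$bins$mappable - 5e3) < 1e-9))
  spans <- bs$bins$end - bs$bins$start
  half <- bs$bins$start >= 6e4 & bs$bins$end <= 1.2e5
  expect_true(all(spans[half] == 1e4))       # twice the genomic width
  expect_true(all(spans[!half] == 5e3))
})

test_that("binning is deterministic and conserves mappable content", {
  g <- make_genome(n_chrom = 2, chrom_length = 2e6, window = 1e4,
                   low_map_frac = 0.2, low_map_range = c(0.2, 0.8), seed = 5)
  b1 <- build_dynamic_bins(g, 1e5)
  b2 <- build_dynamic_bins(g, 1e5)
  expect_identical(b1, b2)
  total <- sum(g$windows$mappability * (g$windows$end - g$windows$start))
  expect_equal(sum(b1$bins$mappable), total, tolerance = 1e-12)
  # per-bin content within one window's worth of the quota (last bins aside)
  quota <- 1e5 * mean(g$windows$mappability)
  inner <- unlist(lapply(split(seq_len(nrow(b1$bins)), b1$bins$chrom),
                         function(ix) head(ix, -1)))
  expect_true(all(abs(b1$bins$mappable[inner] - quota) <= 1e4))
})

test_that("zero-mappability chromosomes yield no bins, with a warning", {
  win <- rbind(data.frame(chrom = "chr1", start = (0:9) * 1e3,
                          end = (1:10) * 1e3, gc = 0.5, mappability = 1),
               data.frame(chrom = "chr2", start = (0:9) * 1e3,
                          end = (1:10) * 1e3, gc = 0.5, mappability = 0))
  expect_warning(bs <- build_dynamic_bins(win, 2e3), "chr2")
  expect_true(all(bs$bins$chrom == "chr1"))
})

test_that("read counting filters on MapQ, conserves records, skips unknowns", {
  bs <- uniform_binset(10, size = 1000)
  empty <- count_reads(bs, data.frame(chrom = character(), start = numeric(),
                                      mapq = numeric()))
  expect_true(all(empty$counts == 0))

  ten <- data.frame(chrom = "chr1", start = rep(2500, 10), mapq = 60)
  bc <- count_reads(bs, ten)
  expect_equal(bc$counts[3], 10)
  expect_equal(sum(bc$counts), 10)

  # toy MapQ ladder: brute-force subset at the threshold
  toy <- data.frame(chrom = "chr1", start = seq(100, 7100, by = 1000),
                    mapq = seq(10, 80, by = 10))
  bc2 <- count_reads(bs, toy, mapq_min = 15)
  expect_equal(sum(bc2$counts), sum(toy$mapq >= 15))
  expect_equal(which(bc2$counts == 1), which(toy$mapq >= 15))

  # unknown chromosome and off-territory records are skipped, not fatal
  odd <- data.frame(chrom = c("chrZ", "chr1", "chr1"),
                    start = c(100, 50000, 500), mapq = 60)
  bc3 <- count_reads(bs, odd)
  expect_equal(sum(bc3$counts), 1)
  expect_equal(bc3$n_skipped, 2)

  # permutation invariance in record order
  perm <- toy[sample(nrow(toy)), ]
  expect_equal(count_reads(bs, perm, mapq_min = 15)$counts, bc2$counts)
})

test_that("dropout ratio counts empty bins", {
  expect_equal(dropout_ratio(make_counts(c(0, 5, 0, 7))), 0.5)
  expect_equal(dropout_ratio(make_counts(c(1, 2, 3))), 0)
  expect_error(dropout_ratio(integer()), "no bins")
})

test_that("bin_set rejects malformed tilings", {
  expect_error(bin_set(data.frame(chrom = "chr1", start = c(0, 500),
                                  end = c(1000, 1500))),
               "non-overlapping")
  expect_error(bin_set(data.frame(chrom = "chr1", start = 10, end = 10)),
               "end > start")
})

test_that("heavy fragment loss at shallow depth drives dropout toward 1", {
  g <- flat_genome(chrom_length = 2e6, seed = 6)
  cfg <- sim_config(n_droplets = 200, fragment_loss_prob = 0.99,
                    total_reads = 2000, seed = 7)
  sim <- simulate_amplification(g, NULL, cfg)
  bs <- build_dynamic_bins(g, 5e4)
  bc <- count_reads(bs, sim$reads, total_reads = sim$total_reads)
  expect_gt(dropout_ratio(bc), 0.5)
})
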