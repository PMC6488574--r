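test_that("GC correction is a near-identity when counts carry no GC trend", {
  set.seed(41)
  n <- 10000
  bs <- uniform_binset(n, gc = runif(n, 0.3, 0.6))
  counts <- rpois(n, 200)
  res <- gc_correct(make_counts(counts), bs, span = 0.3)
  keep <- counts > 0
  baseline <- counts[keep] / mean(counts[keep])
  expect_lt(max(abs(res$ratio[keep] / baseline - 1)), 0.02)
  expect_equal(mean(res$ratio[keep]), 1, tolerance = 1e-9)
})

test_that("GC correction removes an injected smooth bias", {
  set.seed(42)
  n <- 4000
  gc <- runif(n, 0.3, 0.6)
  bias <- exp(3 * (gc - 0.45) - 30 * (gc - 0.45)^2)
  counts <- rpois(n, 1000 * bias)
  bs <- uniform_binset(n, gc = gc)
  res <- gc_correct(make_counts(counts), bs, span = 0.3)
  keep <- counts > 0
  uncorrected <- counts[keep] / mean(counts[keep])
  expect_gt(sd(uncorrected) / sd(res$ratio[keep]), 5)
  # dropout bins excluded from the fit and reported as 0
  counts2 <- counts; counts2[1:50] <- 0
  res2 <- gc_correct(make_counts(counts2), bs)
  expect_true(all(res2$ratio[1:50] == 0))
})

test_that("GC correction preserves ranking within narrow GC strata", {
  set.seed(43)
  n <- 2000
  gc <- runif(n, 0.35, 0.55)
  counts <- rpois(n, 100 * exp(-3 * (gc - 0.45)^2))
  res <- gc_correct(make_counts(counts), uniform_binset(n, gc = gc))
  stratum <- which(gc > 0.44 & gc < 0.46 & counts > 0)
  expect_gt(cor(rank(counts[stratum]), rank(res$ratio[stratum])), 0.98)
})

test_that("GC correction refuses unfittable inputs", {
  bs <- uniform_binset(20, gc = runif(20, 0.3, 0.6))
  expect_error(gc_correct(make_counts(c(rep(0, 15), rep(10, 5))), bs),
               "non-dropout")
  expect_error(gc_correct(make_counts(rep(5, 19)), bs), "aligned")
})

test_that("ACD finds exact ploidies and breaks ties toward the smallest", {
  # half CN2 / half CN3 profile: residual is 0 at P = 2.5 and at P = 5
  ratio <- rep(c(2, 3), each = 100) / 2.5
  fit <- acd_ploidy(ratio)
  expect_equal(fit$ploidy, 2.5, tolerance = 1e-9)
  r25 <- fit$curve$residual[abs(fit$curve$ploidy - 2.5) < 1e-9]
  r50 <- fit$curve$residual[abs(fit$curve$ploidy - 5.0) < 1e-9]
  expect_lt(r25, 1e-9)
  expect_lt(r50, 1e-9)

  # flat profile fits every integer ploidy; smallest wins
  expect_equal(acd_ploidy(rep(1, 50))$ploidy, 2)

  # residual curve ignores bin order
  shuffled <- acd_ploidy(sample(ratio))
  expect_equal(shuffled$curve$residual, fit$curve$residual, tolerance = 1e-12)

  expect_error(acd_ploidy(ratio, grid = numeric()), "empty")
  expect_error(acd_ploidy(ratio, grid = c(0.5, 2)), "within")
})

test_that("CBS matches the exhaustive arc scan exactly", {
  set.seed(44)
  for (rep_i in 1:25) {
    n <- sample(10:30, 1)
    v <- rnorm(n, 2, 0.3)
    if (rep_i %% 3 == 0) v[seq_len(floor(n / 2))] <- v[seq_len(floor(n / 2))] + 2
    ours <- scwga:::.cbs_scan_cpp(v)
    brute <- brute_arc_scan(v)
    expect_equal(ours$stat, brute$stat, tolerance = 1e-9)
    # an arc and its complement carry the same statistic and imply the same
    # breakpoints; compare the breakpoint sets
    expect_equal(sort(setdiff(c(ours$i, ours$j), c(0L, n))),
                 sort(setdiff(c(brute$i, brute$j), c(0, n))))
  }
})

test_that("segmentation equals the exhaustive oracle on forced-decision series", {
  # noiseless step series: every split decision is forced, so the
  # independently coded recursive oracle must agree exactly
  cases <- list(
    c(rep(2, 10), rep(4, 8)),
    c(rep(1, 8), rep(3, 10), rep(6, 9)),
    c(rep(2, 7), rep(5, 6), rep(2.5, 9), rep(7, 8))
  )
  for (v in cases) {
    segs <- cbs_segment(v, seed = 5, min_width = 1)$segments
    cps <- segs$end_bin[-nrow(segs)]
    expect_equal(cps, brute_cbs(v))
  }
})

test_that("CBS recovers a single change point and resists pure noise", {
  set.seed(46)
  v <- c(rnorm(100, 2, 0.2), rnorm(100, 4, 0.2))
  segs <- cbs_segment(v, seed = 6)$segments
  expect_equal(nrow(segs), 2)
  expect_lte(abs(segs$end_bin[1] - 100), 2)

  # constant series: exactly one segment
  expect_equal(nrow(cbs_segment(rep(2, 50), seed = 1)$segments), 1)

  # determinism given the seed
  expect_identical(cbs_segment(v, seed = 7)$segments,
                   cbs_segment(v, seed = 7)$segments)

  # chromosome boundaries are never crossed
  chrom <- rep(c("chr1", "chr2"), each = 100)
  v2 <- c(rnorm(100, 2, 0.1), rnorm(100, 5, 0.1))
  segs2 <- cbs_segment(v2, chrom, seed = 8)$segments
  expect_equal(nrow(segs2), 2)
  expect_equal(segs2$chrom, c("chr1", "chr2"))
})

test_that("short segments are merged into the nearest-mean neighbour", {
  # a 2-bin spike: alpha 0.05 because a 2-outlier arc recurs in ~3% of
  # permutations (two outliers adjacent by chance)
  v <- c(rep(2, 30), rep(6, 2), rep(2.2, 30))
  unpruned <- cbs_segment(v, seed = 9, alpha = 0.05, min_width = 1)$segments
  pruned <- cbs_segment(v, seed = 9, alpha = 0.05, min_width = 3)$segments
  expect_equal(nrow(unpruned), 3)
  expect_equal(nrow(pruned), 2)           # spike absorbed, 2/30 bins wide
  expect_true(all(pruned$n_bins >= 3))
  # the spike merges into the closer-mean right neighbour
  expect_equal(pruned$mean[2], (2 * 6 + 30 * 2.2) / 32, tolerance = 1e-9)
})

test_that("integer profiles follow the half-away-from-zero rounding contract", {
  seg <- function(m) {
    s <- cbs_segment(rep(m, 10), seed = 1)
    s$segments$integer_cn
  }
  expect_equal(seg(2.49), 2L)
  expect_equal(seg(2.51), 3L)
  expect_equal(seg(2.5), 3L)
  sset <- cbs_segment(c(rep(2, 20), rep(3, 20)), seed = 2)
  expect_equal(integer_profile(sset), rep(c(2L, 3L), each = 20))
})

test_that("a low-noise simulated cell is recovered bin-for-bin", {
  g <- flat_genome(chrom_length = 1e7, seed = 47)
  tp <- truth_profile(data.frame(chrom = "chr1",
                                 start = c(2e6, 6e6), end = c(3.6e6, 8e6),
                                 cn = c(1L, 3L)), baseline_ploidy = 2L)
  cfg <- sim_config(n_droplets = 1, tube_bias_sigma = 0,
                    within_droplet_cv = 0, gc_bias_coefficients = c(0, 0),
                    fragment_loss_prob = 0, empty_droplet_background = 0,
                    total_reads = 1e6, seed = 48)
  sim <- simulate_amplification(g, tp, cfg)
  bs <- build_dynamic_bins(g, 2e5)
  bc <- count_reads(bs, sim$reads, total_reads = sim$total_reads)
  prof <- cnv_call(bc, bs, seed = 49)
  truth_bins <- truth_cn_bins(tp, bs)
  expect_equal(prof$ploidy, mean(truth_bins), tolerance = 0.051)
  expect_equal(prof$integer_cn, truth_bins)
  expect_equal(detection_rate(prof$integer_cn, tp, bs), 1)
})

test_that("detection rate scores reference events by bin overlap", {
  bs <- uniform_binset(610, size = 1e4)
  ev <- data.frame(chrom = "chr1", start = (0:60) * 1e5,
                   end = (0:60) * 1e5 + 5e4,
                   cn = rep(c(1L, 3L), length.out = 61))
  tp <- truth_profile(ev, baseline_ploidy = 2L)
  perfect <- truth_cn_bins(tp, bs)
  expect_equal(detection_rate(perfect, tp, bs), 1)
  expect_equal(detection_rate(rep(2L, 610), tp, bs), 0)
  # one missed event out of 61 reproduces a 98.4% detection rate
  miss <- perfect
  miss[bs$bins$start >= ev$start[5] & bs$bins$start < ev$end[5]] <- 2L
  expect_equal(detection_rate(miss, tp, bs), 60 / 61, tolerance = 1e-9)
  expect_equal(round(100 * detection_rate(miss, tp, bs), 1), 98.4)
  expect_error(detection_rate(perfect, truth_profile(ev[0, ]), bs), "events")
})
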