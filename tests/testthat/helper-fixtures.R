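# Shared fixture builders and independent oracles for the test suite.

# n equal bins on one chromosome with chosen GC values.
uniform_binset <- function(n, size = 1000, gc = NULL, chrom = "chr1") {
  start <- (seq_len(n) - 1) * size
  bin_set(data.frame(chrom = chrom, start = start, end = start + size,
                     mappable = size,
                     gc = if (is.null(gc)) rep(0.5, n) else gc,
                     stringsAsFactors = FALSE),
          target_size = size, window = size)
}

# Fabricate a bin_counts object from a raw count vector.
make_counts <- function(counts, sample_id = "test", total = NULL) {
  structure(list(sample_id = sample_id, counts = as.integer(counts),
                 mapped_reads = sum(counts),
                 total_reads = if (is.null(total)) sum(counts) else total,
                 n_skipped = 0L),
            class = "bin_counts")
}

# Brute-force max arc statistic: exhaustive scan over all circular arcs,
# written independently of the package's C++ path.
brute_arc_scan <- function(v) {
  n <- length(v)
  S <- c(0, cumsum(v))
  s <- sd(v)
  best <- -Inf; bi <- NA; bj <- NA
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k == n) next
      arc <- S[j + 1] - S[i + 1]
      z <- abs(arc / k - (S[n + 1] - arc) / (n - k)) /
        (s * sqrt(1 / k + 1 / (n - k)))
      if (z > best) { best <- z; bi <- i; bj <- j }
    }
  }
  list(stat = best, i = bi, j = bj)
}

# Independent recursive segmentation oracle for deterministic (noiseless
# step) series: every accepted split is forced because the observed arc
# statistic is the maximum achievable, so permutation streams cannot flip
# decisions; constant pieces have zero variance and never split.
brute_cbs <- function(v, alpha = 0.01, nperm = 200) {
  recurse <- function(v, off) {
    n <- length(v)
    if (n < 4 || sd(v) <= 1e-12) return(integer())
    sc <- brute_arc_scan(v)
    exceed <- sum(replicate(nperm, brute_arc_scan(sample(v))$stat) >=
                    sc$stat * (1 - 1e-12))
    if ((exceed + 1) / (nperm + 1) >= alpha) return(integer())
    cps <- c(if (sc$i > 0) sc$i, if (sc$j < n) sc$j)
    segs <- list(c(1, sc$i), c(sc$i + 1, sc$j), c(sc$j + 1, n))
    for (sg in segs) {
      if (sg[2] >= sg[1] && sg[2] - sg[1] + 1 >= 4)
        cps <- c(cps, recurse(v[sg[1]:sg[2]], 0) + sg[1] - 1)
    }
    sort(unique(cps)) + off
  }
  recurse(v, 0)
}

# A small diploid test genome with fully mappable windows (exact bin
# arithmetic) and optional het sites.
flat_genome <- function(n_chrom = 1, chrom_length = 1e7, n_het = 0,
                        seed = 1) {
  make_genome(n_chrom = n_chrom, chrom_length = chrom_length, window = 1e4,
              low_map_frac = 0, n_het_sites = n_het, seed = seed)
}
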