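#' Simulator configuration for compartmentalized vs one-pot MDA
#'
#' Parameters of the generative amplification model used by
#' [simulate_amplification()]. `n_droplets = 1` is conventional one-pot
#' ("tube") MDA; large `n_droplets` is emulsion MDA.
#'
#' Defaults describe the emulsion operating point of a 30--40 uL reaction of
#' 40-um droplets seeded with ~10-kb fragments (occupancy near 0.7):
#' `tube_bias_sigma = 2` gives the roughly two-orders-of-magnitude spread of
#' per-template gain characteristic of unconstrained MDA;
#' `fragment_loss_prob = 0.11` reproduces an allele-dropout rate near 20%
#' (ADO = 2p/(1+p)); `empty_droplet_background = 0.5` makes an empty droplet
#' emit half a saturated droplet's mass as unmappable primer-derived
#' product, placing mapping rates near 50--70% at the emulsion optimum.
#'
#' @param n_droplets Number of droplets (1 = one-pot tube MDA).
#' @param fragment_length Template fragment length in bases.
#' @param saturation_yield Product mass of one saturated droplet (arbitrary
#'   units; only relative masses matter).
#' @param within_droplet_cv Log-scale sd of the per-droplet saturation jitter.
#' @param tube_bias_sigma Log-scale sd of per-template amplification gain
#'   when templates compete in the same compartment; at `n_droplets = 1`
#'   this is the one-pot exponential amplification bias.
#' @param empty_droplet_background Unmappable product mass of an empty
#'   droplet, as a fraction of `saturation_yield`.
#' @param fragment_loss_prob Probability a template fragment is lost before
#'   amplification (lysis/handling loss); drives allele dropout.
#' @param gc_bias_coefficients Length-2 numeric `c(b1, b2)`: per-fragment
#'   mass is multiplied by `exp(b1*(gc-0.5) + b2*(gc-0.5)^2)` with `gc` the
#'   local window GC fraction.
#' @param total_reads Total sequenced reads (mapped + unmapped).
#' @param read_length Read length in bases.
#' @param seed Integer seed; all randomness in the simulation flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_droplets = 9e5, fragment_length = 1e4,
                       saturation_yield = 1, within_droplet_cv = 0.2,
                       tube_bias_sigma = 2, empty_droplet_background = 0.5,
                       fragment_loss_prob = 0.11,
                       gc_bias_coefficients = c(1, -10),
                       total_reads = 5e5, read_length = 100, seed = 1L) {
  stop_if_not_positive(n_droplets, "n_droplets")
  stop_if_not_positive(fragment_length, "fragment_length")
  stop_if_not_positive(saturation_yield, "saturation_yield")
  stop_if_not_positive(total_reads, "total_reads")
  stop_if_not_positive(read_length, "read_length")
  if (within_droplet_cv < 0 || tube_bias_sigma < 0)
    stop("dispersion parameters must be non-negative", call. = FALSE)
  if (fragment_loss_prob < 0 || fragment_loss_prob > 1)
    stop("`fragment_loss_prob` must be in [0, 1]", call. = FALSE)
  if (empty_droplet_background < 0)
    stop("`empty_droplet_background` must be non-negative", call. = FALSE)
  if (length(gc_bias_coefficients) != 2L)
    stop("`gc_bias_coefficients` must have length 2", call. = FALSE)
  structure(list(n_droplets = n_droplets, fragment_length = fragment_length,
                 saturation_yield = saturation_yield,
                 within_droplet_cv = within_droplet_cv,
                 tube_bias_sigma = tube_bias_sigma,
                 empty_droplet_background = empty_droplet_background,
                 fragment_loss_prob = fragment_loss_prob,
                 gc_bias_coefficients = as.numeric(gc_bias_coefficients),
                 total_reads = total_reads, read_length = read_length,
                 seed = seed),
            class = "sim_config")
}

# Enumerate template fragments by tiling each genomic copy with fragments of
# length L at a random phase: every base of every surviving copy is covered
# by exactly one fragment, so expected fragment counts per window are
# cn * window/L and the allele-dropout closed form 2p/(1+p) is exact.
enumerate_fragments <- function(genome, truth, L) {
  cnw <- truth_cn_windows(truth, genome)
  hap <- hap_copy_counts(cnw)
  w <- genome$window
  out <- vector("list", 64L); nout <- 0L
  for (ci in seq_len(nrow(genome$chromosomes))) {
    cname <- genome$chromosomes$name[ci]
    rows <- genome$windows$chrom == cname
    for (h in c("a", "b")) {
      copies <- hap[[h]][rows]
      if (!length(copies) || max(copies) == 0) next
      for (lev in seq_len(max(copies))) {
        r <- rle(copies >= lev)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
          s <- (starts[k] - 1L) * w
          e <- ends[k] * w
          u <- floor(runif(1) * L)
          bnd <- unique(c(s, seq(s + u, e, by = L), e))
          bnd <- bnd[bnd >= s & bnd <= e]
          if (length(bnd) < 2L) bnd <- c(s, e)
          nf <- length(bnd) - 1L
          nout <- nout + 1L
          if (nout > length(out)) out <- c(out, vector("list", length(out)))
          out[[nout]] <- data.frame(chrom = cname,
                                    start = bnd[-length(bnd)], end = bnd[-1L],
                                    hap = if (h == "a") "A" else "B",
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (nout == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      hap = character(), stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(nout)])
}

# Haplotype-resolved depths at het sites from placed reads. A read starting
# at 0-based s covers 1-based position P when s is in [P - read_length, P - 1].
tally_allele_depths <- function(reads, het_sites, read_length) {
  n <- nrow(het_sites)
  ref_d <- integer(n); alt_d <- integer(n)
  if (nrow(reads) && n) {
    for (cname in unique(het_sites$chrom)) {
      si <- which(het_sites$chrom == cname)
      pos <- het_sites$pos[si]
      for (h in c("A", "B")) {
        st <- sort(reads$start[reads$chrom == cname & reads$hap == h])
        if (!length(st)) next
        cnt <- findInterval(pos - 1, st) - findInterval(pos - read_length - 1, st)
        if (h == "A") ref_d[si] <- cnt else alt_d[si] <- cnt
      }
    }
  }
  data.frame(chrom = het_sites$chrom, pos = het_sites$pos,
             ref = het_sites$ref, alt = het_sites$alt,
             ref_depth = ref_d, alt_depth = alt_d,
             stringsAsFactors = FALSE)
}

# Per-window read-start counts, concatenated in genome window order.
tally_window_counts <- function(reads, genome) {
  w <- genome$window
  counts <- integer(nrow(genome$windows))
  if (nrow(reads)) {
    off <- 0L
    for (ci in seq_len(nrow(genome$chromosomes))) {
      cname <- genome$chromosomes$name[ci]
      nwin <- as.integer(genome$chromosomes$length[ci] / w)
      st <- reads$start[reads$chrom == cname]
      if (length(st))
        counts[off + seq_len(nwin)] <- tabulate(floor(st / w) + 1L, nbins = nwin)
      off <- off + nwin
    }
  }
  counts
}

sim_output <- function(reads, mapping_rate, total_reads, n_unmapped,
                       allele_depths, truth, genome, window_counts,
                       bin_counts = NULL, fragments = NULL, config = NULL) {
  structure(list(reads = reads, mapping_rate = mapping_rate,
                 total_reads = total_reads, n_unmapped = n_unmapped,
                 allele_depths = allele_depths, truth = truth,
                 genome = genome, window_counts = window_counts,
                 bin_counts = bin_counts, fragments = fragments,
                 config = config),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("Simulated sequencing run: %g reads, mapping rate %.3f\n",
              x$total_reads, x$mapping_rate))
  cat(sprintf("  %d mapped reads, %d het sites tallied\n",
              nrow(x$reads), nrow(x$allele_depths)))
  invisible(x)
}

#' Simulate whole-genome amplification and shallow sequencing of one cell
#'
#' Generative model of MDA with optional emulsion compartmentalization:
#'
#' 1. template fragments tile every genomic copy (see `fragment_length`),
#'    each carrying its copy's haplotype, and are lost independently with
#'    probability `fragment_loss_prob`;
#' 2. surviving fragments are distributed uniformly over `n_droplets`;
#' 3. each occupied droplet amplifies to saturation: its total product mass
#'    `saturation_yield * lognormal(0, within_droplet_cv)` is split among
#'    its k templates proportionally to lognormal(0, `tube_bias_sigma`)
#'    competition weights, so a lone template is amplified to full
#'    saturation while co-encapsulated templates compete as in a miniature
#'    one-pot reaction (`n_droplets = 1` is exactly conventional tube MDA);
#' 4. each empty droplet emits `empty_droplet_background * saturation_yield`
#'    of unmappable primer-derived product;
#' 5. per-fragment mass is modulated by a quadratic-in-GC factor;
#' 6. `total_reads` reads are drawn from fragments and the unmappable pool
#'    in proportion to mass; mapped reads start uniformly within their
#'    fragment;
#' 7. per-window counts and haplotype-resolved depths at the genome's het
#'    sites are tallied.
#'
#' @param genome A [make_genome()] model.
#' @param truth A [make_truth_profile()] profile, or `NULL` for flat diploid.
#' @param cfg A [sim_config()].
#' @param bins Optional `bin_set`; when supplied, `bin_counts` holds
#'   [count_reads()] of the simulated alignments on it.
#' @param keep_lineage Keep the per-fragment table (with droplet assignment)
#'   for debugging.
#' @return An object of class `sim_output`: mapped reads as BED-like records
#'   (`chrom`, `start`, `end`, `hap`, `mapq`), `mapping_rate`,
#'   `window_counts` on the genome's windows, `allele_depths`
#'   (chrom, pos, ref, alt, ref_depth, alt_depth), the truth, and metadata.
#'   Mapped plus unmapped reads always total `cfg$total_reads`.
#' @examples
#' g <- make_genome(n_chrom = 1, chrom_length = 2e6, n_het_sites = 50, seed = 1)
#' cfg <- sim_config(n_droplets = 500, total_reads = 5e4, seed = 2)
#' sim <- simulate_amplification(g, NULL, cfg)
#' sim$mapping_rate
#' @export
simulate_amplification <- function(genome, truth = NULL, cfg = sim_config(),
                                   bins = NULL, keep_lineage = FALSE) {
  stopifnot(inherits(genome, "genome_model"), inherits(cfg, "sim_config"))
  if (is.null(truth))
    truth <- make_truth_profile(genome, n_events = 0L, baseline = 2L)
  stopifnot(inherits(truth, "truth_profile"))

  with_seed(cfg$seed, {
    frags <- enumerate_fragments(genome, truth, cfg$fragment_length)
    if (nrow(frags))
      frags <- frags[runif(nrow(frags)) >= cfg$fragment_loss_prob, ,
                     drop = FALSE]
    n_frag <- nrow(frags)
    empty_reads <- data.frame(chrom = character(), start = numeric(),
                              end = numeric(), hap = character(),
                              mapq = integer(), stringsAsFactors = FALSE)

    if (n_frag == 0L) {
      warning("no template fragments survived; all counts are zero",
              call. = FALSE)
      pool <- cfg$n_droplets * cfg$empty_droplet_background *
        cfg$saturation_yield
      n_un <- if (pool > 0) cfg$total_reads else 0L
      return(sim_output(empty_reads, 0, cfg$total_reads, n_un,
                        tally_allele_depths(empty_reads, genome$het_sites,
                                            cfg$read_length),
                        truth, genome, tally_window_counts(empty_reads, genome),
                        if (!is.null(bins))
                          count_reads(bins, empty_reads,
                                      total_reads = cfg$total_reads),
                        config = cfg))
    }

    # droplet assignment and saturation-competition masses
    did <- sample.int(cfg$n_droplets, n_frag, replace = TRUE)
    f <- match(did, unique(did))
    n_occ <- max(f)
    w <- rlnorm(n_frag, 0, cfg$tube_bias_sigma)
    sw <- unname(rowsum(w, f)[, 1L]) # groups 1..n_occ in sorted order
    yd <- cfg$saturation_yield * rlnorm(n_occ, 0, cfg$within_droplet_cv)
    mass <- yd[f] * w / sw[f]

    # GC modulation from the fragment midpoint's window
    gi <- window_index(genome, frags$chrom, floor((frags$start + frags$end) / 2))
    g <- genome$windows$gc[gi] - 0.5
    b <- cfg$gc_bias_coefficients
    mass <- mass * exp(b[1] * g + b[2] * g^2)

    pool <- (cfg$n_droplets - n_occ) * cfg$empty_droplet_background *
      cfg$saturation_yield

    n_un <- rbinom(1L, cfg$total_reads, pool / (pool + sum(mass)))
    n_map <- cfg$total_reads - n_un
    reads <- empty_reads
    if (n_map > 0) {
      fi <- sample.int(n_frag, n_map, replace = TRUE, prob = mass)
      fs <- frags$start[fi]
      fl <- frags$end[fi] - fs
      # start support widened by read_length - 1 so expected coverage is
      # exactly uniform over the fragment (no under-covered fragment edges)
      off <- floor(runif(n_map) * (fl + cfg$read_length - 1))
      clen <- genome$chromosomes$length[match(frags$chrom[fi],
                                              genome$chromosomes$name)]
      rs <- fs - cfg$read_length + 1 + off
      rs <- pmin(pmax(rs, 0), pmax(clen - cfg$read_length, 0))
      reads <- data.frame(chrom = frags$chrom[fi], start = rs,
                          end = rs + cfg$read_length, hap = frags$hap[fi],
                          mapq = 60L, stringsAsFactors = FALSE)
    }

    if (keep_lineage) frags$droplet <- did
    sim_output(reads, n_map / cfg$total_reads, cfg$total_reads, n_un,
               tally_allele_depths(reads, genome$het_sites, cfg$read_length),
               truth, genome, tally_window_counts(reads, genome),
               if (!is.null(bins))
                 count_reads(bins, reads, total_reads = cfg$total_reads),
               fragments = if (keep_lineage) frags,
               config = cfg)
  })
}

#' Simulate an unamplified bulk sequencing run
#'
#' Reads are drawn multinomially over genome windows with probability
#' proportional to copy number times mappability — library sampling noise
#' only, no amplification bias. Both haplotypes contribute in proportion to
#' their copy counts.
#'
#' @param genome A [make_genome()] model.
#' @param truth A [make_truth_profile()] profile, or `NULL` for flat diploid.
#' @param total_reads Number of reads to draw (all map).
#' @param read_length Read length in bases.
#' @param seed Integer seed.
#' @param bins Optional `bin_set` for `bin_counts`.
#' @return A `sim_output` with `mapping_rate = 1`.
#' @export
simulate_bulk <- function(genome, truth = NULL, total_reads = 5e5,
                          read_length = 100, seed = 1L, bins = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(truth))
    truth <- make_truth_profile(genome, n_events = 0L, baseline = 2L)
  cnw <- truth_cn_windows(truth, genome)
  hap <- hap_copy_counts(cnw)
  wt <- cnw * genome$windows$mappability
  if (sum(wt) <= 0) stop("no sequenceable territory", call. = FALSE)

  with_seed(seed, {
    wi <- sample.int(length(wt), total_reads, replace = TRUE, prob = wt)
    w <- genome$window
    clen <- genome$chromosomes$length[match(genome$windows$chrom[wi],
                                            genome$chromosomes$name)]
    rs <- genome$windows$start[wi] + floor(runif(total_reads) * w)
    rs <- pmin(rs, pmax(clen - read_length, 0))
    pa <- hap$a[wi] / pmax(cnw[wi], 1)
    haps <- ifelse(runif(total_reads) < pa, "A", "B")
    reads <- data.frame(chrom = genome$windows$chrom[wi], start = rs,
                        end = rs + read_length, hap = haps, mapq = 60L,
                        stringsAsFactors = FALSE)
    sim_output(reads, 1, total_reads, 0L,
               tally_allele_depths(reads, genome$het_sites, read_length),
               truth, genome, tally_window_counts(reads, genome),
               if (!is.null(bins))
                 count_reads(bins, reads, total_reads = total_reads))
  })
}

# Row index into genome$windows for (chrom, 0-based position).
window_index <- function(genome, chrom, pos) {
  nwin <- as.integer(genome$chromosomes$length / genome$window)
  off <- setNames(c(0L, cumsum(nwin))[seq_along(nwin)],
                  genome$chromosomes$name)
  off[chrom] + floor(pos / genome$window) + 1L
}
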