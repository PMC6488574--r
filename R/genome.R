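#' Build a synthetic reference genome model
#'
#' Produces the reference-side inputs that the binning and simulation
#' operations need: chromosome lengths, a per-window GC-fraction track, a
#' per-window uniquely-mappable-fraction track, and a set of phased
#' heterozygous sites. This is a synthetic stand-in for the hg19/GRCh38
#' tracks a real pipeline would load; it emulates their statistical shape
#' (smooth GC variation, mostly-mappable genome with depressed patches), not
#' any particular genome.
#'
#' GC is a smoothed Gaussian process rescaled to `gc_mean`/`gc_sd` and
#' clamped to the interval 0.2--0.8; mappability is 1 except in a random fraction of
#' windows drawn from `low_map_range`. Heterozygous sites are uniformly
#' placed, unique and sorted; haplotype A carries the reference allele and
#' haplotype B the alternate (a synthetic phasing convention).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length(s) in bases, recycled to `n_chrom`.
#'   Each must be a multiple of `window`.
#' @param window Track window size in bases (resolution of GC/mappability).
#' @param gc_mean,gc_sd Target mean and sd of the GC track.
#' @param gc_smooth Moving-average width (in windows) of the GC process.
#' @param low_map_frac Fraction of windows with depressed mappability.
#' @param low_map_range Range of mappability values in depressed windows.
#' @param n_het_sites Total number of heterozygous sites across the genome.
#' @param seed Integer seed; the model is reproducible given the seed.
#' @return An object of class `genome_model`: a list with `chromosomes`
#'   (data.frame name/length), `window`, `windows` (data.frame chrom, start,
#'   end (0-based half-open), gc, mappability), `het_sites` (data.frame
#'   chrom, pos (1-based), ref, alt), and `seed`.
#' @examples
#' g <- make_genome(n_chrom = 2, chrom_length = 1e6, window = 1e4, seed = 1)
#' g
#' @export
make_genome <- function(n_chrom = 2L, chrom_length = 10e6, window = 1e4,
                        gc_mean = 0.41, gc_sd = 0.04, gc_smooth = 25L,
                        low_map_frac = 0.03, low_map_range = c(0.3, 0.9),
                        n_het_sites = 0L, seed = 1L) {
  stop_if_not_positive(n_chrom, "n_chrom")
  stop_if_not_positive(window, "window")
  if (!is.numeric(chrom_length) || any(chrom_length <= 0))
    stop("`chrom_length` must be positive", call. = FALSE)
  lens <- rep_len(as.numeric(chrom_length), n_chrom)
  if (any(window > lens))
    stop("`window` exceeds a chromosome length", call. = FALSE)
  if (any(lens %% window != 0))
    stop("each chromosome length must be a multiple of `window`", call. = FALSE)
  if (low_map_frac < 0 || low_map_frac > 1)
    stop("`low_map_frac` must be in [0, 1]", call. = FALSE)

  chroms <- data.frame(name = paste0("chr", seq_len(n_chrom)),
                       length = lens, stringsAsFactors = FALSE)

  with_seed(seed, {
    win_list <- vector("list", n_chrom)
    for (i in seq_len(n_chrom)) {
      nwin <- as.integer(lens[i] / window)
      gc <- if (nwin == 1L) gc_mean else {
        k <- max(1L, min(as.integer(gc_smooth), nwin))
        z <- stats::filter(rnorm(nwin), rep(1 / k, k), sides = 2,
                           circular = TRUE)
        z <- as.numeric(z)
        if (sd(z) > 0) z <- (z - mean(z)) / sd(z)
        pmin(pmax(gc_mean + gc_sd * z, 0.2), 0.8)
      }
      mp <- rep(1, nwin)
      n_low <- round(low_map_frac * nwin)
      if (n_low > 0) {
        idx <- sample.int(nwin, n_low)
        mp[idx] <- runif(n_low, low_map_range[1], low_map_range[2])
      }
      start <- (seq_len(nwin) - 1L) * window
      win_list[[i]] <- data.frame(chrom = chroms$name[i], start = start,
                                  end = start + window, gc = gc,
                                  mappability = mp, stringsAsFactors = FALSE)
    }
    windows <- do.call(rbind, win_list)

    het <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
    if (n_het_sites > 0) {
      per <- as.vector(round(n_het_sites * lens / sum(lens)))
      per[n_chrom] <- n_het_sites - sum(per[-n_chrom])
      site_list <- vector("list", n_chrom)
      bases <- c("A", "C", "G", "T")
      for (i in seq_len(n_chrom)) {
        k <- per[i]
        if (k <= 0) next
        if (k > lens[i] - 2)
          stop("more het sites requested than positions available", call. = FALSE)
        pos <- sort(sample.int(lens[i] - 2L, k)) + 1 # 1-based, strictly inside
        ref <- sample(bases, k, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
        site_list[[i]] <- data.frame(chrom = chroms$name[i], pos = pos,
                                     ref = ref, alt = unname(alt),
                                     stringsAsFactors = FALSE)
      }
      het <- do.call(rbind, site_list)
      rownames(het) <- NULL
    }

    structure(list(chromosomes = chroms, window = window, windows = windows,
                   het_sites = het, seed = seed),
              class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("Synthetic genome model: %d chromosome(s), %g b total, %g-b windows\n",
              nrow(x$chromosomes), sum(x$chromosomes$length), x$window))
  cat(sprintf("  GC %.3f +/- %.3f; mean mappability %.3f; %d het site(s)\n",
              mean(x$windows$gc), sd(x$windows$gc),
              mean(x$windows$mappability), nrow(x$het_sites)))
  invisible(x)
}

#' Draw a ground-truth copy-number profile
#'
#' Places `n_events` non-overlapping copy-number events on a genome model,
#' with sizes uniform in `size_range` (snapped to the window grid) and copy
#' numbers drawn from `cn_states` excluding the baseline. The rest of the
#' genome sits at `baseline` copies.
#'
#' @param genome A [make_genome()] model.
#' @param n_events Number of events; 0 gives a flat profile.
#' @param size_range Event size range in bases.
#' @param cn_states Integer copy numbers events may take (baseline removed).
#' @param baseline Baseline (background) integer ploidy, >= 1.
#' @param seed Integer seed.
#' @param max_tries Bounded retries for non-overlapping placement before
#'   erroring.
#' @return An object of class `truth_profile`: list with `events`
#'   (data.frame chrom, start, end (0-based half-open), cn) and
#'   `baseline_ploidy`.
#' @examples
#' g <- make_genome(n_chrom = 2, chrom_length = 10e6, seed = 1)
#' tp <- make_truth_profile(g, n_events = 4, size_range = c(5e5, 2e6), seed = 2)
#' tp$events
#' @export
make_truth_profile <- function(genome, n_events = 5L,
                               size_range = c(1e6, 3e6),
                               cn_states = c(1L, 3L), baseline = 2L,
                               seed = 1L, max_tries = 1000L) {
  stopifnot(inherits(genome, "genome_model"))
  if (baseline < 1 || baseline != round(baseline))
    stop("`baseline` must be an integer >= 1", call. = FALSE)
  states <- setdiff(as.integer(cn_states), as.integer(baseline))
  if (n_events > 0 && length(states) == 0)
    stop("`cn_states` must contain a non-baseline state", call. = FALSE)
  if (any(states < 0)) stop("copy numbers must be >= 0", call. = FALSE)
  lens <- genome$chromosomes$length
  w <- genome$window
  if (size_range[1] > max(lens))
    stop("`size_range` does not fit within any chromosome", call. = FALSE)
  if (n_events * size_range[1] > sum(lens))
    stop("requested total event span exceeds the genome size", call. = FALSE)

  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), cn = integer(),
                      stringsAsFactors = FALSE)
  if (n_events == 0)
    return(structure(list(events = empty, baseline_ploidy = as.integer(baseline)),
                     class = "truth_profile"))

  with_seed(seed, {
    ev <- empty
    tries <- 0L
    while (nrow(ev) < n_events && tries < max_tries * n_events) {
      tries <- tries + 1L
      ci <- sample.int(length(lens), 1L, prob = lens)
      size <- max(w, round(runif(1, size_range[1], size_range[2]) / w) * w)
      if (size > lens[ci]) next
      start <- sample.int(as.integer((lens[ci] - size) / w) + 1L, 1L) * w - w
      end <- start + size
      same <- ev$chrom == genome$chromosomes$name[ci]
      if (any(same & start < ev$end & end > ev$start)) next
      ev <- rbind(ev, data.frame(chrom = genome$chromosomes$name[ci],
                                 start = start, end = end,
                                 cn = sample(states, 1L),
                                 stringsAsFactors = FALSE))
    }
    if (nrow(ev) < n_events)
      stop("could not place non-overlapping events within bounded retries",
           call. = FALSE)
    ev <- ev[order(match(ev$chrom, genome$chromosomes$name), ev$start), ]
    rownames(ev) <- NULL
    structure(list(events = ev, baseline_ploidy = as.integer(baseline)),
              class = "truth_profile")
  })
}

#' Construct a truth profile from explicit events
#'
#' Companion constructor to [make_truth_profile()] for hand-specified
#' ground truth (e.g. balanced designs in calibration experiments).
#'
#' @param events data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and integer `cn`; events must not overlap.
#' @param baseline_ploidy Integer background ploidy, >= 1.
#' @return An object of class `truth_profile`.
#' @export
truth_profile <- function(events, baseline_ploidy = 2L) {
  stopifnot(is.data.frame(events),
            all(c("chrom", "start", "end", "cn") %in% names(events)))
  if (baseline_ploidy < 1 || baseline_ploidy != round(baseline_ploidy))
    stop("`baseline_ploidy` must be an integer >= 1", call. = FALSE)
  if (nrow(events)) {
    if (any(events$cn < 0) || any(events$cn != round(events$cn)))
      stop("event copy numbers must be non-negative integers", call. = FALSE)
    if (any(events$end <= events$start))
      stop("events must have end > start", call. = FALSE)
    for (cname in unique(events$chrom)) {
      e <- events[events$chrom == cname, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
        stop("events must not overlap", call. = FALSE)
    }
    events <- events[order(events$chrom, events$start), ]
    events$cn <- as.integer(events$cn)
    rownames(events) <- NULL
  }
  structure(list(events = events,
                 baseline_ploidy = as.integer(baseline_ploidy)),
            class = "truth_profile")
}

#' @export
print.truth_profile <- function(x, ...) {
  cat(sprintf("Truth profile: baseline ploidy %d, %d event(s)\n",
              x$baseline_ploidy, nrow(x$events)))
  if (nrow(x$events)) print(x$events, row.names = FALSE)
  invisible(x)
}

#' Per-window true copy number
#'
#' @param truth A [make_truth_profile()] object.
#' @param genome The genome model the truth was drawn on.
#' @return Integer copy number for each row of `genome$windows` (a window
#'   takes an event's copy number when its start lies inside the event;
#'   events are window-aligned by construction).
#' @export
truth_cn_windows <- function(truth, genome) {
  stopifnot(inherits(truth, "truth_profile"), inherits(genome, "genome_model"))
  cn <- rep.int(truth$baseline_ploidy, nrow(genome$windows))
  if (nrow(truth$events)) {
    for (i in seq_len(nrow(truth$events))) {
      e <- truth$events[i, ]
      hit <- genome$windows$chrom == e$chrom &
        genome$windows$start >= e$start & genome$windows$start < e$end
      cn[hit] <- e$cn
    }
  }
  cn
}

#' Per-bin true copy number
#'
#' Assigns each bin of a [build_dynamic_bins()] bin set the copy number of
#' the truth event containing its midpoint (baseline otherwise).
#'
#' @param truth A [make_truth_profile()] object.
#' @param binset A `bin_set`.
#' @return Integer copy number per bin.
#' @export
truth_cn_bins <- function(truth, binset) {
  stopifnot(inherits(truth, "truth_profile"), inherits(binset, "bin_set"))
  b <- binset$bins
  mid <- (b$start + b$end) / 2
  cn <- rep.int(truth$baseline_ploidy, nrow(b))
  if (nrow(truth$events)) {
    for (i in seq_len(nrow(truth$events))) {
      e <- truth$events[i, ]
      hit <- b$chrom == e$chrom & mid >= e$start & mid < e$end
      cn[hit] <- e$cn
    }
  }
  cn
}

# Haplotype copy counts for a total copy number: copies alternate between the
# two haplotypes, A first (cn 3 = 2A + 1B; cn 1 = 1A; cn 0 = none).
hap_copy_counts <- function(cn) {
  list(a = ceiling(cn / 2), b = floor(cn / 2))
}
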