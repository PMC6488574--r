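#' GC-bias correction of bin counts by locally weighted regression
#'
#' Fits a LOWESS curve of count versus bin GC fraction over non-dropout
#' bins and divides each count by its fitted value (multiplicative bias
#' model), renormalizing the corrected ratios to mean 1. Dropout bins are
#' excluded from the fit and assigned a corrected value of 0. The
#' pre-correction GC trend is retained for quality-control plotting.
#'
#' @param counts A `bin_counts` object or integer vector aligned to `binset`.
#' @param binset A `bin_set` with per-bin `gc`.
#' @param span LOWESS smoother span in (0, 1].
#' @return List with `ratio` (corrected, mean-1 over non-dropout bins; 0 at
#'   dropout bins) and `gc_fit` (data.frame gc, count, fitted — the
#'   diagnostic trend before correction).
#' @export
gc_correct <- function(counts, binset, span = 0.3) {
  x <- if (inherits(counts, "bin_counts")) counts$counts else counts
  stopifnot(inherits(binset, "bin_set"))
  if (length(x) != nrow(binset$bins))
    stop("counts are not aligned to the bin set", call. = FALSE)
  if (span <= 0 || span > 1) stop("`span` must be in (0, 1]", call. = FALSE)
  keep <- x > 0
  if (sum(keep) < 10)
    stop("fewer than 10 non-dropout bins: cannot fit a GC curve",
         call. = FALSE)
  gc <- binset$bins$gc
  fit <- lowess(gc[keep], x[keep], f = span)
  fitted <- approx(fit$x, fit$y, xout = gc[keep], rule = 2, ties = mean)$y
  fitted <- pmax(fitted, 1e-8 * mean(x[keep]))
  r <- x[keep] / fitted
  r <- r / mean(r)
  ratio <- numeric(length(x))
  ratio[keep] <- r
  list(ratio = ratio,
       gc_fit = data.frame(gc = gc[keep], count = x[keep], fitted = fitted))
}

#' Absolute copy-number determination by residual minimization
#'
#' Grid search over candidate ploidies: for each candidate P the bin ratios
#' are scaled to P and the residual error — the summed squared deviation
#' between the scaled values and their nearest integers — is computed over
#' non-dropout bins. The candidate with the smallest residual is the
#' inferred ploidy; ties (within `tie_tol`, e.g. exact multiples of the true
#' ploidy) break toward the smallest candidate.
#'
#' @param raw_ratio Mean-1 corrected ratios (0 marks dropout bins).
#' @param grid Candidate ploidies, e.g. `seq(1.5, 6, by = 0.05)`.
#' @param tie_tol Residuals within this of the minimum count as ties.
#' @return List with `ploidy` and `curve` (data.frame ploidy, residual).
#' @examples
#' ratio <- rep(c(2, 3), each = 50) / 2.5
#' acd_ploidy(ratio)$ploidy # 2.5 (5.0 also fits exactly; ties break low)
#' @export
acd_ploidy <- function(raw_ratio, grid = seq(1.5, 6, by = 0.05),
                       tie_tol = 1e-9) {
  if (length(grid) == 0) stop("empty ploidy grid", call. = FALSE)
  if (any(grid < 1) || any(grid > 8))
    stop("ploidy grid must lie within [1, 8]", call. = FALSE)
  r <- raw_ratio[raw_ratio > 0]
  if (!length(r)) stop("no non-dropout bins", call. = FALSE)
  res <- vapply(grid, function(p) {
    s <- p * r
    sum((s - floor(s + 0.5))^2)
  }, numeric(1))
  best <- min(res)
  list(ploidy = min(grid[res <= best + tie_tol]),
       curve = data.frame(ploidy = grid, residual = res))
}

#' Circular binary segmentation with permutation significance
#'
#' Recursively finds, within each chromosome, the circular arc whose mean
#' most differs from its complement (standardized arc statistic), accepts
#' the split when its permutation p-value is below `alpha`, and recurses
#' into the resulting pieces. Short segments (fewer than `min_width` bins)
#' are then merged into the neighbour with the nearest mean. Deterministic
#' given `seed`.
#'
#' @param x Numeric series (e.g. scaled copy numbers), no NAs.
#' @param chrom Chromosome label per element (segmentation never crosses a
#'   boundary); default treats `x` as one chromosome.
#' @param alpha Significance level for accepting a split.
#' @param nperm Number of permutations per tested split.
#' @param seed Integer seed for the permutation stream.
#' @param min_width Minimum segment width in bins (merged below this);
#'   set to 1 to disable pruning.
#' @return An object of class `segment_set`: data.frame `segments` with
#'   `chrom`, `start_bin`, `end_bin` (1-based inclusive indices into `x`),
#'   `n_bins`, `mean`, `integer_cn` (= mean rounded half away from zero),
#'   plus `alpha` and `nperm`.
#' @examples
#' x <- c(rnorm(50, 2, 0.2), rnorm(50, 4, 0.2))
#' cbs_segment(x, seed = 1)$segments
#' @export
cbs_segment <- function(x, chrom = NULL, alpha = 0.01, nperm = 1000L,
                        seed = NULL, min_width = 3L) {
  if (anyNA(x)) stop("`x` must not contain NA; drop dropout bins first",
                     call. = FALSE)
  if (is.null(chrom)) chrom <- rep("chr1", length(x))
  stopifnot(length(chrom) == length(x))
  if (length(x) < 2) stop("need a series of length >= 2", call. = FALSE)

  with_seed(seed, {
    segs <- list()
    for (cname in unique(chrom)) {
      idx <- which(chrom == cname)
      v <- x[idx]
      cps <- if (length(v) >= 4) cbs_recurse(v, alpha, nperm) else integer()
      b <- c(0L, sort(cps), length(v))
      sdf <- data.frame(chrom = cname,
                        start_bin = idx[b[-length(b)] + 1L],
                        end_bin = idx[b[-1L]],
                        stringsAsFactors = FALSE)
      sdf$n_bins <- b[-1L] - b[-length(b)]
      sdf$mean <- vapply(seq_len(nrow(sdf)), function(i)
        mean(v[(b[i] + 1L):b[i + 1L]]), numeric(1))
      if (min_width > 1L) sdf <- merge_short_segments(sdf, min_width)
      segs[[cname]] <- sdf
    }
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    out$integer_cn <- as.integer(round_half_away(out$mean))
    structure(list(segments = out, alpha = alpha, nperm = as.integer(nperm)),
              class = "segment_set")
  })
}

# Recursive splitter; returns 0-based breakpoints relative to v.
cbs_recurse <- function(v, alpha, nperm) {
  n <- length(v)
  if (n < 4) return(integer())
  scan <- .cbs_scan_cpp(v)
  if (scan$sd <= 0 || !is.finite(scan$stat) || scan$stat <= 0)
    return(integer())
  stop_count <- ceiling(alpha * (nperm + 1))
  pc <- .cbs_perm_count_cpp(v, scan$stat, as.integer(nperm),
                            as.integer(stop_count))
  p <- (pc$count + 1) / (pc$nperm_done + 1)
  if (p >= alpha) return(integer())
  i <- scan$i; j <- scan$j
  cps <- c(if (i > 0L) i, if (j < n) j)
  parts <- list(c(1L, i), c(i + 1L, j), c(j + 1L, n))
  for (p_ in parts) {
    if (p_[2] - p_[1] + 1L >= 4L && p_[1] <= p_[2]) {
      sub <- cbs_recurse(v[p_[1]:p_[2]], alpha, nperm)
      cps <- c(cps, sub + p_[1] - 1L)
    }
  }
  sort(unique(cps))
}

# Merge segments narrower than min_width into the neighbour with the
# nearest mean, recomputing the weighted mean.
merge_short_segments <- function(sdf, min_width) {
  while (nrow(sdf) > 1L && any(sdf$n_bins < min_width)) {
    k <- which.min(sdf$n_bins)
    if (sdf$n_bins[k] >= min_width) break
    nb <- c(if (k > 1L) k - 1L, if (k < nrow(sdf)) k + 1L)
    tgt <- nb[which.min(abs(sdf$mean[nb] - sdf$mean[k]))]
    lo <- min(k, tgt); hi <- max(k, tgt)
    wsum <- sdf$n_bins[lo] + sdf$n_bins[hi]
    sdf$mean[lo] <- (sdf$mean[lo] * sdf$n_bins[lo] +
                     sdf$mean[hi] * sdf$n_bins[hi]) / wsum
    sdf$end_bin[lo] <- sdf$end_bin[hi]
    sdf$n_bins[lo] <- wsum
    sdf <- sdf[-hi, , drop = FALSE]
  }
  rownames(sdf) <- NULL
  sdf
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("Segment set: %d segment(s), alpha = %g, %d permutations\n",
              nrow(x$segments), x$alpha, x$nperm))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Per-bin integer copy numbers from a segment set
#'
#' Every bin inherits its segment's mean rounded to the nearest integer,
#' halves away from zero.
#'
#' @param segments A `segment_set`.
#' @param n_bins Length of the output vector (defaults to the largest bin
#'   index in the segments).
#' @return Integer vector; bins not covered by any segment are NA.
#' @export
integer_profile <- function(segments, n_bins = NULL) {
  stopifnot(inherits(segments, "segment_set"))
  s <- segments$segments
  if (is.null(n_bins)) n_bins <- max(s$end_bin)
  out <- rep(NA_integer_, n_bins)
  for (i in seq_len(nrow(s)))
    out[s$start_bin[i]:s$end_bin[i]] <- s$integer_cn[i]
  out
}

#' Full single-cell copy-number call
#'
#' Chains the copy-number core on one sample: GC correction, absolute
#' copy-number (ploidy) determination over a grid, scaling, circular binary
#' segmentation, and per-bin integer copy numbers. Dropout bins are
#' excluded from the residual, the segmentation input, and the MAD, and are
#' reported with NA copy number.
#'
#' @param counts A `bin_counts` object aligned to `binset`.
#' @param binset A `bin_set`.
#' @param gc_span LOWESS span for [gc_correct()].
#' @param ploidy_grid Candidate ploidies for [acd_ploidy()].
#' @param cbs_alpha,cbs_nperm,min_width Segmentation controls, see
#'   [cbs_segment()].
#' @param seed Integer seed (CBS permutations).
#' @return An object of class `cn_profile`: `sample_id`, `binset`,
#'   `raw_ratio` (0 at dropout), `ploidy`, `residual_curve`, `scaled_cn`
#'   (= ratio x ploidy; NA at dropout), `segments` (with genomic
#'   coordinates), `integer_cn` per bin (NA at dropout), `mad`, `dropout`,
#'   `mapping_rate` and `gc_fit`.
#' @export
cnv_call <- function(counts, binset, gc_span = 0.3,
                     ploidy_grid = seq(1.5, 6, by = 0.05),
                     cbs_alpha = 0.01, cbs_nperm = 1000L, min_width = 3L,
                     seed = 1L) {
  stopifnot(inherits(counts, "bin_counts"), inherits(binset, "bin_set"))
  gcres <- gc_correct(counts, binset, span = gc_span)
  ratio <- gcres$ratio
  acd <- acd_ploidy(ratio, grid = ploidy_grid)
  nd <- which(ratio > 0)
  scaled <- rep(NA_real_, length(ratio))
  scaled[nd] <- ratio[nd] * acd$ploidy

  segs <- cbs_segment(scaled[nd], chrom = binset$bins$chrom[nd],
                      alpha = cbs_alpha, nperm = cbs_nperm, seed = seed,
                      min_width = min_width)
  # map series indices back to bin indices and genomic coordinates
  s <- segs$segments
  s$start_bin <- nd[s$start_bin]
  s$end_bin <- nd[s$end_bin]
  s$start <- binset$bins$start[s$start_bin]
  s$end <- binset$bins$end[s$end_bin]
  segs$segments <- s

  icn <- rep(NA_integer_, length(ratio))
  for (i in seq_len(nrow(s))) {
    span_ <- s$start_bin[i]:s$end_bin[i]
    icn[intersect(span_, nd)] <- s$integer_cn[i]
  }

  structure(list(sample_id = counts$sample_id, binset = binset,
                 raw_ratio = ratio, ploidy = acd$ploidy,
                 residual_curve = acd$curve, scaled_cn = scaled,
                 segments = segs, integer_cn = icn,
                 mad = mad_adjacent(scaled, binset$bins$chrom),
                 dropout = dropout_ratio(counts),
                 mapping_rate = counts$mapped_reads / counts$total_reads,
                 gc_fit = gcres$gc_fit),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("Copy-number profile [%s]\n", x$sample_id))
  cat(sprintf("  ploidy %.2f | MAD %.3f | dropout %.3f | %d segment(s)\n",
              x$ploidy, x$mad, x$dropout, nrow(x$segments$segments)))
  invisible(x)
}

#' Copy-number detection rate against reference events
#'
#' Scores how many reference copy-number events a single-cell integer
#' profile recovers: an event counts as detected when at least
#' `min_overlap` of its bins carry the event's integer copy number in the
#' cell (NA bins count as mismatches).
#'
#' @param integer_cn Per-bin integer copy numbers of the cell (NA allowed).
#' @param truth A `truth_profile` of reference events (the denominator).
#' @param binset The `bin_set` both profiles live on.
#' @param min_overlap Required fraction of event bins matching, in (0, 1].
#' @return Fraction of reference events detected.
#' @export
detection_rate <- function(integer_cn, truth, binset, min_overlap = 0.5) {
  stopifnot(inherits(truth, "truth_profile"), inherits(binset, "bin_set"))
  if (min_overlap <= 0 || min_overlap > 1)
    stop("`min_overlap` must be in (0, 1]", call. = FALSE)
  ev <- truth$events
  if (nrow(ev) == 0) stop("no reference events to score", call. = FALSE)
  if (length(integer_cn) != nrow(binset$bins))
    stop("profile not aligned to the bin set", call. = FALSE)
  b <- binset$bins
  mid <- (b$start + b$end) / 2
  det <- vapply(seq_len(nrow(ev)), function(i) {
    sel <- b$chrom == ev$chrom[i] & mid >= ev$start[i] & mid < ev$end[i]
    if (!any(sel)) return(FALSE)
    cn <- integer_cn[sel]
    mean(!is.na(cn) & cn == ev$cn[i]) >= min_overlap
  }, logical(1))
  mean(det)
}
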