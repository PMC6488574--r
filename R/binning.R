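#' Construct a bin set from explicit intervals
#'
#' Low-level constructor used by [build_dynamic_bins()] and by readers of
#' externally supplied bin files. Bins must tile each chromosome without
#' overlap, in order, using 0-based half-open coordinates.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end` and
#'   optionally `mappable` (uniquely mappable positions per bin) and `gc`.
#' @param target_size Nominal mappable content per bin, in bases.
#' @param window Resolution (in bases) of the underlying track, if known.
#' @return An object of class `bin_set`.
#' @export
bin_set <- function(bins, target_size = NA_real_, window = NA_real_) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end") %in% names(bins)))
  if (any(bins$end <= bins$start))
    stop("bins must have end > start", call. = FALSE)
  for (cname in unique(bins$chrom)) {
    b <- bins[bins$chrom == cname, ]
    if (is.unsorted(b$start, strictly = TRUE) ||
        any(b$start[-1] < b$end[-nrow(b)]))
      stop("bins must be sorted and non-overlapping within chromosomes",
           call. = FALSE)
  }
  if (is.null(bins$mappable)) bins$mappable <- bins$end - bins$start
  if (is.null(bins$gc)) bins$gc <- NA_real_
  rownames(bins) <- NULL
  structure(list(bins = bins, target_size = target_size, window = window),
            class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("Bin set: %d bins over %d chromosome(s), target %g mappable b/bin\n",
              nrow(x$bins), length(unique(x$bins$chrom)), x$target_size))
  invisible(x)
}

#' @export
length.bin_set <- function(x) nrow(x$bins)

#' Dynamic genome binning by equal uniquely-mappable content
#'
#' Partitions each chromosome into bins holding (nearly) equal amounts of
#' uniquely mappable sequence, so that bins in poorly mappable regions span
#' proportionally more genomic territory. The per-bin quota is
#' `target_size` times the genome-wide mean mappability, which makes bins
#' span exactly `target_size` bases on a fully mappable genome. Track
#' windows are accumulated greedily until the quota is met; each
#' chromosome's final partial bin is kept if it holds at least half the
#' quota and merged into its neighbour otherwise. Per-bin GC is the
#' mappability-weighted mean of the member windows.
#'
#' @param genome A [make_genome()] model (or a data.frame shaped like its
#'   `windows` element: chrom, start, end, gc, mappability).
#' @param target_size Nominal bin size in bases (e.g. 5e4 for 50-kb bins).
#'   Must be at least the track window size.
#' @return A `bin_set` whose bins carry `mappable` content and `gc`.
#' @examples
#' g <- make_genome(n_chrom = 1, chrom_length = 1e6, window = 1e4,
#'                  low_map_frac = 0, seed = 1)
#' bs <- build_dynamic_bins(g, 5e4)
#' nrow(bs$bins) # 20 equal bins on a fully mappable 1-Mb chromosome
#' @export
build_dynamic_bins <- function(genome, target_size = 5e4) {
  windows <- if (inherits(genome, "genome_model")) genome$windows else genome
  stopifnot(is.data.frame(windows),
            all(c("chrom", "start", "end", "mappability") %in% names(windows)))
  win <- unique(windows$end - windows$start)
  if (length(win) > 1L) win <- max(win)
  if (target_size < win)
    stop("`target_size` must be at least the track window size", call. = FALSE)
  if (is.null(windows$gc)) windows$gc <- NA_real_

  quota <- target_size * mean(windows$mappability)
  out <- list()
  for (cname in unique(windows$chrom)) {
    wdf <- windows[windows$chrom == cname, ]
    m <- wdf$mappability * (wdf$end - wdf$start)
    if (sum(m) <= 0) {
      warning(sprintf("chromosome %s has no mappable content; no bins emitted",
                      cname), call. = FALSE)
      next
    }
    # a window joins the bin its cumulative-content endpoint falls in
    id <- pmax(ceiling((cumsum(m) - 1e-9) / quota), 1L)
    last <- max(id)
    if (last > 1L && sum(m[id == last]) < quota / 2) id[id == last] <- last - 1L
    agg <- lapply(split(seq_along(id), id), function(ix) {
      wt <- m[ix]
      data.frame(chrom = cname, start = wdf$start[ix[1L]],
                 end = wdf$end[ix[length(ix)]], mappable = sum(wt),
                 gc = if (sum(wt) > 0) sum(wdf$gc[ix] * wt) / sum(wt)
                      else mean(wdf$gc[ix]),
                 stringsAsFactors = FALSE)
    })
    out[[cname]] <- do.call(rbind, agg)
  }
  if (!length(out)) stop("no bins could be built", call. = FALSE)
  bin_set(do.call(rbind, out), target_size = target_size, window = win)
}

#' Count reads per bin
#'
#' Assigns each alignment passing the mapping-quality gate to the bin
#' containing its start coordinate (the conventional, order-independent
#' choice; `assign = "midpoint"` is available). Records on chromosomes
#' absent from the bin set are skipped and counted, not an error. The MapQ
#' threshold operationalizes "uniquely mapped" and defaults to 15.
#'
#' @param binset A `bin_set`.
#' @param alignments BED-like data.frame with columns `chrom`, `start`
#'   (0-based) and `mapq` (an `end` column is accepted and used for
#'   midpoints).
#' @param mapq_min Minimum mapping quality (inclusive).
#' @param assign Coordinate used for bin assignment.
#' @param sample_id Sample label carried into downstream reports.
#' @param total_reads Total reads sequenced for this sample (defaults to the
#'   number of alignment records, i.e. assumes all reads mapped).
#' @return An object of class `bin_counts`: list with `sample_id`, integer
#'   `counts` aligned to the bin set, `mapped_reads`, `total_reads`, and
#'   `n_skipped` (records off known chromosomes or past binned territory).
#' @export
count_reads <- function(binset, alignments, mapq_min = 15,
                        assign = c("start", "midpoint"),
                        sample_id = "sample", total_reads = NULL) {
  stopifnot(inherits(binset, "bin_set"), is.data.frame(alignments))
  assign <- match.arg(assign)
  if (!all(c("chrom", "start") %in% names(alignments)))
    stop("alignments need `chrom` and `start` columns", call. = FALSE)
  mq <- if (is.null(alignments$mapq)) rep(Inf, nrow(alignments))
        else alignments$mapq
  keep <- mq >= mapq_min
  aln <- alignments[keep, , drop = FALSE]
  pos <- if (assign == "midpoint" && !is.null(aln$end))
    floor((aln$start + aln$end) / 2) else aln$start

  b <- binset$bins
  counts <- integer(nrow(b))
  n_skip <- 0L
  for (cname in unique(b$chrom)) {
    bi <- which(b$chrom == cname)
    sel <- aln$chrom == cname
    if (!any(sel)) next
    p <- pos[sel]
    idx <- findInterval(p, b$start[bi])
    ok <- idx >= 1L & p < b$end[bi][pmax(idx, 1L)]
    n_skip <- n_skip + sum(!ok)
    counts[bi] <- counts[bi] + tabulate(idx[ok], nbins = length(bi))
  }
  n_skip <- n_skip + sum(!aln$chrom %in% b$chrom)
  mapped <- nrow(aln)
  if (is.null(total_reads)) total_reads <- nrow(alignments)
  structure(list(sample_id = sample_id, counts = counts,
                 mapped_reads = mapped, total_reads = total_reads,
                 n_skipped = n_skip),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("Bin counts [%s]: %d bins, %g assigned reads, dropout %.3f\n",
              x$sample_id, length(x$counts), sum(x$counts),
              mean(x$counts == 0)))
  invisible(x)
}

#' Dropout ratio: fraction of bins with zero uniquely mapped reads
#'
#' A genome-coverage proxy; bins with no uniquely mapped reads are defined
#' as dropout.
#'
#' @param counts A `bin_counts` object or a non-negative integer vector.
#' @return Fraction between 0 and 1.
#' @export
dropout_ratio <- function(counts) {
  x <- if (inherits(counts, "bin_counts")) counts$counts else counts
  if (length(x) == 0) stop("no bins: dropout ratio undefined", call. = FALSE)
  mean(x == 0)
}
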