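#' Adjacent-bin MAD: the amplification-evenness metric
#'
#' Collects the absolute copy-number differences between adjacent bins
#' within each chromosome — never across a chromosome boundary, so
#' aneuploidy or large CNVs do not inflate the value — and summarizes them.
#' The defining summary is the mean; a median mode is exposed because the
#' metric is often referred to as a median absolute deviation in the
#' single-cell literature.
#'
#' Dropout bins (NA) are skipped: only pairs of adjacent bins that are both
#' non-dropout contribute.
#'
#' @param cn Per-bin copy numbers (e.g. `scaled_cn`), NA marking dropout.
#' @param chrom Chromosome label per bin; default treats all bins as one
#'   chromosome.
#' @param mode `"mean"` (default) or `"median"` summary of the absolute
#'   adjacent differences.
#' @return The MAD value (dimensionless, on the copy-number scale).
#' @examples
#' mad_adjacent(c(2, 3, 2, 3))                     # 1
#' mad_adjacent(c(2, 2, 5, 5), c("a", "a", "b", "b")) # 0: jump crosses chroms
#' @export
mad_adjacent <- function(cn, chrom = NULL, mode = c("mean", "median")) {
  mode <- match.arg(mode)
  if (is.null(chrom)) chrom <- rep("chr1", length(cn))
  stopifnot(length(chrom) == length(cn))
  diffs <- unlist(lapply(split(cn, factor(chrom, levels = unique(chrom))),
                         function(v) {
    if (length(v) < 2) return(numeric())
    d <- abs(diff(v))
    d[!is.na(d)]
  }), use.names = FALSE)
  if (!length(diffs))
    stop("no valid adjacent bin pair: MAD undefined", call. = FALSE)
  if (mode == "mean") mean(diffs) else median(diffs)
}

#' Quality-control gate on MAD and dropout ratio
#'
#' A cell is valid when MAD and dropout ratio are both at or below their
#' thresholds (inclusive bounds).
#'
#' @param mad Adjacent-bin MAD of the cell.
#' @param dropout Dropout ratio of the cell.
#' @param mad_threshold,dropout_threshold Inclusive pass thresholds.
#' @return List with `passed` (logical) and `reasons` (character vector of
#'   failing metrics, empty when passing).
#' @examples
#' qc_gate(0.4, 0.2)$passed  # TRUE: a typical emulsion-MDA cell
#' qc_gate(1.3, 0.2)$reasons # "MAD": a typical one-pot MDA cell fails
#' @export
qc_gate <- function(mad, dropout, mad_threshold = 1.0,
                    dropout_threshold = 0.5) {
  stopifnot(is.finite(mad), is.finite(dropout), dropout >= 0, dropout <= 1)
  reasons <- c(if (mad > mad_threshold) "MAD",
               if (dropout > dropout_threshold) "dropout")
  list(passed = length(reasons) == 0L, reasons = as.character(reasons))
}

#' Lorenz curve and Gini coefficient of coverage uniformity
#'
#' Bins are sorted by read count ascending; the curve traces cumulative bin
#' fraction against cumulative read fraction. Perfectly uniform coverage
#' gives the diagonal (Gini 0); concentration of reads in few bins bows the
#' curve away from it. Gini is 1 minus twice the trapezoidal area under the
#' curve.
#'
#' @param counts A `bin_counts` object or non-negative count vector with at
#'   least one nonzero entry.
#' @return List with `points` (data.frame `frac_bins`, `frac_reads`,
#'   starting at (0,0) and ending at (1,1)) and `gini` between 0 and 1.
#' @examples
#' lorenz_curve(rep(5, 10))$gini          # 0: uniform
#' lorenz_curve(c(rep(0, 9), 42))$gini    # (n-1)/n: one-hot extreme
#' @export
lorenz_curve <- function(counts) {
  x <- if (inherits(counts, "bin_counts")) counts$counts else counts
  if (!length(x) || all(x == 0))
    stop("all-zero counts: Lorenz curve undefined", call. = FALSE)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  s <- sort(x)
  n <- length(s)
  fx <- c(0, seq_len(n) / n)
  fy <- c(0, cumsum(s) / sum(s))
  auc <- sum(diff(fx) * (fy[-1] + fy[-length(fy)]) / 2)
  list(points = data.frame(frac_bins = fx, frac_reads = fy),
       gini = 1 - 2 * auc)
}

#' Assemble a per-cell quality-control report
#'
#' Computes the evenness and coverage metrics for one cell and applies the
#' validity gate: adjacent-bin MAD of the scaled copy numbers, dropout
#' ratio, Lorenz curve and Gini of the bin counts.
#'
#' @param profile A `cn_profile` from [cnv_call()].
#' @param counts The `bin_counts` the profile was called from.
#' @param mad_mode Summary mode for [mad_adjacent()].
#' @param mad_threshold,dropout_threshold Gate thresholds, see [qc_gate()].
#' @return An object of class `qc_report` with fields `sample_id`, `mad`,
#'   `mad_mode`, `dropout`, `passed`, `reasons`, the thresholds, `lorenz`
#'   points and `gini`.
#' @export
qc_report <- function(profile, counts, mad_mode = c("mean", "median"),
                      mad_threshold = 1.0, dropout_threshold = 0.5) {
  stopifnot(inherits(profile, "cn_profile"), inherits(counts, "bin_counts"))
  mad_mode <- match.arg(mad_mode)
  mad <- mad_adjacent(profile$scaled_cn, profile$binset$bins$chrom,
                      mode = mad_mode)
  dropout <- dropout_ratio(counts)
  gate <- qc_gate(mad, dropout, mad_threshold, dropout_threshold)
  lz <- lorenz_curve(counts)
  structure(list(sample_id = profile$sample_id, mad = mad,
                 mad_mode = mad_mode, dropout = dropout,
                 passed = gate$passed, reasons = gate$reasons,
                 mad_threshold = mad_threshold,
                 dropout_threshold = dropout_threshold,
                 lorenz = lz$points, gini = lz$gini),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report [%s]: %s\n", x$sample_id,
              if (x$passed) "PASS" else
                paste("FAIL:", paste(x$reasons, collapse = ", "))))
  cat(sprintf("  MAD (%s) %.3f (<= %g) | dropout %.3f (<= %g) | Gini %.3f\n",
              x$mad_mode, x$mad, x$mad_threshold, x$dropout,
              x$dropout_threshold, x$gini))
  invisible(x)
}
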