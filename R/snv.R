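#' Construct/validate a per-site allele-depth table
#'
#' The SNV-side data model: one row per candidate site with reference and
#' alternate read depths for one sample. Positions are 1-based (VCF
#' convention).
#'
#' @param chrom,pos,ref,alt,ref_depth,alt_depth Site coordinates, alleles
#'   and non-negative integer depths (vectors of equal length).
#' @return A data.frame of class `allele_table`, sorted by chrom then pos.
#' @export
allele_table <- function(chrom, pos, ref = "N", alt = "N",
                         ref_depth, alt_depth) {
  n <- length(chrom)
  tab <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    ref = rep_len(as.character(ref), n),
                    alt = rep_len(as.character(alt), n),
                    ref_depth = as.integer(ref_depth),
                    alt_depth = as.integer(alt_depth),
                    stringsAsFactors = FALSE)
  if (any(tab$ref_depth < 0) || any(tab$alt_depth < 0))
    stop("depths must be non-negative", call. = FALSE)
  if (anyDuplicated(tab[c("chrom", "pos", "alt")]))
    stop("(chrom, pos, alt) must be unique", call. = FALSE)
  tab <- tab[order(tab$chrom, tab$pos), ]
  rownames(tab) <- NULL
  class(tab) <- c("allele_table", "data.frame")
  tab
}

as_allele_table <- function(x) {
  if (inherits(x, "allele_table")) return(x)
  stopifnot(is.data.frame(x),
            all(c("chrom", "pos", "ref_depth", "alt_depth") %in% names(x)))
  allele_table(x$chrom, x$pos,
               if (is.null(x$ref)) "N" else x$ref,
               if (is.null(x$alt)) "N" else x$alt,
               x$ref_depth, x$alt_depth)
}

#' Call heterozygous sites from allele depths
#'
#' A site is heterozygous when its total depth reaches `depth_min` and its
#' minor allele frequency `min(ref, alt) / (ref + alt)` reaches `maf_min`
#' (both inclusive). The conventional thresholds are MAF at least 5% with
#' depth at least 5 for amplified single cells, and MAF at least 20% with
#' depth at least 30 for unamplified bulk samples; bulk calls are a strict
#' subset of single-cell calls on the same table.
#'
#' @param table An `allele_table` (or coercible data.frame).
#' @param maf_min Minimum minor allele frequency, in (0, 0.5].
#' @param depth_min Minimum total depth, >= 1.
#' @return The subset of rows called heterozygous, with `maf` and `depth`
#'   columns appended.
#' @examples
#' tab <- allele_table("chr1", c(100, 200), ref_depth = c(27, 4),
#'                     alt_depth = c(3, 4))
#' nrow(call_het_sites(tab, 0.05, 5))  # both pass single-cell thresholds
#' nrow(call_het_sites(tab, 0.20, 30)) # neither passes bulk thresholds
#' @export
call_het_sites <- function(table, maf_min = 0.05, depth_min = 5) {
  tab <- as_allele_table(table)
  if (maf_min <= 0 || maf_min > 0.5)
    stop("`maf_min` must be in (0, 0.5]", call. = FALSE)
  if (depth_min < 1) stop("`depth_min` must be >= 1", call. = FALSE)
  depth <- tab$ref_depth + tab$alt_depth
  maf <- ifelse(depth > 0, pmin(tab$ref_depth, tab$alt_depth) / depth, 0)
  keep <- depth >= depth_min & maf >= maf_min
  out <- tab[keep, , drop = FALSE]
  out$depth <- depth[keep]
  out$maf <- maf[keep]
  rownames(out) <- NULL
  out
}

#' Allele-dropout rate against a bulk heterozygous-site control
#'
#' Restricts to heterozygous sites established in an unamplified bulk
#' control, keeps those the single cell covers to at least `depth_cutoff`
#' reads, and scores a covered site as dropout when either allele has fewer
#' than `alt_evidence_min` supporting reads. The report tabulates the rate
#' across a ladder of depth cutoffs. Sites absent from the cell table count
#' as depth 0; sites outside `bulk_het` never enter the computation.
#'
#' @param cell `allele_table` of the single cell.
#' @param bulk_het data.frame of bulk heterozygous sites (columns `chrom`,
#'   `pos`), e.g. from [call_het_sites()] on the bulk sample.
#' @param depth_cutoffs Integer ladder of minimum cell depths.
#' @param alt_evidence_min Minimum reads per allele for the allele to count
#'   as observed (default 1: any read rescues the allele).
#' @param mask Optional data.frame of intervals (`chrom`, `start`, `end`,
#'   0-based half-open) restricting the analysis, e.g. the diploid segments
#'   of a copy-number call.
#' @return An object of class `ado_report`: data.frame `by_cutoff`
#'   (`depth_cutoff`, `n_covered`, `n_both_alleles`, `ado_rate`), plus
#'   `n_bulk_het` and the parameters. `ado_rate` is NA at cutoffs with no
#'   covered site.
#' @export
ado_rate <- function(cell, bulk_het, depth_cutoffs = c(1, 5, 10, 20),
                     alt_evidence_min = 1, mask = NULL) {
  cell <- as_allele_table(cell)
  stopifnot(is.data.frame(bulk_het),
            all(c("chrom", "pos") %in% names(bulk_het)))
  if (nrow(bulk_het) == 0) stop("`bulk_het` is empty", call. = FALSE)
  if (!is.null(mask)) {
    keep <- vapply(seq_len(nrow(bulk_het)), function(i) {
      any(mask$chrom == bulk_het$chrom[i] &
            bulk_het$pos[i] - 1 >= mask$start & bulk_het$pos[i] - 1 < mask$end)
    }, logical(1))
    bulk_het <- bulk_het[keep, , drop = FALSE]
    if (nrow(bulk_het) == 0)
      stop("no bulk het site falls inside the mask", call. = FALSE)
  }
  key_bulk <- paste(bulk_het$chrom, bulk_het$pos)
  key_cell <- paste(cell$chrom, cell$pos)
  m <- match(key_bulk, key_cell)
  rd <- ifelse(is.na(m), 0L, cell$ref_depth[m])
  ad <- ifelse(is.na(m), 0L, cell$alt_depth[m])
  depth <- rd + ad
  both <- rd >= alt_evidence_min & ad >= alt_evidence_min

  by_cutoff <- do.call(rbind, lapply(depth_cutoffs, function(cut) {
    cov <- depth >= cut
    n_cov <- sum(cov)
    n_both <- sum(both & cov)
    data.frame(depth_cutoff = cut, n_covered = n_cov,
               n_both_alleles = n_both,
               ado_rate = if (n_cov > 0) 1 - n_both / n_cov else NA_real_)
  }))
  if (all(by_cutoff$n_covered == 0))
    stop(sprintf(paste0("no bulk het site covered at any cutoff ",
                        "(%d bulk sites, max cell depth %d)"),
                 nrow(bulk_het), if (length(depth)) max(depth) else 0L),
         call. = FALSE)
  structure(list(by_cutoff = by_cutoff, n_bulk_het = nrow(bulk_het),
                 alt_evidence_min = alt_evidence_min),
            class = "ado_report")
}

#' @export
print.ado_report <- function(x, ...) {
  cat(sprintf("Allele-dropout report: %d bulk het sites, allele evidence >= %d\n",
              x$n_bulk_het, x$alt_evidence_min))
  print(x$by_cutoff, row.names = FALSE)
  invisible(x)
}

#' Coverage breadth over target sites
#'
#' Fraction of target sites covered to at least each depth cutoff in the
#' cell; sites absent from the cell table count as depth 0. The result is
#' non-increasing along the cutoff ladder.
#'
#' @param cell `allele_table` of the single cell.
#' @param target_sites data.frame of target loci (columns `chrom`, `pos`).
#' @param depth_cutoffs Integer ladder of minimum depths.
#' @return data.frame with `depth_cutoff` and `breadth`.
#' @export
coverage_breadth <- function(cell, target_sites,
                             depth_cutoffs = c(1, 5, 10, 30)) {
  cell <- as_allele_table(cell)
  stopifnot(is.data.frame(target_sites),
            all(c("chrom", "pos") %in% names(target_sites)))
  if (nrow(target_sites) == 0)
    stop("`target_sites` is empty", call. = FALSE)
  m <- match(paste(target_sites$chrom, target_sites$pos),
             paste(cell$chrom, cell$pos))
  depth <- ifelse(is.na(m), 0L, cell$ref_depth[m] + cell$alt_depth[m])
  data.frame(depth_cutoff = depth_cutoffs,
             breadth = vapply(depth_cutoffs,
                              function(cut) mean(depth >= cut), numeric(1)))
}
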