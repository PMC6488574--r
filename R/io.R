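#' Read and write genomic interval files (BED, 0-based half-open)
#'
#' `read_bed()` accepts 3+ column BED; column 4 becomes `name`, column 5
#' `score` (carried as `mapq` by [read_alignments_bed()]). Comment lines
#' starting with `#` are skipped. `write_bed()` writes the reverse.
#'
#' @param path File path.
#' @param df data.frame with at least `chrom`, `start`, `end`.
#' @param extra Names of additional columns to write after the first three.
#' @return `read_bed()` returns a data.frame.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(df, path, extra = setdiff(names(df),
                                                c("chrom", "start", "end"))) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  out <- df[c("chrom", "start", "end", extra)]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read alignment records from 6-column BED
#'
#' Expects chrom, start, end, name, score, strand with the score column
#' carrying the mapping quality; returns the record contract used by
#' [count_reads()] (`chrom`, `start`, `end`, `mapq`).
#'
#' @param path File path.
#' @return data.frame with `chrom`, `start`, `end`, `mapq`.
#' @export
read_alignments_bed <- function(path) {
  df <- read_bed(path)
  if (is.null(df$score))
    stop("alignment BED needs a score column carrying MapQ", call. = FALSE)
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             mapq = as.numeric(df$score), stringsAsFactors = FALSE)
}

#' Read and write per-bin count tables (TSV)
#'
#' Tab-separated with a header line `chrom start end count`; `#` comments
#' allowed.
#'
#' @param path File path.
#' @param counts A `bin_counts` object.
#' @param binset The `bin_set` the counts align to.
#' @return `read_counts_tsv()` returns a list with `binset` (coordinates
#'   only) and `counts` (a `bin_counts`).
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(df)))
  bs <- bin_set(df[c("chrom", "start", "end",
                     intersect(c("mappable", "gc"), names(df)))])
  bc <- structure(list(sample_id = sub("\\.[^.]*$", "", basename(path)),
                       counts = as.integer(df$count),
                       mapped_reads = sum(df$count),
                       total_reads = sum(df$count), n_skipped = 0L),
                  class = "bin_counts")
  list(binset = bs, counts = bc)
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, binset, path) {
  stopifnot(inherits(counts, "bin_counts"), inherits(binset, "bin_set"))
  df <- data.frame(chrom = binset$bins$chrom, start = binset$bins$start,
                   end = binset$bins$end, count = counts$counts,
                   gc = binset$bins$gc, mappable = binset$bins$mappable)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a copy-number profile and its segments to TSV
#'
#' The per-bin table carries chrom, start, end, raw_ratio, scaled_cn and
#' integer_cn; the segment table is SEG-like (chrom, start, end, n_bins,
#' mean, integer_cn).
#'
#' @param profile A `cn_profile`.
#' @param path Per-bin output path.
#' @param seg_path Optional segments output path.
#' @export
write_profile_tsv <- function(profile, path, seg_path = NULL) {
  stopifnot(inherits(profile, "cn_profile"))
  b <- profile$binset$bins
  df <- data.frame(chrom = b$chrom, start = b$start, end = b$end,
                   raw_ratio = profile$raw_ratio,
                   scaled_cn = profile$scaled_cn,
                   integer_cn = profile$integer_cn)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(seg_path)) {
    s <- profile$segments$segments
    write.table(s[c("chrom", "start", "end", "n_bins", "mean", "integer_cn")],
                seg_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write allele-depth tables (TSV)
#'
#' Tab-separated with header `chrom pos ref alt ref_depth alt_depth`
#' (positions 1-based).
#'
#' @param path File path.
#' @param table An `allele_table`.
#' @return `read_allele_tsv()` returns an `allele_table`.
#' @export
read_allele_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  as_allele_table(df)
}

#' @rdname read_allele_tsv
#' @export
write_allele_tsv <- function(table, path) {
  tab <- as_allele_table(table)
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Extract per-allele depths from a VCF
#'
#' Reads a VCF v4.x and returns the allele-depth table for one sample from
#' its AD field (first ALT allele only, biallelic interpretation). This is
#' deliberately a thin extractor: genotype calling itself is upstream of
#' this package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sample Sample name or index (default: first sample).
#' @return An `allele_table`.
#' @export
read_vcf_allele_depths <- function(path, sample = 1L) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || !ncol(ad))
    stop("no AD field found in VCF", call. = FALSE)
  col <- if (is.numeric(sample)) sample else match(sample, colnames(ad))
  if (is.na(col) || col < 1 || col > ncol(ad))
    stop("sample not found in VCF", call. = FALSE)
  parts <- strsplit(ifelse(is.na(ad[, col]), "0,0", ad[, col]), ",",
                    fixed = TRUE)
  rd <- as.integer(vapply(parts, `[`, "", 1L))
  ad1 <- as.integer(vapply(parts, function(p)
    if (length(p) >= 2L) p[2L] else "0", ""))
  fix <- vcfR::getFIX(v)
  allele_table(fix[, "CHROM"], as.numeric(fix[, "POS"]),
               fix[, "REF"], fix[, "ALT"],
               ifelse(is.na(rd), 0L, rd), ifelse(is.na(ad1), 0L, ad1))
}

#' Write run metadata JSON
#'
#' Records the package version, seed, and an md5 hash of the configuration
#' alongside any pipeline output, so runs are traceable.
#'
#' @param path Output path.
#' @param seed Seed used for the run.
#' @param config Arbitrary configuration list (serialized into the file).
#' @param extra Named list of additional fields (e.g. mapping_rate).
#' @export
write_run_metadata <- function(path, seed, config = list(), extra = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  meta <- c(list(package = "scwga",
                 version = as.character(packageVersion("scwga")),
                 seed = seed,
                 config_md5 = unname(tools::md5sum(tmp)),
                 config = config),
            extra)
  unlink(tmp)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
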