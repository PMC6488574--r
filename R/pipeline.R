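#' Run the simulate -> bin -> count -> call -> QC pipeline
#'
#' End-to-end driver over the package's stages for a cohort of simulated
#' cells (or user-supplied count tables): builds the genome and truth,
#' simulates each cell's amplification and sequencing, bins the genome by
#' mappable content, counts reads, calls copy number, applies the QC gate,
#' and (optionally) computes allele-dropout statistics against a simulated
#' unamplified bulk. All outputs are plain TSV/JSON under `outdir`;
#' a run-metadata JSON records the seed and configuration hash. Runs are
#' idempotent given the seed.
#'
#' @param config Nested list. Recognized entries (all optional):
#'   `outdir` (default `NULL`: nothing written), `seed` (default 1),
#'   `n_cells` (default 3), `mode` (`"emda"` or `"tube"`),
#'   `genome` (arguments to [make_genome()]),
#'   `truth` (arguments to [make_truth_profile()]),
#'   `sim` (arguments to [sim_config()]),
#'   `bin` (`target_size`, default 5e4; `mapq_min`, default 15),
#'   `cnv` (arguments to [cnv_call()]),
#'   `qc` (`mad_threshold`, `dropout_threshold`, `mad_mode`),
#'   `snv` (logical; `TRUE` adds a bulk simulation and per-cell ADO),
#'   `counts_files` (character vector of count TSVs to analyse instead of
#'   simulating).
#' @return Invisibly, a list with `cells` (per-cell profiles and QC
#'   reports), `cohort` (summary data.frame), `binset`, `truth`, `genome`.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(seed = 7, n_cells = 2,
#'                          genome = list(n_chrom = 1, chrom_length = 5e6),
#'                          sim = list(n_droplets = 1500, total_reads = 1e5)))
#' res$cohort
#' }
#' @export
run_pipeline <- function(config = list()) {
  seed <- config$seed %||% 1L
  n_cells <- config$n_cells %||% 3L
  mode <- config$mode %||% "emda"
  if (!mode %in% c("emda", "tube"))
    stop("`mode` must be \"emda\" or \"tube\"", call. = FALSE)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  bin_cfg <- config$bin %||% list()
  target_size <- bin_cfg$target_size %||% 5e4
  mapq_min <- bin_cfg$mapq_min %||% 15
  qc_cfg <- config$qc %||% list()

  t0 <- proc.time()[["elapsed"]]
  log_msg <- function(fmt, ...) {
    message(sprintf("[scwga %6.1fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(fmt, ...)))
  }

  from_files <- !is.null(config$counts_files)
  genome <- truth <- NULL
  if (!from_files) {
    genome <- do.call(make_genome,
                      c(config$genome %||% list(),
                        list(seed = seed)[!"seed" %in% names(config$genome)]))
    truth <- do.call(make_truth_profile,
                     c(list(genome = genome), config$truth %||% list(),
                       list(seed = seed + 1L)[!"seed" %in%
                                                names(config$truth)]))
    log_msg("genome: %d windows, truth: %d event(s)",
            nrow(genome$windows), nrow(truth$events))
  }

  cells <- list()
  if (from_files) {
    binset <- NULL
    for (i in seq_along(config$counts_files)) {
      parsed <- read_counts_tsv(config$counts_files[i])
      if (is.null(binset)) binset <- parsed$binset
      cells[[i]] <- list(counts = parsed$counts,
                         sample_id = parsed$counts$sample_id)
    }
    log_msg("loaded %d count table(s)", length(cells))
  } else {
    binset <- build_dynamic_bins(genome, target_size)
    log_msg("dynamic bins: %d at target %g b", nrow(binset$bins), target_size)
    sim_args <- config$sim %||% list()
    if (mode == "tube") sim_args$n_droplets <- 1
    for (i in seq_len(n_cells)) {
      cfg <- do.call(sim_config, c(sim_args[names(sim_args) != "seed"],
                                   list(seed = seed + 100L + i)))
      sim <- simulate_amplification(genome, truth, cfg)
      counts <- count_reads(binset, sim$reads, mapq_min = mapq_min,
                            sample_id = sprintf("cell%02d", i),
                            total_reads = sim$total_reads)
      cells[[i]] <- list(sim = sim, counts = counts,
                         sample_id = counts$sample_id)
      log_msg("cell %d/%d simulated: mapping rate %.3f", i, n_cells,
              sim$mapping_rate)
    }
  }

  cohort <- list()
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    profile <- do.call(cnv_call,
                       c(list(counts = cl$counts, binset = binset),
                         config$cnv %||% list(),
                         list(seed = seed + 200L +
                                i)[!"seed" %in% names(config$cnv)]))
    qc <- qc_report(profile, cl$counts,
                    mad_mode = qc_cfg$mad_mode %||% "mean",
                    mad_threshold = qc_cfg$mad_threshold %||% 1.0,
                    dropout_threshold = qc_cfg$dropout_threshold %||% 0.5)
    det <- if (!is.null(truth) && nrow(truth$events) > 0)
      detection_rate(profile$integer_cn, truth, binset) else NA_real_
    cells[[i]]$profile <- profile
    cells[[i]]$qc <- qc
    cohort[[i]] <- data.frame(sample_id = cl$sample_id,
                              ploidy = profile$ploidy, mad = qc$mad,
                              dropout = qc$dropout, gini = qc$gini,
                              passed = qc$passed, detection_rate = det,
                              mapping_rate = profile$mapping_rate)
    log_msg("cell %s called: ploidy %.2f, MAD %.3f, %s", cl$sample_id,
            profile$ploidy, qc$mad, if (qc$passed) "PASS" else "FAIL")
    if (!is.null(outdir)) {
      base <- file.path(outdir, cl$sample_id)
      write_counts_tsv(cl$counts, binset, paste0(base, ".counts.tsv"))
      write_profile_tsv(profile, paste0(base, ".profile.tsv"),
                        paste0(base, ".segments.tsv"))
    }
  }
  cohort <- do.call(rbind, cohort)

  ado <- NULL
  if (isTRUE(config$snv) && !from_files && nrow(genome$het_sites) > 0) {
    bulk <- simulate_bulk(genome, truth,
                          total_reads = (config$sim$total_reads %||% 5e5),
                          seed = seed + 999L)
    bulk_het <- call_het_sites(bulk$allele_depths, 0.20, 30)
    if (nrow(bulk_het) > 0) {
      ado <- lapply(cells, function(cl)
        ado_rate(cl$sim$allele_depths, bulk_het))
      names(ado) <- vapply(cells, `[[`, "", "sample_id")
      log_msg("ADO computed for %d cell(s) against %d bulk het sites",
              length(ado), nrow(bulk_het))
    }
  }

  if (!is.null(outdir)) {
    write.table(cohort, file.path(outdir, "cohort_qc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(truth))
      write_bed(truth$events, file.path(outdir, "truth.bed"))
    write_run_metadata(file.path(outdir, "run.json"), seed,
                       config = config,
                       extra = list(n_cells = length(cells),
                                    n_pass = sum(cohort$passed)))
    log_msg("outputs written to %s", outdir)
  }

  invisible(list(cells = cells, cohort = cohort, binset = binset,
                 truth = truth, genome = genome, ado = ado))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
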