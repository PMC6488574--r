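#' Droplet and template parameters for an emulsion MDA reaction
#'
#' Bundles the physical quantities that determine template occupancy in a
#' water-in-oil emulsion: droplet diameter, aqueous reaction volume, total
#' genome size of the input cell, and the typical fragment length of its
#' genomic DNA.
#'
#' Defaults describe a single diploid human cell (about 6 pg, ~6 Gb of DNA
#' counting both homologs) fragmented to ~10 kb by routine handling, and the
#' 40-micron droplets produced by centrifugal emulsification.
#'
#' @param droplet_diameter Droplet diameter in micrometers. Must be positive
#'   and below 1000 (sanity bound; emulsion droplets are sub-millimeter).
#' @param reaction_volume Aqueous reaction volume in microliters. Must be
#'   positive and at most 1000.
#' @param genome_size Total input DNA in bases (diploid total for one cell).
#' @param fragment_length Typical double-stranded fragment length in bases.
#' @return An object of class `droplet_params`.
#' @examples
#' p <- droplet_params()
#' fragments_per_droplet(p)
#' @export
droplet_params <- function(droplet_diameter = 40,
                           reaction_volume = 30,
                           genome_size = 6e9,
                           fragment_length = 1e4) {
  stop_if_not_positive(droplet_diameter, "droplet_diameter")
  stop_if_not_positive(reaction_volume, "reaction_volume")
  stop_if_not_positive(genome_size, "genome_size")
  stop_if_not_positive(fragment_length, "fragment_length")
  if (droplet_diameter >= 1000)
    stop("`droplet_diameter` must be below 1000 um", call. = FALSE)
  if (reaction_volume > 1000)
    stop("`reaction_volume` must be at most 1000 uL", call. = FALSE)
  structure(list(droplet_diameter = droplet_diameter,
                 reaction_volume = reaction_volume,
                 genome_size = genome_size,
                 fragment_length = fragment_length),
            class = "droplet_params")
}

#' @export
print.droplet_params <- function(x, ...) {
  cat("Emulsion droplet parameters\n")
  cat(sprintf("  droplet diameter : %g um\n", x$droplet_diameter))
  cat(sprintf("  reaction volume  : %g uL\n", x$reaction_volume))
  cat(sprintf("  genome size      : %g b\n", x$genome_size))
  cat(sprintf("  fragment length  : %g b\n", x$fragment_length))
  invisible(x)
}

#' Volume of a spherical droplet
#'
#' @param diameter Droplet diameter in micrometers.
#' @return Droplet volume in picoliters, \eqn{(\pi/6) d^3} (1 um^3 = 1e-3 pL).
#' @examples
#' droplet_volume(40) # ~33.5 pL
#' @export
droplet_volume <- function(diameter) {
  if (!is.numeric(diameter) || any(!is.finite(diameter)) || any(diameter <= 0))
    stop("`diameter` must be positive", call. = FALSE)
  (pi / 6) * diameter^3 * 1e-3
}

#' Number of droplets produced from a reaction volume
#'
#' Real-valued (not floored): the result feeds occupancy rates, not discrete
#' allocations.
#'
#' @param reaction_volume Aqueous volume in microliters.
#' @param diameter Droplet diameter in micrometers.
#' @return Expected droplet count, `reaction_volume / droplet_volume(diameter)`.
#' @examples
#' droplet_count(30, 40) # ~9e5 droplets
#' @export
droplet_count <- function(reaction_volume, diameter) {
  if (!is.numeric(reaction_volume) || any(!is.finite(reaction_volume)) ||
      any(reaction_volume <= 0))
    stop("`reaction_volume` must be positive", call. = FALSE)
  reaction_volume * 1e6 / droplet_volume(diameter) # 1 uL = 1e6 pL
}

#' Mean template fragments per droplet
#'
#' The Poisson occupancy parameter of the emulsion: total template fragments
#' divided by droplet count. By default fragments are counted on the
#' double-stranded genome (`genome_size / fragment_length`), the convention
#' under which a 6-Gb diploid genome at 10 kb yields the familiar 0.4--0.7
#' fragments per droplet across 30--50 uL of 40-um droplets. MDA denatures
#' templates, so a single-strand counting convention (twice as many
#' templates) is also exposed.
#'
#' @param params A [droplet_params()] object.
#' @param strands `"double"` (default) or `"single"` fragment counting.
#' @return The dimensionless mean occupancy \eqn{\lambda}.
#' @examples
#' fragments_per_droplet(droplet_params(reaction_volume = 30)) # ~0.67
#' fragments_per_droplet(droplet_params(reaction_volume = 50)) # ~0.40
#' @export
fragments_per_droplet <- function(params, strands = c("double", "single")) {
  stopifnot(inherits(params, "droplet_params"))
  strands <- match.arg(strands)
  n_frag <- params$genome_size / params$fragment_length
  if (strands == "single") n_frag <- 2 * n_frag
  n_frag / droplet_count(params$reaction_volume, params$droplet_diameter)
}

#' Poisson occupancy distribution of templates over droplets
#'
#' @param lam Mean templates per droplet (non-negative).
#' @param kmax Largest occupancy count to tabulate explicitly; the remaining
#'   probability is reported as `tail`.
#' @return An object of class `occupancy_distribution` with fields `lam`,
#'   `k` (0..kmax), `pmf`, and `tail` (P(K > kmax)); `sum(pmf) + tail = 1`.
#' @examples
#' occ <- occupancy_distribution(0.7, kmax = 5)
#' occ$pmf[1]                 # P(empty droplet) = exp(-0.7)
#' 1 - occ$pmf[1] - occ$pmf[2] - occ$tail # P(K = 2..5)
#' @export
occupancy_distribution <- function(lam, kmax = 10L) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0)
    stop("`lam` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(kmax) || length(kmax) != 1L || kmax < 1)
    stop("`kmax` must be at least 1", call. = FALSE)
  kmax <- as.integer(kmax)
  k <- 0:kmax
  structure(list(lam = lam, k = k, pmf = dpois(k, lam),
                 tail = ppois(kmax, lam, lower.tail = FALSE)),
            class = "occupancy_distribution")
}

#' @export
print.occupancy_distribution <- function(x, ...) {
  cat(sprintf("Poisson droplet occupancy, lambda = %g\n", x$lam))
  print(data.frame(k = x$k, p = signif(x$pmf, 4)), row.names = FALSE)
  cat(sprintf("  P(K > %d) = %.3g\n", max(x$k), x$tail))
  invisible(x)
}
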