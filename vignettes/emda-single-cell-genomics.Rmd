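---
title: "Models and methods: copy number, allele dropout, and emulsion MDA simulation"
author: "scwga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: copy number, allele dropout, and emulsion MDA simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scwga)
```

# The problem

Single-cell whole-genome sequencing needs whole-genome amplification (WGA)
first: one diploid human cell carries only ~6 pg of DNA. Multiple
displacement amplification (MDA) with phi-29 polymerase covers the genome
well and has low error rates, but in a single tube its random, exponential
initiation makes per-template gain vary by orders of magnitude, which ruins
copy-number inference. Emulsion MDA (eMDA) compartmentalizes the reaction
into ~picoliter droplets: each droplet amplifies its template(s) to local
reagent saturation, so per-template gain is equalized and coverage becomes
far more uniform, at the cost of some reads being wasted on primer-derived
product from empty droplets.

`scwga` implements the computational side of this experiment: the droplet
occupancy arithmetic used to design the emulsion, the copy-number calling
chain for shallow single-cell data (dynamic binning, GC correction,
absolute copy-number determination, circular binary segmentation), the
evenness and coverage quality metrics used to gate cells, the
heterozygosity/allele-dropout analysis for deeper data, and a generative
simulator of the amplification itself so that every stage is testable
without sequencing data.

# Droplet occupancy arithmetic

A droplet of diameter $d$ has volume $(\pi/6)d^3$; a reaction of volume $V$
yields $N = V / [(\pi/6)d^3]$ droplets. A diploid genome of $G$ bases
fragmented to length $L$ gives $G/L$ template fragments, so the mean
occupancy is
$$\lambda = \frac{G/L}{N},$$
and occupancy counts follow a Poisson law. With the defaults ($d$ = 40 µm,
$G$ = 6 Gb, $L$ = 10 kb), 30 µL and 50 µL reactions give $\lambda$ = 0.67
and 0.40 — the design window in which most occupied droplets hold a single
template. Counts are kept real-valued (they feed rates, not allocations),
and fragments are counted on the double-stranded genome by default; a
`strands = "single"` flag doubles the count for the denatured-template
convention. Note that exact arithmetic gives $1.19\times10^6$ droplets for
a 40-µL reaction of 40-µm droplets; quoted figures of $1.3\times10^6$
correspond to a mean diameter nearer 39 µm, well within the dispersion of
real emulsions — we do not force agreement.

```{r}
fragments_per_droplet(droplet_params(reaction_volume = 30))
occupancy_distribution(0.7, kmax = 3)
```

# The amplification simulator

`simulate_amplification()` generates one cell's sequencing run from a
synthetic genome (`make_genome()`) and a ground-truth copy-number profile
(`make_truth_profile()` / `truth_profile()`):

1. **Templates.** Every genomic copy is tiled by fragments of length
   `fragment_length` at a random phase, so each base of each copy lies in
   exactly one fragment and expected fragment counts per window equal
   $c \cdot \mathrm{window}/L$. Tiling (rather than Poisson placement of
   fragment midpoints) is deliberate: it makes allele dropout purely a
   function of fragment loss, with the exact closed form below. Each
   fragment carries the haplotype of its copy (copies alternate A/B, A
   first) and is lost independently with probability `fragment_loss_prob`.
2. **Compartments.** Surviving fragments are assigned uniformly to
   `n_droplets` droplets (`n_droplets = 1` is one-pot tube MDA).
3. **Saturation with competition.** A droplet holding $k$ templates
   produces total mass $Y \cdot \mathrm{LN}(0, \sigma_w)$
   (`saturation_yield`, `within_droplet_cv`), split among its templates
   proportionally to competition weights
   $w_i \sim \mathrm{LN}(0, \sigma_t)$ (`tube_bias_sigma`). A lone
   template therefore receives the droplet's full saturated yield, while
   co-encapsulated templates compete as in a miniature one-pot reaction;
   at `n_droplets = 1` the model reduces exactly to conventional tube MDA
   with log-normal per-template gain. This is what produces the observed
   U-shape of evenness versus droplet number: too few droplets
   re-introduce one-pot competition, too many waste reads (next item).
4. **Empty-droplet background.** Each empty droplet still consumes primers
   and emits `empty_droplet_background` × `saturation_yield` of product
   that cannot be mapped; this is a single pooled mass, not simulated
   sequence. It drives the monotone decline of mapping rate with droplet
   number.
5. **GC bias.** Per-fragment mass is modulated by
   $\exp\{b_1(g-0.5) + b_2(g-0.5)^2\}$ with $g$ the local window GC.
6. **Sequencing.** `total_reads` reads are allocated between fragments and
   the unmappable pool in proportion to mass (mapped + unmapped reads
   always equal `total_reads` exactly). Mapped read starts are uniform
   over an interval widened by one read length around the fragment, which
   makes expected coverage exactly uniform across the fragment — without
   this, fragment edges are systematically undercovered and produce
   spurious allele dropout.

`simulate_bulk()` draws reads multinomially over windows in proportion to
copy number × mappability: library sampling noise only, the unamplified
control.

## Default parameters

| parameter | default | rationale |
|---|---|---|
| `n_droplets` | 9e5 | a 30–40 µL reaction of 40-µm droplets |
| `fragment_length` | 10 kb | routine handling fragments DNA to ~10–20 kb |
| `tube_bias_sigma` | 2 | ~2 orders of magnitude spread of one-pot MDA gain |
| `within_droplet_cv` | 0.2 | droplets saturate at similar, not identical, yield |
| `empty_droplet_background` | 0.5 | places mapping rates near 50–70% at the emulsion optimum |
| `fragment_loss_prob` | 0.11 | ADO = 2p/(1+p) ≈ 0.20 at the design point |
| `gc_bias_coefficients` | (1, −10) | mild amplification preference near mid-GC |

The background yield of empty droplets is not quantified by any
measurement we know of; 0.5 is a one-time choice that reproduces the
qualitative mapping-rate trend, not a fitted constant.

# Copy-number calling

**Dynamic binning.** `build_dynamic_bins()` partitions each chromosome
into bins of (nearly) equal uniquely mappable content — the per-bin quota
is `target_size` × genome-wide mean mappability — so bins widen in poorly
mappable regions instead of losing counts. The final partial bin of a
chromosome is kept if it holds ≥ 50% of the quota, else merged. Reads are
assigned to the bin containing their start coordinate (order-independent;
a midpoint mode exists), gated at MapQ ≥ 15, which operationalizes
"uniquely mapped". Bins with zero uniquely mapped reads are *dropout*
bins; they are excluded from the GC fit, the ploidy residual, the
segmentation input and the MAD, and reported with `NA` copy number.

**GC correction.** `gc_correct()` fits `stats::lowess` of count versus bin
GC (span 0.3) over non-dropout bins and divides by the fit — a
multiplicative bias model — then renormalizes to mean 1. The
pre-correction trend is kept for QC plotting.

**Absolute copy-number determination (ACD).** For each candidate ploidy
$P$ on a grid (default 1.5–6 by 0.05) the residual
$$R(P) = \sum_b \left(P r_b - [P r_b]\right)^2$$
is computed over non-dropout bins, where $[x]$ is the nearest integer; the
minimizing $P$ is the inferred ploidy. Any exact fit is also exact at its
integer multiples, so ties (within 1e-9) break toward the smallest
candidate. A genuinely flat genome is unidentifiable (every integer fits);
identifiability comes from CNV events, and recovery degrades when events
cover only a small fraction of bins — our calibration experiments use
designs whose events cover 25–50% of the genome.

**Segmentation.** `cbs_segment()` is circular binary segmentation: within
each chromosome, find the arc $(i, j]$ maximizing
$$Z_{ij} = \frac{\bar{x}_{\mathrm{arc}} - \bar{x}_{\mathrm{rest}}}
  {s\sqrt{1/k + 1/(n-k)}},$$
accept the split when its permutation p-value (default 1000 permutations,
early-stopped once significance is impossible) is below `alpha` = 0.01,
and recurse. The scan is exhaustive over arcs (O(n²), in C++); an arc and
its complement carry the same statistic and the same breakpoints.
Segments narrower than `min_width` = 3 bins are merged into the
neighbour with the nearest mean (switchable). Per-bin integer copy
numbers inherit the segment mean rounded half away from zero (so a
segment at exactly 2.5 reports 3). Integer copy numbers are assigned at
segment level by default; bin-level rounding is available by rounding
`scaled_cn` directly.

**Detection rate.** `detection_rate()` scores a reference event as
detected when ≥ `min_overlap` (default 0.5; the choice is not dictated by
any measurement) of its bins carry the event's integer copy number.

# Quality metrics

* **Adjacent-bin MAD** (`mad_adjacent()`): the mean — optionally median,
  since the metric is often *named* a median absolute deviation while
  being computed as a mean; we default to the computed definition —
  of $|c_{b+1} - c_b|$ over within-chromosome adjacent non-dropout pairs.
  Chromosome boundaries are excluded, so aneuploidy and large CNVs do not
  inflate it. It is invariant under additive shifts, scales linearly with
  multiplicative ones, and shrinks with coarser bins (sampling noise
  averages out).
* **QC gate** (`qc_gate()`): a cell is valid when MAD ≤ 1 and dropout
  ratio ≤ 0.5, thresholds inclusive.
* **Lorenz curve / Gini** (`lorenz_curve()`): bins sorted by count;
  cumulative bin fraction vs cumulative read fraction; Gini = 1 − 2 × area
  under the curve. Uniform counts give the diagonal and Gini 0; all reads
  in one of $n$ bins give $(n-1)/n$. Computed at bin resolution, not
  per-base depth — it measures the same data model the CNV chain uses;
  whether per-base curves would differ materially is untested here.

# Heterozygosity and allele dropout

`call_het_sites()` applies inclusive minor-allele-frequency and depth
gates to an allele-depth table (TSV or VCF `AD` field via
`read_vcf_allele_depths()`): MAF ≥ 5% and depth ≥ 5 for amplified single
cells, MAF ≥ 20% and depth ≥ 30 for unamplified bulk — the bulk calls are
strictly nested in the single-cell calls.

`ado_rate()` restricts to bulk-established heterozygous sites covered to
at least a depth cutoff in the cell and counts sites where either allele
has fewer than `alt_evidence_min` reads (default 1: any read rescues the
allele; the threshold is exposed because no standard value exists). An
optional interval mask restricts the analysis, e.g. to the diploid
segments of a copy-number call. Under the simulator's loss model, a
diploid site has exactly one fragment per haplotype, so
$$\mathrm{ADO} = \frac{2p(1-p)}{1-p^2} = \frac{2p}{1+p},$$
with $p$ the fragment loss probability — exact in the idealized
saturation regime (`tube_bias_sigma = 0`). With competition switched on,
a co-encapsulated allele can also be *outcompeted*, adding a
depth-dependent amplification component of roughly 0.5–5% on top of the
loss-driven rate; parameter-recovery experiments therefore run in the
idealized regime, where inverting the formula recovers $p$.

# What the simulator does and does not emulate

It emulates: per-bin counts with ground-truth CNV, the one-pot vs
emulsion evenness contrast and its dependence on droplet number, mapping
rate loss from empty droplets, smooth GC bias, bin dropout at low depth,
and haplotype-resolved allele depths with loss-driven ADO.

It does not emulate: read sequences (no FASTQ), polymerase errors and
chimeras, alignment artifacts and mappability-dependent MapQ, duplicate
reads, hybridization-capture bias, or kinetic phi-29 amplification (the
saturation-competition model is a statistical surrogate, not an ODE). A
passing suite therefore shows the *analysis chain* is correct and the
*mechanistic orderings* (evenness, mapping rate, ADO) are reproduced; it
does not validate error rates or capture behavior on real libraries.
Genomes are synthetic and desk-scale — the test suite and acceptance
script use 2–20 Mb genomes, 4×10⁵–10⁶ reads per cell, and 100–200 kb bins
(chosen so events span well over the 3-bin pruning width), versus 3 Gb /
50 kb–1 Mb bins in real use.

# Numerical choices and degenerate inputs

* All randomness flows from explicit per-call seeds through a
  seed-restoring wrapper; identical seeds give byte-identical output.
* Genomic intervals are 0-based half-open everywhere (BED on disk); site
  positions are 1-based (VCF), converted at the file boundary.
* Integer rounding is half-away-from-zero, documented where it matters.
* Zero surviving fragments: all-zero counts with a warning, mapping rate
  0. All-equal series: one segment. Zero-mappability chromosome: no bins,
  with a warning. Fewer than 10 non-dropout bins: GC fit refuses.
* LOWESS fitted values are floored at a small positive value before
  division.

# Limitations

Ploidy grids stop at 8; near-flat genomes make ACD unidentifiable by
construction. The CBS permutation test is scale-free, so very short
spikes (2 bins) in long series are capped near p ≈ 3% and need a more
permissive `alpha` to be called. MAD values depend on bin size, so gates
are meaningful only at a stated resolution. The pipeline assumes one cell
per run directory and plain-text formats; BAM ingestion is out of scope
behind the alignment-record contract.
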