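Package: scwga
Title: Single-Cell Whole-Genome Amplification Analysis for Emulsion MDA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for shallow single-cell whole-genome sequencing
    data produced by multiple displacement amplification (MDA), with emphasis
    on emulsion MDA (eMDA) where the reaction is compartmentalized into
    picoliter droplets. Implements dynamic genome binning by equal uniquely
    mappable content, GC-bias correction by locally weighted regression,
    absolute copy-number determination by residual minimization over a ploidy
    grid, circular binary segmentation with permutation significance testing,
    copy-number detection-rate scoring, amplification-evenness and coverage
    quality metrics (adjacent-bin MAD, dropout ratio, Lorenz curve, Gini
    coefficient), heterozygous-site calling and allele-dropout quantification
    from allele-depth tables, droplet occupancy arithmetic for emulsion
    design, and a generative simulator of compartmentalized versus one-pot
    amplification that produces per-bin read counts, mapping rates, and
    haplotype-resolved allele depths with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
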