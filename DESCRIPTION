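Package: ivhash
Title: Interval-Hash-Augmented Minimizer Seeding for Tandem-Repeat Overlap Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Seeding and all-vs-all overlap detection for long reads from
    highly repetitive tandem arrays such as centromeric alpha-satellite
    higher-order repeats (HORs). Identical minimizers drawn from different
    repeat copies are disambiguated by hashing the local pattern of their
    occurrence intervals ("interval hashing"): the distances between
    consecutive occurrences of the same minimizer are sliced around each
    occurrence, normalised by the local repeat period, quantized, and mixed
    into a 64-bit context hash that is combined with the minimizer value into
    an augmented seed key. The package provides canonical (w,k)-minimizer
    extraction with optional homopolymer compression, interval-hash seed
    augmentation, a simplified colinear chainer emitting PAF records with
    match-rate and overhang filters, seed-level dotplots, and a synthetic
    alpha-satellite HOR simulator (monomer libraries, higher-order units with
    truncations and insertions, haplotype variants, noisy long reads) with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
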