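Package: temposcan
Title: Temporal Population Genomics of Inbred Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-serial population-genomic analysis for panels of
    near-homozygous (inbred) crop varieties genotyped at biallelic SNP
    markers, as in century-scale soybean improvement. Traces fractional
    ancestral contributions by longest-flanking-haplotype matching,
    computes sliding-window nucleotide diversity and log2 diversity
    ratios, builds per-locus temporal allele-frequency series across
    decade cohorts and scores them with frequency-change (delta-f),
    logistic-regression and temporal-Fst statistics, estimates effective
    population size by exact Wright-Fisher likelihood from temporal
    samples, calibrates neutral thresholds and power by forward
    simulation, classifies selective-sweep modes (hard sweep, soft
    sweep, haplotype sneak), and tracks window haplotype spectra
    including the average shared-haplotype-length (H) scan. A
    synthetic-data generator produces ancestor panels, recombinant
    inbred mosaic cohorts with known ancestry, and Wright-Fisher
    trajectories so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    jsonlite
Config/testthat/edition: 3
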