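Package: hsrscan
Title: Windowed Haplotype-Distance Scans for Introgressed Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects introgressed haplotype blocks in admixed individuals by
    scoring phased query haplotypes in genomic windows with the ratio of
    minimum Hamming distances to two divergent reference panels, calls
    high-similarity regions (HSRs) by fold-deviation from the genome-wide
    mean ratio, quantifies their recurrence across haplotypes against a
    binomial random-placement null (M-values), dates tracts with a
    recombination-clock decay simulation, and computes the supporting
    windowed diversity statistics (pi, d_xy, Hudson F_ST), exon density and
    recombination-rate contrasts. Includes a synthetic hybrid-population
    generator (Balding-Nichols panels plus known introgressed blocks) so the
    whole pipeline is testable end to end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    vcfR,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
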