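Package: ltgmap
Title: Bin-Map Construction and QTL Mapping for Low-Temperature
    Germinability in Rice Recombinant Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resequencing-based genetic mapping in selfed
    recombinant inbred line (RIL) populations, motivated by the dissection
    of low-temperature germinability in a japonica rice SN265 x LTH cross.
    Implements sliding-window genotype calling from low-coverage per-site
    parental-origin calls, recombination-breakpoint detection, 15-kb bin-map
    assembly, pairwise genetic-map estimation with the Haldane-Waddington
    RIL correction, Haley-Knott interval and composite-interval QTL scans
    with permutation thresholds and 1.5-LOD support intervals, substitution
    fine mapping from key homozygous recombinants, and candidate-gene
    extraction. A seeded simulator of RIL populations (meiosis by single-seed
    descent, Poisson low-coverage origin calls, additive multi-QTL
    phenotypes) makes the whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
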