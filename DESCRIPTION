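Package: splicemapr
Title: Splicing Regulatory Maps from CLIP Signal and Alternative Splicing Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds position-wise RNA splicing regulatory maps by integrating
    strand-specific CLIP read densities or enriched peak intervals with
    alternative-splicing event tables (rMATS JunctionCountsOnly format).
    Events are filtered, deduplicated by overlap (keeping the highest
    inclusion-junction-count event) and classified against control
    percent-spliced-in values into constitutive and native background sets.
    Signal is vectorized over splice-site-anchored meta-event windows,
    normalized by input subtraction or a relative-information (entropy)
    score, outlier-trimmed, and averaged into per-condition splicing maps
    with position-wise Fisher exact or Kolmogorov-Smirnov tests and
    bootstrap permutation confidence bounds. A synthetic-fixture generator
    produces toy genomes, event tables, Poisson coverage with planted
    positional enrichment, peaks and control-Psi tables for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
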