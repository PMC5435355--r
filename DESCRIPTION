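Package: trnarray
Title: Design, Simulation and Quantification of Radiolabeled tRNA Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling cellular tRNA abundance on spotted
    oligonucleotide microarrays hybridized with metabolically 32P-labeled
    total RNA. Covers the full computational stack: parsing tRNA gene sets
    into a deduplicated species catalog, designing a minimal panel of
    degenerate 70-mer DNA probes against the tRNA 3' end, laying out
    replicated spot grids, simulating phosphorimager exposures with Poisson
    counting noise, quantifying spot signals with local background
    subtraction and percent-of-total normalization, and downstream analytics
    (replicate statistics, size-class fractions, fold change, gene-copy
    views, operon grouping, and wobble-aware codon-usage correlation),
    together with closed-form metabolic-labeling calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
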