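Package: ifnchrom
Title: Chromatin-Context Analysis of the Cell Type-Specific Interferon-Beta Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Downstream analysis of cell type-specific interferon-beta (IFNb)
    responses at the chromatin level. Classifies STAT1/STAT2 ChIP-seq peak sets
    into STAT1-only, STAT2-only and STAT1/2 (ISGF3 proxy) binding sites, links
    STAT1/2 sites to interferon-stimulated genes (ISGs) by single-cell ATAC
    co-accessibility with a shuffled-matrix permutation null, derives
    active/repressed expression thresholds from a two-Gaussian mixture fit,
    assigns each ISG a STAT1/2-dependent regulation mechanism, and clusters
    chromatin features at binding sites into five named chromatin states.
    Ships a synthetic-data generator that emulates the statistical structure of
    the study design so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    cluster,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
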