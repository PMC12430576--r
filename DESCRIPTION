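Package: bulkseg
Title: Bulked Segregant Analysis of Introgression-Line Populations by
    SNP-Index Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci from extreme-phenotype
    DNA bulks sequenced against two inbred parents (BSA-Seq / QTL-seq).
    Implements per-bulk SNP-index and delta(SNP-index) statistics with
    depth-aware simulated confidence envelopes, sliding-window genome scans,
    candidate-region calling, and extraction of nonsynonymous candidate genes
    with hypergeometric term enrichment. Includes a forward simulator of
    backcross chromosome-segment substitution populations (gametes with
    Haldane crossovers, optional marker-assisted segment retention), correlated
    fiber-quality phenotypes, and pooled sequencing readout, so the whole
    pipeline runs end-to-end on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    ggplot2,
    patchwork,
    e1071,
    vcfR,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
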