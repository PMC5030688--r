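Package: taxalink
Title: Linking 16S rRNA OTUs to Metagenomic Species by Cross-Sample
    Co-Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links 16S rRNA operational taxonomic units (OTUs) to
    metagenomic species (MGS) genomes through the correlation of their
    abundance profiles across many metagenomic samples. Provides readers
    for QIIME classic OTU tables and plain TSV count matrices, rarefaction
    by multivariate hypergeometric downsampling, RPKM+TC normalization of
    gene counts, tracer-gene MGS abundance profiling via within-MGS
    co-abundance connectivity, log-ratio profile normalization with
    prevalence filtering, cross-table Pearson correlation with
    best/second-best hit reporting, genus-concordance validation and
    cutoff calibration, and a synthetic community generator with known
    OTU-MGS ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
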