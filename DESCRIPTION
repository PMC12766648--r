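Package: mosaiclineage
Title: Clonal Architecture of Tissues from Somatic Mosaic SNVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping the clonal architecture of a tissue from
    somatic single-nucleotide variants (sSNVs): sensitivity-corrected
    regional sSNV-count ratio estimation with an empirical uniform-mixing
    null, position-weight-matrix likelihood-ratio filtering of
    platform-specific sequencing artifacts, mosaic-fraction estimation and
    detection calls from deep replicate-amplicon data with a simulated
    region-restriction null, binomial posterior genotyping of panel sSNVs
    in amplified single cells, perfect-phylogeny imputation and lineage-tree
    construction with a coalescent model for variant times of origin,
    regional restriction statistics, cell-type variant-sharing statistics
    (minimum mosaic fraction), shared-variant clone detection, and
    empirical-Bayes clone composition estimates. Includes a synthetic
    developmental-lineage simulator that emits bulk whole-genome,
    deep-amplicon, single-cell panel, and single-nucleus UMI readouts so
    the full pipeline can be exercised without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    ape,
    igraph,
    glmmTMB,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
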