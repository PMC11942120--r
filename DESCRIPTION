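Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and ROH Islands from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in diploid genotype matrices
    with a PLINK-style sliding-window scan, summarizes them per individual,
    breed and length class, computes the genomic inbreeding coefficients
    F_ROH and F_HOM, locates ROH islands (population hotspots of
    autozygosity) with gene annotation, and estimates linkage-disequilibrium
    decay and historical effective population size via the Sved relation.
    Ships a planted-tract genotype simulator with exact ground truth so that
    every pipeline stage is testable at desk scale, plus an end-to-end
    pipeline driver with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    BiocGenerics,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
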