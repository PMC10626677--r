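Package: sweepstack
Title: Within-Population Selection-Signature Scans for SNP-Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A single tested pipeline for the four within-population
    selection-signature scans commonly applied to livestock SNP-array data:
    runs-of-homozygosity islands (consecutive-runs ROH with chromosome-wise
    outlier normalisation), the integrated haplotype score (iHS), the
    number-of-segregating-sites-by-length statistic (nSL), and a
    SweepFinder-style composite likelihood ratio (CLR) scan over the site
    frequency spectrum.  Includes genotype quality control (call rates,
    minor allele frequency, exact Hardy-Weinberg test, relatedness pruning
    by method-of-moments identity by descent), linkage-disequilibrium decay
    summaries, multi-method consensus regions, QTL-interval enrichment with
    richness factors and FDR, and a forward Wright-Fisher simulator of
    neutral and hard-sweep datasets so the whole pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    vcfR,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
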