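Package: cnassoc
Title: Co-Occurrence and Outcome Analysis of Somatic Copy-Number Aberrations
Version: 0.1.0
Authors@R:
    person("cnassoc", "developers", email = "cnassoc@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of segmented SNP-array copy-number profiles
    from tumour cohorts: common copy-number-polymorphism derivation from
    normals and exclusion, small-segment merging, thresholded aberration
    calling, tiered frequency/amplitude region discovery on the
    breakpoint-union partition, construction of binary sample-by-region
    aberration matrices, pairwise co-occurrence and mutual-exclusivity
    testing by a signed score test with Benjamini-Hochberg correction and a
    Monte Carlo column-permutation test with average-rank FDR, replication
    filtering across cohorts, copy-number/expression linkage of associated
    regions, genomic-instability indices and Cox proportional-hazards
    survival association.  Includes a synthetic-cohort generator with
    planted region frequencies, latent-factor co-occurrence structure,
    copy-number-coupled expression and amplification-linked hazard, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
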