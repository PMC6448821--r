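Package: tractScan
Title: Gene-Conversion Chimera Detection and Bulk-Segregant Mapping for
    Yeast Gene Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping a Mendelian trait and dissecting the chimeric
    allele that causes it, modelled on the genetics of de novo maltotriose
    utilization in Saccharomyces eubayanus. Implements bulk-segregant
    mapping from pooled allele counts (fixed-difference calling, 1-kb
    candidate-window scans, collapsed-paralog artifact flagging), detection
    of ectopic gene-conversion tracts between paralogs (informative-site
    assignment, run-based breakpoint inference, codon-aware substitution
    accounting), sliding-window sequence identity tracks, tetrad segregation
    analysis for dominant single-locus traits, a serial-passaging division
    budget model, and a seeded synthetic-data generator that produces every
    input with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, SNP, Alignment, Sequencing
RoxygenNote: 7.3.3
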