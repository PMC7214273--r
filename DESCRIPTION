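Package: meth3dlink
Title: DNA Methylation Timecourse Analysis with Long-Range Regulatory Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for CpG methylation dynamics during cellular
    transdifferentiation and their regulatory consequences. Calls
    differentially methylated CpGs from array-style beta-value matrices over
    a timecourse (significance plus beta-change thresholding), scores
    endpoint concordance with control methylomes, partitions CpGs by genomic
    context, links methylation to expression of annotated genes by exact
    permutation correlation, tests transcription-factor category enrichment
    with the hypergeometric distribution, integrates promoter-capture Hi-C
    interaction calls to classify distal CpGs as candidate enhancers or
    silencers of their looped target genes, and quantifies differential
    bait-anchored UMI-4C contact profiles (smoothing, multi-scale
    domainogram, chi-square contact test). Includes a seeded synthetic-study
    generator with planted ground truth so the full pipeline is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
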