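Package: methbin
Title: Promoter Methylome Binning Analysis of Methylated and Unmethylated CpG Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates bisulfite methylome read counts with gene expression to
    quantify how the numbers of methylated (CMepG) and unmethylated (CUn-MepG)
    promoter CpGs relate to transcription. Derives 1 kb upstream promoters,
    collapses strand-level bisulfite observations into per-site methylation
    levels with extrapolation over unsequenced CpGs, classifies promoters as
    CpG-island (CGI) or non-CGI by overlap fraction, forms equal-count or
    fixed-span bins, and tests bin trends with Spearman correlation on bin
    medians (exact permutation p-values) and median-split subgroups with
    one-sided Mann-Whitney tests (exact by enumeration for small groups).
    Includes a seeded synthetic methylome generator implementing a combined
    activator/repressor expression model for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    methods,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
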