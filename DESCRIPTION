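Package: eploopr
Title: Enhancer-Promoter Loop Annotation from Chromatin Marks and Hi-C Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates chromatin loops as enhancer-promoter (EP) interactions
    by integrating ATAC-seq accessibility with H3K4me3 and H3K27ac histone-mark
    peaks. Accessible regions carrying all three signals are classified as
    promoters and regions carrying ATAC-seq and H3K27ac but lacking H3K4me3 as
    enhancers; loops whose anchors connect an enhancer to a promoter are called
    EP-loops and summarized per chromosome. Also provides the upstream
    bridge-linker splitting of chimeric Hi-C reads, the CRISPRi sgRNA selection
    rule (efficiency and MM0-MM3 off-target ranking within a TSS window), the
    2^-ddCt relative-expression and pairwise Bonferroni formulas, thresholded
    stain quantification for hemoglobin imaging, and a seeded synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    png,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
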