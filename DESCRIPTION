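Package: meiomap
Title: Sex-Specific Crossover Detection from Parent-Offspring Quartet
    Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects meiotic crossovers from whole-genome genotypes of
    parent-offspring quartets (father, mother, son, daughter) by Mendelian
    transmission phasing and changepoint segmentation of sibling
    allele-sharing tracks, with quality and gene-conversion filters.
    Computes sex-specific recombination maps and heterochiasmy statistics,
    models telomere and centromere effects on crossover placement with
    linear mixed models compared by AIC, runs permutation tests for
    recombination hotspots and gene-feature overlap, analyses GC content
    of crossover intervals, and relates recombination to interspecific
    differentiation (scaled FST) along chromosomes. Includes a meiosis
    simulator that generates quartet genotypes with known crossover ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    lme4,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
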