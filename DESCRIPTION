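Package: areqtl
Title: Active Regulatory Element QTL Mapping, Tissue Sharing,
    Colocalization and Genetic Gene Linking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the genetic regulation of active
    regulatory elements (AREs) profiled by H3K27ac ChIP-seq across
    multiple tissues. Implements fragment-based ARE activity
    quantification with median-of-ratios normalization, Jaccard
    k-centroids classification of AREs into coactivity modules and
    named groups, cis histone-acetylation QTL (haQTL) mapping with
    permutation-based empirical p-values via a fitted Beta
    distribution, a directionality-consistency estimator of
    cross-tissue sharing of genetic effects, approximate-Bayes-factor
    colocalization of QTL and GWAS signals, and six genetic ARE-gene
    linking (gLink) scores with a unified rank aggregate. A synthetic
    multitissue cohort generator with planted genetic effects supports
    end-to-end testing without access to protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
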