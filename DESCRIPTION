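Package: rdmeth
Title: Integrative Relative-Difference Analysis of DNA Methylation and
    Gene Expression in Matched Tumor/Normal Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates Illumina HM450K DNA methylation with RNA-seq counts
    in matched tumor and adjacent-normal (paracancerous) samples. Implements
    median-of-log-ratios count normalization, negative-binomial differential
    expression with Benjamini-Hochberg correction, the relative-difference
    (RD) methylation statistic at probe, gene-promoter and genomic-bin
    resolution (30 x 100 bp promoter bins around the TSS, 10 bins for other
    functional regions), nearest-TSS enhancer target assignment, and a
    differentially-methylated-enhancer (DME) model that calls
    enhancer/target-gene pairs by Spearman anti-correlation of per-patient
    enhancer methylation change and expression fold change. Candidate key
    genes are selected by intersecting expression/methylation classes with
    oncogene and tumor-suppressor sets and requiring abnormal methylation in
    the TSS +/- 200 bp key bins. A seeded synthetic-study generator with
    planted ground truth supports calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
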