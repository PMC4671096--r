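Package: vcbench
Title: Genotype-Aware Benchmarking of Variant Calling Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks variant callsets (VCF) against a gold-standard
    diploid truth set inside high-confidence and exome-capture regions
    (BED). Callsets are regularized to allelic primitives by pairwise
    alignment, restricted to the evaluation territory, and classified
    genotype-aware into true positives, false positives, false negatives
    and genotyping errors; SNP genotyping errors are further typed as
    ignoring-the-reference-allele (IR), adding-the-reference-allele (AR)
    or other. Performance is summarized by QUAL-ranked precision-recall
    curves and the area under the precision-recall curve (APR), caller
    bias by IR/AR probabilities, and multi-caller agreement by Venn
    concordance of quality-filtered calls. A seeded simulator generates
    diploid truth sets and degraded query callsets with controlled error
    structure for fully reproducible evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
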