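Package: pdxfid
Title: Genomic and Transcriptomic Fidelity Assessment for Patient-Derived Xenografts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how faithfully patient-derived xenografts (PDXs)
    preserve the genome and transcriptome of the originating tumor. Implements
    k-mer based graft/host/both/neither/ambiguous read classification and host
    read removal, somatic variant filter chains (reporting, concordance
    eligibility, purity eligibility with a flanking-window uniqueness check),
    recall/precision and allele-frequency concordance metrics, an exome
    coverage-pattern CNV workflow (reference coverage model, GC correction,
    log2 ratios, circular binary segmentation, amplification/deletion calls),
    a multi-timepoint binomial-mixture subclone and purity model, splice-read
    isoform quantification (splice reads per million), RPKM expression with
    correlation and fold-change differential expression, and a synthetic
    paired patient/PDX cohort generator with full ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
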