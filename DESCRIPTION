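Package: editome
Title: Detection, Quantification and Differential Analysis of A-to-I RNA
    Editing from Matched DNA and RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for characterising an A-to-I RNA editome
    from matched DNA-seq and stranded RNA-seq alignments. Calls normal
    editing sites from quality- and end-trimmed base pileups with a
    DNA-derived SNP mask, recovers hyper-edited sites from unalignable
    reads via A-to-G transformed realignment, quantifies per-site and
    overall editing levels, per-Mb site density and the repeat editing
    index, annotates sites by genomic feature and codon consequence, and
    tests per-site differential editing between conditions with a
    binomial logistic-regression likelihood-ratio test under
    Benjamini-Hochberg FDR control. Includes a fully deterministic
    synthetic-editome simulator with planted truth so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
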