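Package: cpgmpra
Title: Design and Analysis of CpG-Density Promoter Reporter Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the contribution of CpG dinucleotide
    density to mammalian promoter activity with barcoded parallel reporter
    assays. Covers normalized CpG density (observed/expected) statistics and
    CpG-island classification; generation of promoter mutant libraries
    (window combinations, CpG density series, transcription-factor motif
    mutations, tiling replacements, and CpG add-back designs) with
    pattern-based barcodes; assignment of read pairs to reference constructs
    by mismatch distance with an ambiguity margin and barcode purity
    filtering; quantification of per-promoter transcriptional activity from
    DNA/RNA barcode counts with a pseudocount model; permutation tests for
    Spearman correlations; CpG-density-aware transcription-factor binding
    prediction with precision-recall curves; bisulfite methylation
    summarization; and seeded synthetic-data generators with known ground
    truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
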