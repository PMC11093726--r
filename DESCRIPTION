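Package: isocurate
Title: Classification, Quality Control and Curation of Long-Read Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to curate transcriptomes built from long-read RNA
    sequencing. Query transcript models are classified against a reference
    annotation into structural categories and subcategories based on splice
    junction chain matching; transcript- and junction-level quality attributes
    are computed from the genome sequence, CAGE-like and polyA peak regions,
    polyadenylation motifs, short-read coverage and short-read splice junction
    counts. Likely artifacts are removed either with user-defined JSON rules
    or with a random-forest classifier, discarded signal is rescued back into
    the transcriptome from the reference annotation, and curation performance
    can be scored against spike-in style ground truth. A deterministic
    synthetic fixture generator makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
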