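Package: immunedit
Title: Immunoediting Analysis and Discovery of Non-Canonical MHC-I
    Associated Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A proteogenomic pipeline for detecting cancer immunoediting in
    mismatch-repair-deficient versus proficient tumour cells. Computes
    per-genomic-region tumour mutational burden and immune-editing
    log-ratios from filtered somatic variants; builds genotype-specific
    databases of 8-11-mer peptides by six-frame translation and k-mer
    counting of RNA-seq reads with differential loss/counter-selection
    formulas; maps observed MHC class I associated peptides back to
    genomic loci through their source reads; annotates genomic region,
    reading-frame and mutation status; and ranks candidate immunogenic
    peptides. Includes a synthetic-data generator with planted truth so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
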