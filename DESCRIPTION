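Package: foramsig
Title: Signature-Based Classification of Foraminiferal rDNA Metabarcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Taxonomy-free classification of 18S rRNA metabarcodes from
    benthic foraminifera. Screens amplicons for foraminifera-specific
    conserved motifs flanking the 37F hypervariable region, discovers
    ultra-short diagnostic nucleotide signatures (12-53 nt) that define
    novel lineages among taxonomically unassigned OTUs, classifies
    datasets by exact (zero-mismatch) signature matching, and summarizes
    lineage biogeography across sampling areas and habitats. Includes a
    synthetic amplicon community simulator with planted ground truth so
    every pipeline stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
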