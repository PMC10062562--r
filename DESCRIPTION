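Package: srnapipe
Title: Small RNA Classification, Factor Dependency and Terminal Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing collapsed small-RNA sequencing libraries from
    knockdown panels. Reads are assigned to an ordered reference hierarchy
    (miRNA, RNA polymerase III transcripts, rRNA, snoRNA/mRNA, repeats, genome
    background) by exact matching on both strands, normalised to reads per
    million genome-mapping reads, and profiled per locus by strand, 5' position,
    length and 5' nucleotide. Downstream modules call biogenesis-factor
    dependencies from knockdown/control fold changes, test for the piRNA
    ping-pong amplification signature via 5'-5' overlap Z-scores, infer 3'
    (2'-O-methyl vs 2',3'-OH) and 5' (mono- vs poly-phosphate) terminal states
    from periodate-oxidised and terminator-treated libraries, and classify
    mRNAs by polyA status against a spliceosomal-RNA regression baseline. A
    synthetic-library generator with planted ground truth provides an oracle
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
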