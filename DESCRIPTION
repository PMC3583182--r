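Package: wrkyminer
Title: Genome Mining, Curation and Phylogenetics for the WRKY Transcription Factor Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Splice-aware discovery of WRKY-domain-encoding loci in genome
    assemblies, subfamily classification from zinc-finger structure and the
    conserved domain-splitting intron, auditing of GFF3 gene models against
    domain evidence, pseudogene flagging, tandem-array detection, and
    distance-based phylogenetics (neighbor-joining on Poisson-corrected
    pairwise-deletion distances with bootstrap supports). Ships a curated
    86-member Brachypodium distachyon WRKY family table and a synthetic
    genome generator with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
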