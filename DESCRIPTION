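Package: glutannot
Title: Structural and Evolutionary Annotation of HMW Glutenin Subunit Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural and evolutionary characterization of
    high molecular weight glutenin subunit (HMW-GS) genes of wheat and its
    wild relatives: ORF translation with trailing-stop accounting, signal
    peptide removal and x/y subunit typing, partitioning of mature subunits
    into N-terminal, repetitive and C-terminal domains, cysteine census,
    dynamic-programming decomposition of the repetitive domain into
    tripeptide/hexapeptide/nonapeptide motifs, detection of large inserted
    blocks relative to a reference subunit with tandem-duplication
    verification, annotation of Glu-1 promoter cis-regulatory elements,
    neighbor-joining trees with bootstrap support, and median-joining
    haplotype networks. Includes a seeded synthetic-data generator that
    emits HMW-GS-like genes, promoters and sequence families with known
    ground truth so every pipeline stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
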