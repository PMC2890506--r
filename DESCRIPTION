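Package: PolyPrime
Title: Genome-Specific PCR Primer Design for Homoeologous Genes in
    Allopolyploids
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Designs genome-specific PCR primer sets that discriminate
    homoeologous gene copies in allopolyploid species such as bread wheat.
    Discovers subgenome-diagnostic SNP and indel sites in a multiple
    alignment of homoeologs, anchors primer 3' termini on those sites,
    adjusts primers into a melting-temperature window by editing the 5'
    terminus under a nearest-neighbor thermodynamic model, validates
    specificity with a mismatch-position-aware in-silico PCR model, tiles
    a gene with overlapping amplicons while reporting union coverage, and
    genotypes deletion-based null alleles from presence/absence patterns
    of diagnostic primer sets. Includes a seeded simulator of homoeologous
    gene families with exon/intron-specific divergence for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, Software
RoxygenNote: 7.3.3
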