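# Shared fixtures. The full default-size design run is computed once per
# test session and reused by the tests that need it.

.fixtureCache <- new.env(parent = emptyenv())

defaultFamily <- function() {
  if (is.null(.fixtureCache$family))
    .fixtureCache$family <- simulateFamily(simulationParams(seed = 2024))
  .fixtureCache$family
}

defaultDesign <- function() {
  if (is.null(.fixtureCache$design)) {
    fam <- defaultFamily()
    .fixtureCache$design <- designPrimers(
      fam$copies, precomputedAlignment = fam$trueAlignment)
  }
  .fixtureCache$design
}

smallFamily <- function(seed = 7L) {
  simulateFamily(simulationParams(seed = seed, n_exons = 4L,
                                  exon_length_range = c(80L, 120L),
                                  intron_length_range = c(80L, 120L)))
}

# a toy alignment of ungapped equal-length rows; no exons annotated, so
# every column is INTRON for every genome
toyAlignment <- function(rows) {
  copies <- lapply(names(rows), function(g)
    geneCopy(g, gsub("-", "", rows[[g]], fixed = TRUE)))
  names(copies) <- names(rows)
  buildAlignment(copies, precomputed = rows)
}

# a synthetic specific-pair table with the columns the tiling optimizer
# expects, for tests that exercise tiling in isolation
fakePairs <- function(starts, ends, margin = NULL, genome = "A") {
  n <- length(starts)
  if (n == 0L) return(PolyPrime:::.emptyPairs())
  if (is.null(margin)) margin <- rep(2L, n)
  data.frame(genome = genome, fwd_seq = strrep("A", 18),
             rev_seq = strrep("T", 18),
             fwd_start = starts, fwd_end = starts + 17L,
             rev_start = ends - 17L, rev_end = ends,
             fwd_anchor_pos = starts + 17L, rev_anchor_pos = ends - 17L,
             fwd_tm_C = 60, rev_tm_C = 60,
             fwd_region = "INTRON", rev_region = "INTRON",
             amplicon_start = as.integer(starts),
             amplicon_end = as.integer(ends),
             size_bp = as.integer(ends - starts + 1L),
             size_penalty = 0L, margin = as.integer(margin),
             stringsAsFactors = FALSE)
}

printedPrimerPanel <- function() {
  readPrimerTable(system.file("extdata", "wheat_wx_ssii_primers.tsv",
                              package = "PolyPrime"))
}

printedGenotypeTable <- function() {
  utils::read.delim(system.file("extdata", "wheat_waxy_genotypes.tsv",
                                package = "PolyPrime"),
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

waxyPanelForClassification <- function() {
  diagnosticPanel(data.frame(
    locus = c("Wx-A1", "Wx-B1", "Wx-D1"),
    fwd_name = c("Wx-7A-F1", "Wx-4A-F2", "Wx-7D-F3"),
    fwd_seq = c("GTAAGCTTGCGCCACTGC", "TCAACAACACCCAGCAGCTA",
                "CCAGATCGTTCTCCTGGTACA"),
    rev_name = c("Wx-7A-R1a", "Wx-4A-R2", "Wx-7D-R3a"),
    rev_seq = c("GGATGCAGAATGCCACCTA", "GGTTGGGGTCGATGACGTA",
                "CTCGCTCCCCTCGACA"),
    stringsAsFactors = FALSE))
}
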