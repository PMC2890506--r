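#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom IRanges IRanges start end width
NULL

#' GeneCopy: one genome's copy of a homoeologous gene
#'
#' Container for a single gene copy: the genomic sequence of one subgenome
#' (e.g. the 7A, 4A or 7D copy of the wheat waxy gene) together with its
#' exon structure. Introns are implied by the gaps between consecutive
#' exons.
#'
#' @slot genomeId single character label for the subgenome (e.g. "7A").
#' @slot sequence a [Biostrings::DNAString] over A,C,G,T,N (uppercase).
#' @slot exons an [IRanges::IRanges] of exon intervals, 1-based closed,
#'   sorted, non-overlapping, within the sequence.
#' @slot sourceId free-text provenance (e.g. a GenBank accession).
#'
#' @seealso [geneCopy()], [introns()], [readGeneFamily()]
#' @exportClass GeneCopy
setClass("GeneCopy",
  representation(
    genomeId = "character",
    sequence = "DNAString",
    exons = "IRanges",
    sourceId = "character"
  )
)

setValidity("GeneCopy", function(object) {
  msg <- character()
  if (length(object@genomeId) != 1L || is.na(object@genomeId) ||
      !nzchar(object@genomeId))
    msg <- c(msg, "'genomeId' must be a single non-empty string")
  if (length(object@sequence) == 0L && length(object@exons) > 0L)
    msg <- c(msg, paste("an empty sequence (whole-gene-deletion sentinel)",
                        "cannot carry exon annotation"))
  bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1L]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("sequence contains letters outside {A,C,G,T,N}: ",
                         paste(bad, collapse = ",")))
  ex <- object@exons
  if (length(ex)) {
    if (any(IRanges::start(ex) < 1L) ||
        any(IRanges::end(ex) > length(object@sequence)))
      msg <- c(msg, "exon intervals must lie within the sequence")
    if (is.unsorted(IRanges::start(ex)))
      msg <- c(msg, "exons must be sorted by start")
    if (length(ex) > 1L &&
        any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping and separated by introns")
  }
  if (length(msg)) msg else TRUE
})

#' HomoeologAlignment: gapped multiple alignment of homoeologous copies
#'
#' A multiple alignment of two or more [GeneCopy] objects together with
#' per-genome coordinate maps between ungapped sequence positions and
#' alignment columns, and a per-genome, per-column region label
#' (EXON / INTRON / JUNCTION). JUNCTION marks columns within a fixed
#' window of an exon/intron boundary.
#'
#' @slot copies named list of [GeneCopy] objects.
#' @slot rows character vector of gapped rows (over A,C,G,T,N,-), one per
#'   copy, all the same width; degapping a row reproduces the copy's
#'   sequence exactly.
#' @slot columnRegion character matrix (genomes x columns) with values in
#'   EXON, INTRON, JUNCTION.
#' @slot colToPos list of integer vectors: per genome, alignment column ->
#'   ungapped 1-based position (NA at gap columns).
#' @slot posToCol list of integer vectors: per genome, ungapped position ->
#'   alignment column.
#' @slot junctionWindow integer: half-width (in columns) of the JUNCTION
#'   label around each exon/intron boundary.
#'
#' @seealso [buildAlignment()], [findDiscriminativeSites()]
#' @exportClass HomoeologAlignment
setClass("HomoeologAlignment",
  representation(
    copies = "list",
    rows = "character",
    columnRegion = "matrix",
    colToPos = "list",
    posToCol = "list",
    junctionWindow = "integer"
  )
)

setValidity("HomoeologAlignment", function(object) {
  msg <- character()
  n <- length(object@copies)
  if (n < 2L) msg <- c(msg, "an alignment needs at least 2 copies")
  if (length(object@rows) != n)
    msg <- c(msg, "one gapped row per copy is required")
  if (length(unique(nchar(object@rows))) > 1L)
    msg <- c(msg, "all rows must have equal width")
  ids <- vapply(object@copies, function(x) x@genomeId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "genome ids must be unique")
  for (i in seq_len(n)) {
    degapped <- gsub("-", "", object@rows[[i]], fixed = TRUE)
    if (!identical(degapped, as.character(object@copies[[i]]@sequence))) {
      msg <- c(msg, sprintf(
        "degapped row %d does not reproduce the sequence of copy '%s'",
        i, ids[i]))
    }
  }
  if (!is.null(dim(object@columnRegion)) && length(object@rows) &&
      !identical(dim(object@columnRegion),
                 c(length(object@rows), nchar(object@rows[1L]))))
    msg <- c(msg, "columnRegion must be genomes x columns")
  if (length(msg)) msg else TRUE
})

#' TilingSolution: selected primer pairs tiling one gene copy
#'
#' The per-genome result of the tiling optimizer: an ordered set of
#' genome-specific primer pairs whose predicted amplicons cover the gene,
#' with union-coverage accounting and the overlap between neighboring
#' amplicons.
#'
#' @slot genomeId subgenome label.
#' @slot pairs data.frame of chosen pairs (one row per pair: primer
#'   sequences, template coordinates, amplicon start/end/size, class,
#'   specificity margin), sorted by amplicon start.
#' @slot coveredBp integer: size of the union of the chosen amplicon
#'   intervals.
#' @slot geneLength integer: full genomic length of the gene copy.
#' @slot junctionOverlaps integer vector: overlap (bp) between each pair of
#'   neighboring amplicons (negative = gap between them).
#'
#' @seealso [tileGene()], [coverageReport()]
#' @exportClass TilingSolution
setClass("TilingSolution",
  representation(
    genomeId = "character",
    pairs = "data.frame",
    coveredBp = "integer",
    geneLength = "integer",
    junctionOverlaps = "integer"
  )
)

setValidity("TilingSolution", function(object) {
  msg <- character()
  if (object@geneLength <= 0L) msg <- c(msg, "geneLength must be positive")
  if (object@coveredBp < 0L || object@coveredBp > object@geneLength)
    msg <- c(msg, "coveredBp must be in [0, geneLength]")
  if (nrow(object@pairs) > 1L &&
      is.unsorted(object@pairs$amplicon_start))
    msg <- c(msg, "pairs must be sorted by amplicon start")
  if (length(msg)) msg else TRUE
})

#' DiagnosticPanel: presence/absence genotyping panel
#'
#' A set of diagnostic genome-specific primer pairs (one per locus) plus
#' the mapping from a presence/absence pattern across loci to a genotype
#' label and numeric type code (wild type, single / double / triple null).
#'
#' @slot entries data.frame with one row per locus: columns `locus`,
#'   `fwd_name`, `fwd_seq`, `rev_name`, `rev_seq`, `expected_size_bp`
#'   (NA allowed).
#' @slot codeMap data.frame with columns `pattern` (string of "+"/"-",
#'   one character per locus, in entry order), `label`, `code` (integer),
#'   `inferred` (logical: TRUE for codes never printed in the source
#'   classification and filled in by analogy).
#'
#' @seealso [diagnosticPanel()], [classifyGenotype()], [typeAlleles()]
#' @exportClass DiagnosticPanel
setClass("DiagnosticPanel",
  representation(entries = "data.frame", codeMap = "data.frame")
)

setValidity("DiagnosticPanel", function(object) {
  msg <- character()
  need <- c("locus", "fwd_name", "fwd_seq", "rev_name", "rev_seq")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, paste("entries must have columns:",
                        paste(need, collapse = ", ")))
  if (anyDuplicated(object@entries$locus))
    msg <- c(msg, "one entry per locus is required")
  k <- nrow(object@entries)
  if (nrow(object@codeMap) &&
      any(nchar(object@codeMap$pattern) != k))
    msg <- c(msg, "codeMap patterns must have one character per locus")
  if (length(msg)) msg else TRUE
})
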