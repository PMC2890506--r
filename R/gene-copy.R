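#' Construct a GeneCopy
#'
#' @param genomeId subgenome label, e.g. `"7A"`.
#' @param sequence genomic sequence: a character string or
#'   [Biostrings::DNAString]. Lowercase is uppercased and `U` is mapped
#'   to `T`.
#' @param exons exon intervals: an [IRanges::IRanges] or a two-column
#'   matrix/data.frame of 1-based closed `start`,`end`.
#' @param sourceId free-text provenance, e.g. a GenBank accession.
#'
#' @return A [GeneCopy-class] object.
#' @examples
#' gc <- geneCopy("7A", "ATGAAATTTGGGCCCTAG",
#'                exons = cbind(c(1, 13), c(6, 18)))
#' introns(gc)
#' @export
geneCopy <- function(genomeId, sequence, exons = IRanges::IRanges(),
                     sourceId = NA_character_) {
  seq <- toupper(as.character(sequence))
  seq <- chartr("U", "T", seq)
  if (!inherits(exons, "IRanges")) {
    ex <- as.matrix(exons)
    exons <- if (nrow(ex)) {
      IRanges::IRanges(start = as.integer(ex[, 1L]),
                       end = as.integer(ex[, 2L]))
    } else IRanges::IRanges()
  }
  methods::new("GeneCopy", genomeId = as.character(genomeId),
               sequence = Biostrings::DNAString(seq),
               exons = exons, sourceId = as.character(sourceId))
}

#' @rdname geneCopy
#' @param x a `GeneCopy`.
#' @export
setMethod("genomeId", "GeneCopy", function(x) x@genomeId)

#' @rdname geneCopy
#' @export
setMethod("sourceId", "GeneCopy", function(x) x@sourceId)

#' @rdname geneCopy
#' @export
setMethod("exons", "GeneCopy", function(x) x@exons)

#' @rdname geneCopy
#' @export
setMethod("geneLength", "GeneCopy", function(x) length(x@sequence))

#' Intron intervals of a gene copy
#'
#' Introns are the gaps between consecutive exons; leading/trailing
#' unannotated sequence (UTR flanks) is not counted as intron.
#'
#' @rdname geneCopy
#' @export
setMethod("introns", "GeneCopy", function(x) {
  ex <- x@exons
  if (length(ex) < 2L) return(IRanges::IRanges())
  s <- IRanges::end(ex)[-length(ex)] + 1L
  e <- IRanges::start(ex)[-1L] - 1L
  keep <- e >= s
  IRanges::IRanges(start = s[keep], end = e[keep])
})

setMethod("show", "GeneCopy", function(object) {
  cat(sprintf("GeneCopy '%s' (%s): %d bp, %d exons / %d introns\n",
              object@genomeId,
              ifelse(is.na(object@sourceId), "unknown source",
                     object@sourceId),
              length(object@sequence), length(object@exons),
              length(introns(object))))
})

#' Region label for each position of a gene copy
#'
#' @param copy a [GeneCopy-class].
#' @return character vector of length `geneLength(copy)` with values
#'   `"EXON"` or `"INTRON"` (positions outside any exon, including
#'   unannotated flanks, are labelled INTRON).
#' @keywords internal
.positionRegions <- function(copy) {
  lab <- rep("INTRON", geneLength(copy))
  ex <- exons(copy)
  for (i in seq_along(ex)) {
    lab[IRanges::start(ex)[i]:IRanges::end(ex)[i]] <- "EXON"
  }
  lab
}

#' Read a homoeologous gene family from FASTA + GFF3
#'
#' Loads one [GeneCopy-class] per FASTA record, taking exon structure from
#' GFF3 `exon` features whose `seqid` matches the FASTA record ID. Both
#' files may be gzip-compressed. Sequences are uppercased and `U` mapped
#' to `T`. The genome label of each copy is taken from the GFF3 exon
#' features' `Parent` (or `ID`) attribute when present, else from the
#' FASTA record ID.
#'
#' @param fastaPath path to a (optionally gzipped) FASTA of genomic
#'   sequences, one record per genome copy.
#' @param gff3Path path to a GFF3 with `exon` features for every record.
#' @return named list of [GeneCopy-class] objects (names = genome ids).
#' @examples
#' fam <- simulateFamily(simulationParams(seed = 1))
#' dir <- tempfile(); dir.create(dir)
#' writeGeneFamily(fam$copies, dir)
#' copies <- readGeneFamily(file.path(dir, "family.fasta"),
#'                          file.path(dir, "family.gff3"))
#' @export
readGeneFamily <- function(fastaPath, gff3Path) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff3Path, format = "gff3")
  gff <- gff[tolower(as.character(gff$type)) == "exon"]
  if (length(gff) == 0L)
    stop("no exon features found in ", gff3Path)
  bySeq <- split(gff, as.character(GenomicRanges::seqnames(gff)))
  copies <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    if (!id %in% names(bySeq))
      stop("no exon annotation for FASTA record '", id, "'")
    feats <- bySeq[[id]]
    ex <- IRanges::ranges(feats)
    ex <- ex[order(IRanges::start(ex), IRanges::end(ex))]
    if (length(ex) > 1L &&
        any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      stop("overlapping exons annotated for record '", id, "'")
    if (any(IRanges::end(ex) > length(seqs[[i]])))
      stop("exon beyond sequence end for record '", id, "'")
    gid <- id
    par <- feats$Parent
    if (!is.null(par) && length(par)) {
      pv <- unique(unlist(par))
      if (length(pv) == 1L && nzchar(pv)) gid <- pv
    }
    copies[[gid]] <- geneCopy(gid, seqs[[i]], ex, sourceId = id)
  }
  copies
}

#' Write a gene family as FASTA + GFF3
#'
#' Inverse of [readGeneFamily()]: writes `family.fasta` and `family.gff3`
#' into `dir`. Byte-stable for a fixed input, so simulator output is
#' reproducible on disk.
#'
#' @param copies named list of [GeneCopy-class].
#' @param dir output directory (created if missing).
#' @param stem file stem, default `"family"`.
#' @return invisibly, the two file paths.
#' @export
writeGeneFamily <- function(copies, dir, stem = "family") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(stem, ".fasta"))
  gff <- file.path(dir, paste0(stem, ".gff3"))
  seqs <- Biostrings::DNAStringSet(vapply(
    copies, function(x) as.character(x@sequence), character(1)))
  names(seqs) <- vapply(copies, genomeId, character(1))
  Biostrings::writeXStringSet(seqs, fa, width = 70L)
  lines <- c("##gff-version 3")
  for (cp in copies) {
    ex <- exons(cp)
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              genomeId(cp), geneLength(cp)))
    for (i in seq_along(ex)) {
      lines <- c(lines, paste(
        genomeId(cp), "PolyPrime", "exon",
        IRanges::start(ex)[i], IRanges::end(ex)[i],
        ".", "+", ".",
        sprintf("ID=%s.exon%02d;Parent=%s", genomeId(cp), i, genomeId(cp)),
        sep = "\t"))
    }
  }
  writeLines(lines, gff)
  invisible(c(fasta = fa, gff3 = gff))
}
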