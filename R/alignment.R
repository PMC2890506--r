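#' Build (or ingest) a multiple alignment of homoeologous copies
#'
#' Either computes a progressive star alignment internally — every copy is
#' globally aligned to the first copy with affine gap penalties
#' (match +1, mismatch -1, gap open 5, gap extend 1, via
#' [Biostrings::pairwiseAlignment]) and the pairwise alignments are merged
#' on the shared reference coordinates — or ingests a precomputed gapped
#' FASTA. Homoeologs are globally collinear, so a simple global scheme is
#' adequate; supply a curated alignment to override it.
#'
#' Region labels are derived per genome by projecting that genome's exon
#' intervals through the coordinate maps: a column is EXON for genome g if
#' its ungapped position in g lies in an exon, INTRON otherwise; columns
#' within `junctionWindow` columns of an exon/intron boundary are
#' relabelled JUNCTION. Gap columns inherit the label of the nearest
#' preceding ungapped position.
#'
#' @param copies list of [GeneCopy-class] (2 or more).
#' @param precomputed optional: a named character vector / DNAStringSet of
#'   gapped rows (same names as the copies) or the path of an aligned
#'   FASTA. Degapping each row must reproduce the corresponding input
#'   sequence exactly.
#' @param junctionWindow integer half-width (columns) of the JUNCTION
#'   label around each exon/intron boundary; default 5, matching the
#'   3'-proximal window that dominates the specificity model.
#' @return a [HomoeologAlignment-class].
#' @examples
#' fam <- simulateFamily(simulationParams(seed = 7))
#' aln <- buildAlignment(fam$copies)
#' aln
#' @export
buildAlignment <- function(copies, precomputed = NULL, junctionWindow = 5L) {
  if (length(copies) < 2L) stop("need at least 2 gene copies")
  ids <- vapply(copies, genomeId, character(1))
  names(copies) <- ids
  if (is.null(precomputed)) {
    rows <- .starAlign(copies)
  } else {
    rows <- .ingestPrecomputed(precomputed, copies)
  }
  .newAlignment(copies, rows, junctionWindow)
}

.ingestPrecomputed <- function(precomputed, copies) {
  if (is.character(precomputed) && length(precomputed) == 1L &&
      file.exists(precomputed)) {
    ss <- Biostrings::readDNAStringSet(precomputed)
    names(ss) <- sub("\\s.*$", "", names(ss))
    precomputed <- ss
  }
  rows <- toupper(as.character(precomputed))
  ids <- vapply(copies, genomeId, character(1))
  if (!is.null(names(rows)) && all(ids %in% names(rows)))
    rows <- rows[ids]
  if (length(rows) != length(copies))
    stop("precomputed alignment must have one row per copy")
  for (i in seq_along(copies)) {
    if (!identical(gsub("-", "", rows[[i]], fixed = TRUE),
                   as.character(copies[[i]]@sequence)))
      stop("precomputed alignment row for '", ids[i],
           "' does not degap to the input sequence")
  }
  unname(rows)
}

# Star alignment: pairwise-align every copy to copies[[1]], then merge on
# the reference coordinate system. Insertions relative to the reference
# are given private column blocks per copy (deterministic, no attempt to
# homologize insertions of different copies at the same locus).
.starAlign <- function(copies) {
  n <- length(copies)
  ref <- as.character(copies[[1L]]@sequence)
  Lr <- nchar(ref)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  # per copy i >= 2: base aligned to each ref position, and insert strings
  baseAt <- vector("list", n)
  insAt <- vector("list", n)   # insAt[[i]][j + 1] = insert after ref pos j
  for (i in seq_len(n)[-1L]) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = copies[[i]]@sequence, subject = copies[[1L]]@sequence,
      type = "global", substitutionMatrix = sm,
      gapOpening = 5, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    b <- rep("-", Lr)
    ins <- rep("", Lr + 1L)
    j <- 0L  # current ref position
    buf <- character(0)
    for (k in seq_along(s)) {
      if (s[k] == "-") {
        buf <- c(buf, p[k])
      } else {
        if (length(buf)) {
          ins[j + 1L] <- paste0(buf, collapse = "")
          buf <- character(0)
        }
        j <- j + 1L
        b[j] <- p[k]
      }
    }
    if (length(buf)) ins[j + 1L] <- paste0(buf, collapse = "")
    baseAt[[i]] <- b
    insAt[[i]] <- ins
  }
  # merge: emit, for each ref locus j in 0..Lr, each copy's private insert
  # block (in copy order), then (for j >= 1) the shared ref column.
  refChars <- strsplit(ref, "")[[1L]]
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- character(0)
  pieces <- vector("list", n)
  for (i in seq_len(n)) pieces[[i]] <- list()
  for (j in 0L:Lr) {
    if (j >= 1L) {
      for (ii in seq_len(n)) {
        pieces[[ii]][[length(pieces[[ii]]) + 1L]] <-
          if (ii == 1L) refChars[j] else baseAt[[ii]][j]
      }
    }
    # insert blocks keyed j + 1 sit between ref positions j and j + 1
    for (i in seq_len(n)[-1L]) {
      w <- nchar(insAt[[i]][j + 1L])
      if (w > 0L) {
        for (ii in seq_len(n)) {
          pieces[[ii]][[length(pieces[[ii]]) + 1L]] <-
            if (ii == i) insAt[[i]][j + 1L] else strrep("-", w)
        }
      }
    }
  }
  vapply(pieces, function(x) paste0(unlist(x), collapse = ""), character(1))
}

.newAlignment <- function(copies, rows, junctionWindow) {
  n <- length(copies)
  ids <- vapply(copies, genomeId, character(1))
  width <- nchar(rows[1L])
  colToPos <- posToCol <- vector("list", n)
  names(colToPos) <- names(posToCol) <- ids
  region <- matrix(NA_character_, nrow = n, ncol = width,
                   dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    ch <- strsplit(rows[i], "")[[1L]]
    ungapped <- ch != "-"
    c2p <- rep(NA_integer_, width)
    c2p[ungapped] <- seq_len(sum(ungapped))
    p2c <- which(ungapped)
    colToPos[[i]] <- c2p
    posToCol[[i]] <- p2c
    posReg <- .positionRegions(copies[[i]])
    lab <- rep(NA_character_, width)
    lab[ungapped] <- posReg[c2p[ungapped]]
    # gap columns inherit the preceding ungapped label (or the following
    # one at a leading gap)
    if (anyNA(lab)) {
      filled <- lab
      last <- NA_character_
      for (c in seq_len(width)) {
        if (is.na(filled[c])) filled[c] <- last else last <- filled[c]
      }
      nxt <- NA_character_
      for (c in rev(seq_len(width))) {
        if (is.na(filled[c])) filled[c] <- nxt else nxt <- filled[c]
      }
      lab <- filled
    }
    # JUNCTION override around exon/intron boundaries
    if (width > 1L && junctionWindow > 0L) {
      change <- which(lab[-width] != lab[-1L])
      jx <- unique(unlist(lapply(change, function(c)
        max(1L, c - junctionWindow + 1L):min(width, c + junctionWindow))))
      lab[jx] <- "JUNCTION"
    }
    region[i, ] <- lab
  }
  methods::new("HomoeologAlignment", copies = copies, rows = unname(rows),
               columnRegion = region, colToPos = colToPos,
               posToCol = posToCol,
               junctionWindow = as.integer(junctionWindow))
}

#' Accessors for HomoeologAlignment
#'
#' `alignmentRows` returns the gapped rows (named character vector);
#' `columnRegion` the genomes x columns region-label matrix; `colToPos`
#' and `posToCol` the coordinate maps of one genome.
#'
#' @param x a [HomoeologAlignment-class].
#' @param genome genome label.
#' @name homoeologAlignment-accessors
NULL

#' @rdname homoeologAlignment-accessors
#' @export
setMethod("alignmentRows", "HomoeologAlignment", function(x) {
  stats::setNames(x@rows, names(x@copies))
})

#' @rdname homoeologAlignment-accessors
#' @export
setMethod("columnRegion", "HomoeologAlignment", function(x) x@columnRegion)

#' @rdname homoeologAlignment-accessors
#' @export
setMethod("colToPos", "HomoeologAlignment", function(x, genome) {
  .checkGenome(x, genome)
  x@colToPos[[genome]]
})

#' @rdname homoeologAlignment-accessors
#' @export
setMethod("posToCol", "HomoeologAlignment", function(x, genome) {
  .checkGenome(x, genome)
  x@posToCol[[genome]]
})

.checkGenome <- function(aln, genome) {
  if (!genome %in% names(aln@copies))
    stop("unknown genome label '", genome, "'; alignment has: ",
         paste(names(aln@copies), collapse = ", "))
  invisible(genome)
}

setMethod("show", "HomoeologAlignment", function(object) {
  cat(sprintf("HomoeologAlignment: %d copies (%s), %d columns\n",
              length(object@copies),
              paste(names(object@copies), collapse = ", "),
              nchar(object@rows[1L])))
  gapcols <- sum(vapply(seq_len(nchar(object@rows[1L])), function(c)
    any(substr(object@rows, c, c) == "-"), logical(1)))
  cat(sprintf("  columns with a gap in some row: %d\n", gapcols))
})
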