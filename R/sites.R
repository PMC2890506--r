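#' Find subgenome-discriminative sites in a homoeolog alignment
#'
#' Scans alignment columns for positions where the target genome's residue
#' differs from the residue of every other genome — the sites a
#' genome-specific primer can anchor its 3' terminus on. Homoeologs
#' diverge far more in introns than in exons, so the default region
#' filter restricts discovery to INTRON and JUNCTION columns; pass
#' `regions = c("EXON","INTRON","JUNCTION")` to allow exonic anchors too.
#'
#' Site kinds: `SNP` — all genomes have a base at the column and the
#' target base differs from every off-target base; `INDEL_EDGE` — the
#' target has a base where at least one off-target is gapped (the
#' column sits in, or at the edge of, an off-target deletion). Columns
#' where the target itself is gapped cannot anchor a primer and are not
#' returned. Columns containing `N` in any genome are skipped. Partial
#' sites (target differs from some but not all off-targets) are excluded
#' by default and flagged when requested.
#'
#' @param aln a [HomoeologAlignment-class].
#' @param targetGenome genome label to design against.
#' @param regions character subset of EXON/INTRON/JUNCTION (region of the
#'   column in the *target* genome); default intron + junction.
#' @param includePartial also return partially discriminative sites,
#'   flagged with `partial = TRUE` (they are never used for anchoring by
#'   the candidate generator).
#' @return data.frame with one row per site: `target_genome`, `column`
#'   (alignment column), `pos` (1-based position in the target sequence),
#'   `kind`, `target_base`, `offtarget_bases` (comma-joined
#'   `genome=base`), `region`, `partial`, `at_gap_edge` (for INDEL_EDGE:
#'   is this the first/last target base adjacent to the off-target gap
#'   run).
#' @examples
#' fam <- simulateFamily(simulationParams(seed = 3))
#' aln <- buildAlignment(fam$copies, precomputed = fam$trueAlignment)
#' head(findDiscriminativeSites(aln, genomeId(fam$copies[[1]])))
#' @export
findDiscriminativeSites <- function(aln, targetGenome,
                                    regions = c("INTRON", "JUNCTION"),
                                    includePartial = FALSE) {
  .checkGenome(aln, targetGenome)
  regions <- match.arg(regions, c("EXON", "INTRON", "JUNCTION"),
                       several.ok = TRUE)
  ids <- names(aln@copies)
  chars <- do.call(rbind, strsplit(aln@rows, ""))
  rownames(chars) <- ids
  ti <- match(targetGenome, ids)
  others <- ids[-ti]
  width <- ncol(chars)

  tb <- chars[ti, ]
  ob <- chars[others, , drop = FALSE]
  hasN <- tb == "N" | colSums(ob == "N") > 0L
  targetBase <- tb != "-"
  diffs <- sweep(ob, 2L, tb, FUN = "!=")
  nDiff <- colSums(diffs)
  full <- targetBase & !hasN & nDiff == length(others)
  part <- targetBase & !hasN & nDiff > 0L & nDiff < length(others)
  regOK <- aln@columnRegion[ti, ] %in% regions
  keep <- which((full | (includePartial & part)) & regOK)
  if (!length(keep)) {
    return(data.frame(target_genome = character(), column = integer(),
                      pos = integer(), kind = character(),
                      target_base = character(),
                      offtarget_bases = character(), region = character(),
                      partial = logical(), at_gap_edge = logical(),
                      stringsAsFactors = FALSE))
  }
  anyGap <- colSums(ob == "-") > 0L
  # a target base column flanking (or inside) an off-target gap run whose
  # neighbour column is not gapped in that off-target marks the run edge
  edge <- vapply(keep, function(c) {
    if (!anyGap[c]) return(FALSE)
    for (g in seq_len(nrow(ob))) {
      if (ob[g, c] != "-") next
      left <- c > 1L && ob[g, c - 1L] != "-"
      right <- c < width && ob[g, c + 1L] != "-"
      if (left || right) return(TRUE)
    }
    FALSE
  }, logical(1))
  data.frame(
    target_genome = targetGenome,
    column = keep,
    pos = aln@colToPos[[targetGenome]][keep],
    kind = ifelse(anyGap[keep], "INDEL_EDGE", "SNP"),
    target_base = tb[keep],
    offtarget_bases = vapply(keep, function(c)
      paste(paste0(others, "=", ob[, c]), collapse = ","), character(1)),
    region = aln@columnRegion[ti, keep],
    partial = !full[keep],
    at_gap_edge = edge,
    stringsAsFactors = FALSE
  )
}
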