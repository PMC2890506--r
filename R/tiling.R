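#' Amplicon size / overlap constraints for tiling
#'
#' Defaults encode the assay design goals: products of 800-1500 bp are
#' fully sequenceable from both ends on a capillary sequencer, and
#' neighboring amplicons should overlap by 80-100 bp so Sanger reads
#' assemble across junctions. The size band is soft by default — sizes
#' outside it are penalized, not rejected — because useful designs
#' occasionally need a product slightly outside the band.
#'
#' @param amplicon_min_bp,amplicon_max_bp preferred product-size band.
#' @param overlap_min_bp,overlap_max_bp preferred neighbor-overlap band.
#' @param hard_size_band reject (instead of penalize) out-of-band sizes.
#' @return named list of class `TilingConstraints`.
#' @export
tilingConstraints <- function(amplicon_min_bp = 800L,
                              amplicon_max_bp = 1500L,
                              overlap_min_bp = 80L, overlap_max_bp = 100L,
                              hard_size_band = FALSE) {
  stopifnot(amplicon_min_bp > 0L, amplicon_min_bp < amplicon_max_bp,
            overlap_min_bp >= 0L, overlap_min_bp <= overlap_max_bp)
  structure(list(amplicon_min_bp = as.integer(amplicon_min_bp),
                 amplicon_max_bp = as.integer(amplicon_max_bp),
                 overlap_min_bp = as.integer(overlap_min_bp),
                 overlap_max_bp = as.integer(overlap_max_bp),
                 hard_size_band = isTRUE(hard_size_band)),
            class = "TilingConstraints")
}

.sizePenalty <- function(size, constraints) {
  if (size < constraints$amplicon_min_bp)
    constraints$amplicon_min_bp - size
  else if (size > constraints$amplicon_max_bp)
    size - constraints$amplicon_max_bp
  else 0L
}

#' Enumerate genome-specific primer pairs from candidates
#'
#' Combines forward and reverse candidates of one genome, keeps
#' combinations whose predicted on-target product size fits the size
#' band (softly, unless `hard_size_band`) and that pass the full
#' [isGenomeSpecific()] check against the off-target templates, and
#' scores each surviving pair.
#'
#' The specificity margin of a pair is, minimized over off-target
#' templates, the mismatch count of the better-protected primer at its
#' best (fewest-mismatch) off-target binding site — i.e. how many
#' mismatches the off-target would have to tolerate on its least
#' mismatched primer before the pair could amplify it. Sites are
#' searched with an widened mismatch allowance so the margin can exceed
#' the amplification cap; a primer with no off-target site at all gets
#' the maximum margin.
#'
#' @param candidates data.frame from [enumerateAnchoredCandidates()]
#'   (status "ok" rows of one genome).
#' @param target the target template ([GeneCopy-class] or named
#'   sequence).
#' @param offtargets off-target templates (named list/vector or list of
#'   [GeneCopy-class]).
#' @param constraints [tilingConstraints()].
#' @param params [pcrParams()].
#' @param maxPairs safety cap on the number of coordinate-compatible
#'   combinations submitted to the specificity check (closest-to-band
#'   sizes first); default 400.
#' @return data.frame, one row per specific pair: primer columns
#'   (`fwd_seq`, `rev_seq`, `fwd_start`, `rev_end`, ...), `amplicon_start`,
#'   `amplicon_end`, `size_bp`, `size_penalty`, `margin`.
#' @export
enumerateSpecificPairs <- function(candidates, target, offtargets,
                                   constraints = tilingConstraints(),
                                   params = pcrParams(), maxPairs = 400L) {
  cand <- candidates[candidates$status == "ok", , drop = FALSE]
  fwd <- cand[cand$orientation == "forward", , drop = FALSE]
  rev <- cand[cand$orientation == "reverse", , drop = FALSE]
  if (!nrow(fwd) || !nrow(rev)) return(.emptyPairs())
  tgt <- .asTemplateList(target)
  offs <- .asTemplateList(offtargets)
  # coordinate prefilter: projected size from candidate coordinates
  grid <- expand.grid(fi = seq_len(nrow(fwd)), ri = seq_len(nrow(rev)))
  size0 <- rev$end[grid$ri] - fwd$start[grid$fi] + 1L
  slack <- if (constraints$hard_size_band) 0L else
    as.integer(0.25 * constraints$amplicon_max_bp)
  keep <- size0 >= max(constraints$amplicon_min_bp - slack, 50L) &
    size0 <= constraints$amplicon_max_bp + slack &
    fwd$end[grid$fi] < rev$start[grid$ri]
  grid <- grid[keep, , drop = FALSE]
  size0 <- size0[keep]
  pen0 <- vapply(size0, .sizePenalty, integer(1), constraints = constraints)
  ord <- order(pen0, size0, grid$fi, grid$ri)
  grid <- grid[ord, , drop = FALSE]
  if (nrow(grid) > maxPairs) grid <- grid[seq_len(maxPairs), , drop = FALSE]
  # scan each distinct primer once per template (widened tolerance so the
  # same hit tables serve the class rules and the margin computation)
  wide <- params$maxMismatches + 3L
  cache <- new.env(parent = emptyenv())
  hitsOf <- function(primer, tplName, tpl) {
    key <- paste0(tplName, "|", primer)
    if (!is.null(cache[[key]])) return(cache[[key]])
    h <- scanBindingSites(primer, tpl, wide)
    if (nrow(h)) {
      h$class <- vapply(seq_len(nrow(h)), function(i)
        classifyPrimerBinding(.parsePos(h$mismatch_pos_3p[i]),
                              maxMismatches = params$maxMismatches),
        character(1))
    }
    cache[[key]] <- h
    h
  }
  out <- list()
  for (k in seq_len(nrow(grid))) {
    f <- fwd[grid$fi[k], ]
    r <- rev[grid$ri[k], ]
    verdict <- .pairVerdict(f$sequence, r$sequence, tgt, offs, params,
                            hitsOf)
    if (!verdict$specific) next
    amp <- verdict$amplicon
    pen <- .sizePenalty(amp$size_bp, constraints)
    if (constraints$hard_size_band && pen > 0L) next
    out[[length(out) + 1L]] <- data.frame(
      genome = f$genome,
      fwd_seq = f$sequence, rev_seq = r$sequence,
      fwd_start = f$start, fwd_end = f$end,
      rev_start = r$start, rev_end = r$end,
      fwd_anchor_pos = f$anchor_pos, rev_anchor_pos = r$anchor_pos,
      fwd_tm_C = f$tm_C, rev_tm_C = r$tm_C,
      fwd_region = f$region, rev_region = r$region,
      amplicon_start = amp$start, amplicon_end = amp$end,
      size_bp = amp$size_bp, size_penalty = pen,
      margin = verdict$margin,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.emptyPairs())
  res <- do.call(rbind, out)
  res <- res[order(res$amplicon_start, res$size_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.specificityMargin <- function(fwd, rev, offtargets, params) {
  wide <- params$maxMismatches + 3L
  margins <- vapply(offtargets, function(tpl) {
    per <- vapply(c(fwd, rev), function(p) {
      hits <- scanBindingSites(p, tpl, wide)
      if (!nrow(hits)) wide + 1L else min(hits$n_mismatch)
    }, numeric(1))
    max(per)  # the better-protected primer gates off-target amplification
  }, numeric(1))
  as.integer(min(margins))
}

# Same decision rule as isGenomeSpecific(), computed from cached per-primer
# hit tables: amplifiable products are converging (+,-) hit combos within
# the size cap whose pairwise class (weaker of the two) is not NONE.
.pairVerdict <- function(fwdSeq, revSeq, tgt, offs, params, hitsOf) {
  wide <- params$maxMismatches + 3L
  products <- function(tplName, tpl, classed) {
    fh <- hitsOf(fwdSeq, tplName, tpl)
    rh <- hitsOf(revSeq, tplName, tpl)
    if (classed) {
      fh <- fh[fh$class != "NONE", , drop = FALSE]
      rh <- rh[rh$class != "NONE", , drop = FALSE]
    }
    res <- list()
    combos <- list(list(fh[fh$strand == "+", , drop = FALSE],
                        rh[rh$strand == "-", , drop = FALSE]),
                   list(rh[rh$strand == "+", , drop = FALSE],
                        fh[fh$strand == "-", , drop = FALSE]))
    for (cb in combos) {
      ph <- cb[[1L]]; mh <- cb[[2L]]
      if (!nrow(ph) || !nrow(mh)) next
      for (i in seq_len(nrow(ph))) for (j in seq_len(nrow(mh))) {
        if (ph$end[i] > mh$start[j]) next
        size <- mh$end[j] - ph$start[i] + 1L
        if (size > params$maxProductBp) next
        cls <- names(.CLASS_RANK)[1L + min(.CLASS_RANK[ph$class[i]],
                                           .CLASS_RANK[mh$class[j]])]
        res[[length(res) + 1L]] <- list(start = ph$start[i],
                                        end = mh$end[j], size_bp = size,
                                        class = cls)
      }
    }
    res
  }
  onT <- products(names(tgt)[1L], tgt[[1L]], classed = TRUE)
  strong <- Filter(function(x) x$class == "STRONG", onT)
  if (length(strong) != 1L)
    return(list(specific = FALSE))
  for (tn in names(offs)) {
    offP <- products(tn, offs[[tn]], classed = TRUE)
    if (length(offP)) return(list(specific = FALSE))
  }
  margins <- vapply(names(offs), function(tn) {
    per <- vapply(c(fwdSeq, revSeq), function(p) {
      hits <- hitsOf(p, tn, offs[[tn]])
      if (!nrow(hits)) wide + 1L else min(hits$n_mismatch)
    }, numeric(1))
    max(per)
  }, numeric(1))
  list(specific = TRUE, amplicon = strong[[1L]],
       margin = as.integer(min(margins)))
}

.emptyPairs <- function() {
  data.frame(genome = character(), fwd_seq = character(),
             rev_seq = character(), fwd_start = integer(),
             fwd_end = integer(), rev_start = integer(),
             rev_end = integer(), fwd_anchor_pos = integer(),
             rev_anchor_pos = integer(), fwd_tm_C = numeric(),
             rev_tm_C = numeric(), fwd_region = character(),
             rev_region = character(), amplicon_start = integer(),
             amplicon_end = integer(), size_bp = integer(),
             size_penalty = integer(), margin = integer(),
             stringsAsFactors = FALSE)
}

.unionBp <- function(starts, ends) {
  if (!length(starts)) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1L]; ce <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= ce + 1L) {
      ce <- max(ce, ends[i])
    } else {
      tot <- tot + (ce - cs + 1L)
      cs <- starts[i]; ce <- ends[i]
    }
  }
  tot + (ce - cs + 1L)
}

#' Select primer pairs whose amplicons tile the gene
#'
#' Chooses, from the genome-specific pairs, a set of amplicons that (1)
#' maximizes the union of covered bases, (2) among equal-coverage
#' solutions uses the fewest pairs, and (3) among those maximizes the
#' total specificity margin. The maximal attainable union is the union
#' of all candidate amplicons; within each contiguous covered segment a
#' sweep selects the minimum number of intervals that cover it (exact
#' for interval covering), breaking ties by margin, then
#' lexicographically by start and size, so the result is deterministic
#' and independent of input order. Neighboring overlaps outside the
#' preferred band are legal and reported, not rejected.
#'
#' @param pairs data.frame from [enumerateSpecificPairs()] (one genome).
#' @param geneLength full genomic length of the gene copy.
#' @param constraints [tilingConstraints()].
#' @param genome genome label for the solution (defaults to the pairs'
#'   genome).
#' @return a [TilingSolution-class]; with an empty pair list, an empty
#'   solution with coverage 0.
#' @export
tileGene <- function(pairs, geneLength, constraints = tilingConstraints(),
                     genome = NULL) {
  if (is.null(genome))
    genome <- if (nrow(pairs)) pairs$genome[1L] else "NA"
  if (!nrow(pairs)) {
    return(methods::new("TilingSolution", genomeId = genome,
                        pairs = .emptyPairs(), coveredBp = 0L,
                        geneLength = as.integer(geneLength),
                        junctionOverlaps = integer(0)))
  }
  s <- pairs$amplicon_start; e <- pairs$amplicon_end
  # contiguous components of the union of all amplicons
  o <- order(s, e)
  comps <- list(); cs <- s[o[1L]]; ce <- e[o[1L]]
  for (i in o[-1L]) {
    if (s[i] <= ce + 1L) ce <- max(ce, e[i])
    else { comps[[length(comps) + 1L]] <- c(cs, ce); cs <- s[i]; ce <- e[i] }
  }
  comps[[length(comps) + 1L]] <- c(cs, ce)
  chosen <- integer(0)
  for (cp in comps) {
    covered <- cp[1L] - 1L
    while (covered < cp[2L]) {
      elig <- which(s <= covered + 1L & e > covered)
      best <- elig[order(-e[elig], -pairs$margin[elig], s[elig],
                         pairs$size_bp[elig])][1L]
      chosen <- c(chosen, best)
      covered <- e[best]
    }
  }
  chosen <- unique(chosen)
  sol <- pairs[chosen[order(s[chosen], e[chosen])], , drop = FALSE]
  rownames(sol) <- NULL
  ov <- if (nrow(sol) > 1L) {
    as.integer(sol$amplicon_end[-nrow(sol)] - sol$amplicon_start[-1L] + 1L)
  } else integer(0)
  methods::new("TilingSolution", genomeId = genome, pairs = sol,
               coveredBp = .unionBp(sol$amplicon_start, sol$amplicon_end),
               geneLength = as.integer(geneLength),
               junctionOverlaps = ov)
}

#' @rdname tileGene
#' @param x a `TilingSolution`.
#' @export
setMethod("chosenPairs", "TilingSolution", function(x) x@pairs)

#' @rdname tileGene
#' @export
setMethod("coveredBp", "TilingSolution", function(x) x@coveredBp)

#' @rdname tileGene
#' @export
setMethod("coverageFraction", "TilingSolution", function(x)
  x@coveredBp / x@geneLength)

#' @rdname tileGene
#' @export
setMethod("genomeId", "TilingSolution", function(x) x@genomeId)

setMethod("show", "TilingSolution", function(object) {
  cat(sprintf(
    "TilingSolution '%s': %d pairs, %d / %d bp covered (%.1f%%)\n",
    object@genomeId, nrow(object@pairs), object@coveredBp,
    object@geneLength, 100 * object@coveredBp / object@geneLength))
  if (length(object@junctionOverlaps))
    cat("  neighbor overlaps (bp):",
        paste(object@junctionOverlaps, collapse = ", "), "\n")
})

#' Per-genome coverage table for a set of tiling solutions
#'
#' @param solutions list of [TilingSolution-class] (one per genome).
#' @param copies optional named list of [GeneCopy-class]; when given,
#'   gene lengths are cross-checked against the solutions.
#' @return data.frame: `genome`, `n_pairs`, `covered_bp`, `gene_length`,
#'   `coverage_fraction` (and `coverage_pct`, rounded to 0.1).
#' @export
coverageReport <- function(solutions, copies = NULL) {
  rows <- lapply(solutions, function(sol) {
    data.frame(genome = sol@genomeId, n_pairs = nrow(sol@pairs),
               covered_bp = sol@coveredBp, gene_length = sol@geneLength,
               coverage_fraction = sol@coveredBp / sol@geneLength,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(copies)) {
    for (i in seq_len(nrow(out))) {
      cp <- copies[[out$genome[i]]]
      if (!is.null(cp) && geneLength(cp) != out$gene_length[i])
        stop("gene length mismatch for genome ", out$genome[i])
    }
  }
  out$coverage_pct <- round(100 * out$coverage_fraction, 1L)
  out
}
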