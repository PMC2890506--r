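#' Bundle all tunable parameters of a design run
#'
#' @param thermo [thermoParams()].
#' @param quality [qualityParams()].
#' @param pcr [pcrParams()].
#' @param tiling [tilingConstraints()].
#' @param lenMin,lenMax primer length window.
#' @param regions alignment regions searched for anchor sites.
#' @param seed RNG seed recorded with the run.
#' @return named list of class `RunConfig`.
#' @export
runConfig <- function(thermo = thermoParams(), quality = qualityParams(),
                      pcr = pcrParams(), tiling = tilingConstraints(),
                      lenMin = 16L, lenMax = 25L,
                      regions = c("INTRON", "JUNCTION"), seed = 1L) {
  structure(list(thermo = thermo, quality = quality, pcr = pcr,
                 tiling = tiling, lenMin = as.integer(lenMin),
                 lenMax = as.integer(lenMax), regions = regions,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' End-to-end genome-specific primer design
#'
#' Runs the full pipeline for every genome copy of a homoeolog family:
#' multiple alignment, discriminative-site discovery, 3'-anchored
#' candidate generation with Tm adjustment and quality filtering,
#' specificity-checked pairing, and tiling with union-coverage
#' accounting. Stage counts (sites, candidates, pairs, tiled pairs) are
#' reported via `message()` when `verbose`.
#'
#' @param copies named list of [GeneCopy-class] (2+), or pass `fasta` and
#'   `gff3` paths instead.
#' @param config a [runConfig()].
#' @param fasta,gff3 optional input paths forwarded to
#'   [readGeneFamily()] when `copies` is missing.
#' @param precomputedAlignment optional gapped rows / aligned-FASTA path
#'   forwarded to [buildAlignment()].
#' @param verbose narrate per-stage counts.
#' @return list: `alignment`, `sites` (per-genome list), `candidates`
#'   (per-genome data.frame), `pairs` (per-genome data.frame),
#'   `solutions` (per-genome [TilingSolution-class]), `coverage`
#'   (data.frame), `config`.
#' @examples
#' fam <- simulateFamily(simulationParams(seed = 5, n_exons = 4))
#' res <- designPrimers(fam$copies,
#'                      precomputedAlignment = fam$trueAlignment)
#' res$coverage
#' @export
designPrimers <- function(copies = NULL, config = runConfig(),
                          fasta = NULL, gff3 = NULL,
                          precomputedAlignment = NULL, verbose = FALSE) {
  if (is.null(copies)) {
    if (is.null(fasta) || is.null(gff3))
      stop("supply either 'copies' or both 'fasta' and 'gff3'")
    copies <- readGeneFamily(fasta, gff3)
  }
  ids <- vapply(copies, genomeId, character(1))
  names(copies) <- ids
  aln <- buildAlignment(copies, precomputed = precomputedAlignment)
  say <- function(...) if (verbose) message(sprintf(...))
  sites <- candidates <- pairs <- solutions <- list()
  for (g in ids) {
    sites[[g]] <- findDiscriminativeSites(aln, g, regions = config$regions)
    say("[%s] discriminative sites: %d", g, nrow(sites[[g]]))
    candidates[[g]] <- enumerateAnchoredCandidates(
      aln, g, sites[[g]], thermo = config$thermo,
      quality = config$quality, lenMin = config$lenMin,
      lenMax = config$lenMax)
    say("[%s] accepted candidates: %d", g, nrow(candidates[[g]]))
    offs <- copies[setdiff(ids, g)]
    pairs[[g]] <- enumerateSpecificPairs(
      candidates[[g]], copies[[g]], offs,
      constraints = config$tiling, params = config$pcr)
    say("[%s] genome-specific pairs: %d", g, nrow(pairs[[g]]))
    solutions[[g]] <- tileGene(pairs[[g]], geneLength(copies[[g]]),
                               constraints = config$tiling, genome = g)
    say("[%s] tiled pairs: %d, coverage %.1f%%", g,
        nrow(chosenPairs(solutions[[g]])),
        100 * coverageFraction(solutions[[g]]))
  }
  if (all(vapply(pairs, nrow, integer(1)) == 0L))
    warning("no genome-specific primer pair found for any genome ",
            "(copies may be identical or divergence insufficient)")
  list(alignment = aln, sites = sites, candidates = candidates,
       pairs = pairs, solutions = solutions,
       coverage = coverageReport(solutions, copies), config = config)
}

#' Validate a primer panel against template sequences
#'
#' Re-scores externally designed primer pairs (e.g. a published primer
#' table loaded with [readPrimerTable()]): for every pair, runs
#' [insilicoPCR()] on all templates and [isGenomeSpecific()] against the
#' pair's declared target genome.
#'
#' @param panel data.frame with columns `pair`, `fwd_name`, `fwd_seq`,
#'   `rev_name`, `rev_seq`, `genome` (declared target; must match a
#'   template name) and optionally `size_bp` (declared product size).
#' @param templates named list/vector of template sequences or
#'   [GeneCopy-class] objects; names are genome labels.
#' @param params [pcrParams()].
#' @return data.frame: one row per pair with `specific` verdict,
#'   `target_strong_n`, `predicted_size_bp` (NA if no STRONG target
#'   product), `size_matches` (when a declared size is present), and
#'   `offtarget_weak_n` counting the disqualifying faint off-target hits.
#' @export
validatePrimerPanel <- function(panel, templates, params = pcrParams()) {
  templates <- .asTemplateList(templates)
  if (!length(templates)) stop("at least one template is required")
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    p <- panel[i, ]
    if (!p$genome %in% names(templates))
      stop("declared target genome '", p$genome,
           "' not among template names")
    tgt <- templates[p$genome]
    offs <- templates[setdiff(names(templates), p$genome)]
    v <- isGenomeSpecific(p$fwd_seq, p$rev_seq, tgt, offs, params)
    strong <- v$target_amplicons[v$target_amplicons$class == "STRONG", ,
                                 drop = FALSE]
    predSize <- if (nrow(strong)) strong$size_bp[1L] else NA_integer_
    data.frame(pair = p$pair, genome = p$genome,
               specific = v$specific,
               target_strong_n = v$target_strong_n,
               predicted_size_bp = predSize,
               size_matches = if ("size_bp" %in% names(p) &&
                                  !is.na(p$size_bp))
                 identical(as.integer(predSize), as.integer(p$size_bp))
               else NA,
               offtarget_weak_n = sum(v$offtarget_hits$class == "WEAK"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
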