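#' Quality-filter thresholds for primer candidates
#'
#' Thresholds mirror common primer-design defaults; none is fixed by the
#' underlying assay, so all are configurable.
#'
#' @param gcMin,gcMax accepted GC fraction window (inclusive).
#' @param maxHomopolymer longest tolerated single-base run.
#' @param threePrimeSeed reject when the reverse complement of the
#'   3'-terminal k-mer of this length occurs elsewhere in the primer
#'   (3'-end self-complementarity, the seed of primer-dimer extension).
#' @param selfDimerSeed reject when any window of this length is perfectly
#'   self-complementary to another window of the primer.
#' @return a named list of class `QualityParams`.
#' @export
qualityParams <- function(gcMin = 0.30, gcMax = 0.70, maxHomopolymer = 5L,
                          threePrimeSeed = 5L, selfDimerSeed = 8L) {
  stopifnot(gcMin < gcMax, maxHomopolymer >= 1L,
            threePrimeSeed >= 3L, selfDimerSeed >= threePrimeSeed)
  structure(list(gcMin = gcMin, gcMax = gcMax,
                 maxHomopolymer = as.integer(maxHomopolymer),
                 threePrimeSeed = as.integer(threePrimeSeed),
                 selfDimerSeed = as.integer(selfDimerSeed)),
            class = "QualityParams")
}

.gcFraction <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  sum(ch %in% c("G", "C")) / length(ch)
}

.maxRun <- function(seq) {
  r <- rle(strsplit(seq, "")[[1L]])
  max(r$lengths)
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.qualityReason <- function(seq, quality) {
  gc <- .gcFraction(seq)
  if (gc < quality$gcMin || gc > quality$gcMax) return("gc_out_of_range")
  if (.maxRun(seq) > quality$maxHomopolymer) return("homopolymer_run")
  n <- nchar(seq)
  k <- quality$threePrimeSeed
  # a fold-back pairing the 3' seed needs a loop of >= 3 nt, so matches
  # overlapping or abutting the seed itself do not count
  if (n > k + 3L) {
    tail3 <- substr(seq, n - k + 1L, n)
    rest <- substr(seq, 1L, n - k - 3L)
    if (nchar(rest) >= k && grepl(.revcomp(tail3), rest, fixed = TRUE))
      return("three_prime_self_complementarity")
  }
  m <- quality$selfDimerSeed
  if (n >= m) {
    rc <- .revcomp(seq)
    for (i in seq_len(n - m + 1L)) {
      if (grepl(substr(rc, i, i + m - 1L), seq, fixed = TRUE))
        return("self_dimer_seed")
    }
  }
  NA_character_
}

#' Enumerate 3'-anchored genome-specific primer candidates
#'
#' Automates the manual design step of picking primers whose 3'-terminal
#' base sits on a subgenome-diagnostic site: for every fully
#' discriminative site, up to two candidates are generated (one per
#' orientation), each adjusted into the Tm window by 5'-terminal editing
#' ([adjustTmBy5Prime()]) and then quality-filtered
#' ([filterCandidates()]). Candidates whose 5' extension would run off
#' the template are skipped. Partial sites are never anchored.
#'
#' Anchors in INTRON or JUNCTION regions are ranked before EXON anchors
#' in the returned table (intron divergence is what makes homoeologs
#' separable; exonic anchors are allowed, not preferred).
#'
#' @param aln a [HomoeologAlignment-class].
#' @param targetGenome genome label.
#' @param sites data.frame from [findDiscriminativeSites()] on the same
#'   alignment.
#' @param thermo [thermoParams()].
#' @param quality [qualityParams()].
#' @param lenMin,lenMax primer length window (see [adjustTmBy5Prime()]).
#' @param keepRejected keep Tm- or quality-rejected candidates in the
#'   table (with `status`/`reason` filled) instead of dropping them.
#' @return data.frame, one row per candidate: `genome`, `orientation`,
#'   `sequence` (5'->3'), `start`, `end` (1-based closed template
#'   interval), `length`, `tm_C`, `anchor_pos`, `anchor_column`,
#'   `anchor_kind`, `region`, `short`, `status`, `reason`.
#' @export
enumerateAnchoredCandidates <- function(aln, targetGenome, sites,
                                        thermo = thermoParams(),
                                        quality = qualityParams(),
                                        lenMin = 16L, lenMax = 25L,
                                        keepRejected = FALSE) {
  .checkGenome(aln, targetGenome)
  tpl <- as.character(aln@copies[[targetGenome]]@sequence)
  sites <- sites[!sites$partial & sites$target_genome == targetGenome, ,
                 drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    for (orient in c("forward", "reverse")) {
      fit <- adjustTmBy5Prime(tpl, st$pos, orient, thermo, lenMin, lenMax)
      if (fit$status != "ok") {
        if (keepRejected) {
          rows[[length(rows) + 1L]] <- data.frame(
            genome = targetGenome, orientation = orient,
            sequence = NA_character_, start = NA_integer_,
            end = NA_integer_, length = NA_integer_, tm_C = NA_real_,
            anchor_pos = st$pos, anchor_column = st$column,
            anchor_kind = st$kind, region = st$region, short = NA,
            status = "rejected", reason = fit$reason,
            stringsAsFactors = FALSE)
        }
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genome = targetGenome, orientation = orient,
        sequence = fit$sequence, start = fit$start, end = fit$end,
        length = fit$length, tm_C = fit$tm_C,
        anchor_pos = st$pos, anchor_column = st$column,
        anchor_kind = st$kind, region = st$region, short = fit$short,
        status = "ok", reason = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .emptyCandidates()
  out <- filterCandidates(out, quality, keepRejected = keepRejected)
  # intron/junction anchors first, then by template coordinate
  pref <- ifelse(out$region == "EXON", 1L, 0L)
  out <- out[order(pref, out$anchor_pos, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyCandidates <- function() {
  data.frame(genome = character(), orientation = character(),
             sequence = character(), start = integer(), end = integer(),
             length = integer(), tm_C = numeric(), anchor_pos = integer(),
             anchor_column = integer(), anchor_kind = character(),
             region = character(), short = logical(), status = character(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Apply sequence-quality filters to primer candidates
#'
#' Retains candidates with GC fraction inside the configured window, no
#' single-base run longer than the homopolymer cap, no 3'-terminal
#' self-complementarity seed and no perfect self-dimer seed. Each
#' rejection carries a machine-readable reason
#' (`gc_out_of_range`, `homopolymer_run`,
#' `three_prime_self_complementarity`, `self_dimer_seed`). The filter is
#' idempotent.
#'
#' @param candidates data.frame as produced by
#'   [enumerateAnchoredCandidates()] (only `sequence` and `status` are
#'   required).
#' @param quality [qualityParams()].
#' @param keepRejected keep rejected rows (status = "rejected") instead
#'   of dropping them.
#' @return the filtered data.frame.
#' @export
filterCandidates <- function(candidates, quality = qualityParams(),
                             keepRejected = FALSE) {
  if (!nrow(candidates)) return(candidates)
  ok <- candidates$status == "ok"
  reason <- candidates$reason
  for (i in which(ok)) {
    r <- .qualityReason(candidates$sequence[i], quality)
    if (!is.na(r)) {
      ok[i] <- FALSE
      reason[i] <- r
    }
  }
  candidates$status <- ifelse(ok, "ok", "rejected")
  candidates$reason <- reason
  if (!keepRejected) candidates <- candidates[ok, , drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}
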