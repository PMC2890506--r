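#' In-silico PCR model parameters
#'
#' The amplification-class rules reconstruct how primer-template
#' mismatches near the 3' terminus govern extension: a 3'-terminal
#' mismatch blocks amplification, an internal mismatch within the
#' 3'-proximal window only weakens it (faint mismatch-PCR products can
#' still appear in the first cycles), and mismatches further 5' are
#' tolerated.
#'
#' @param maxMismatches maximum total mismatches for a reported binding
#'   site (more than this gives no amplification).
#' @param weakWindow 3'-proximal window (positions 2..weakWindow from the
#'   3' end) in which an internal mismatch downgrades amplification to
#'   WEAK.
#' @param maxProductBp largest product size considered amplifiable.
#' @return named list of class `PcrParams`.
#' @export
pcrParams <- function(maxMismatches = 3L, weakWindow = 5L,
                      maxProductBp = 3000L) {
  stopifnot(maxMismatches >= 0L, weakWindow >= 1L, maxProductBp > 0L)
  structure(list(maxMismatches = as.integer(maxMismatches),
                 weakWindow = as.integer(weakWindow),
                 maxProductBp = as.integer(maxProductBp)),
            class = "PcrParams")
}

#' Scan a template for mismatch-tolerant primer binding sites
#'
#' Finds every gapless alignment of the primer to either strand of the
#' template with at most `maxMismatches` mismatches (overlapping hits all
#' reported), via [Biostrings::matchPattern]. Mismatch positions are
#' reported counted from the primer 3' end (position 1 = 3'-terminal
#' base) — the coordinate the amplification-class rules are written in.
#'
#' Strand convention: a `+` hit means the primer sequence equals the
#' template top strand over the interval, so polymerase extension runs
#' rightward (the primer acts as a forward primer there); a `-` hit means
#' the primer's reverse complement equals the top strand and extension
#' runs leftward (reverse-primer geometry).
#'
#' @param primer primer 5'->3' (character or DNAString, ACGT only).
#' @param template ungapped template (character or DNAString).
#' @param maxMismatches mismatch tolerance (default from [pcrParams()]).
#' @return data.frame: `start`, `end` (1-based closed template interval),
#'   `strand`, `n_mismatch`, `mismatch_pos_3p` (comma-joined integers,
#'   "" if none), `gap_in_3prime_hexamer` (always FALSE in the gapless
#'   model; retained for report compatibility), `class` (STRONG/WEAK/
#'   NONE per [classifyPrimerBinding()]).
#' @export
scanBindingSites <- function(primer, template,
                             maxMismatches = pcrParams()$maxMismatches) {
  p <- toupper(as.character(primer))
  tpl <- Biostrings::DNAString(toupper(as.character(template)))
  L <- nchar(p)
  if (L > length(tpl)) return(.emptyProfiles())
  pd <- Biostrings::DNAString(p)
  prc <- Biostrings::reverseComplement(pd)
  tchars <- strsplit(as.character(tpl), "")[[1L]]
  pchars <- strsplit(p, "")[[1L]]
  rcchars <- strsplit(as.character(prc), "")[[1L]]
  rows <- list()
  collect <- function(hits, strand, qchars) {
    for (k in seq_along(hits)) {
      s <- IRanges::start(hits)[k]
      e <- IRanges::end(hits)[k]
      # matchPattern may report partial hits hanging off the template
      if (s < 1L || e > length(tpl)) next
      mm <- which(qchars != tchars[s:e])
      # qchars is primer 5'->3' on '+', revcomp(primer) on '-';
      # offset j in the revcomp comparison is position j from the 3' end
      pos3p <- if (strand == "+") L - mm + 1L else mm
      pos3p <- sort(pos3p)
      rows[[length(rows) + 1L]] <<- data.frame(
        start = s, end = e, strand = strand,
        n_mismatch = length(mm),
        mismatch_pos_3p = paste(pos3p, collapse = ","),
        gap_in_3prime_hexamer = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  collect(Biostrings::matchPattern(pd, tpl, max.mismatch = maxMismatches),
          "+", pchars)
  collect(Biostrings::matchPattern(prc, tpl, max.mismatch = maxMismatches),
          "-", rcchars)
  if (!length(rows)) return(.emptyProfiles())
  out <- do.call(rbind, rows)
  out$class <- vapply(seq_len(nrow(out)), function(i)
    classifyPrimerBinding(.parsePos(out$mismatch_pos_3p[i]),
                          gapIn3PrimeHexamer = out$gap_in_3prime_hexamer[i],
                          maxMismatches = maxMismatches),
    character(1))
  out[order(out$start, out$strand), , drop = FALSE]
}

.parsePos <- function(x) {
  if (!nzchar(x)) integer(0) else as.integer(strsplit(x, ",")[[1L]])
}

.emptyProfiles <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             n_mismatch = integer(), mismatch_pos_3p = character(),
             gap_in_3prime_hexamer = logical(), class = character(),
             stringsAsFactors = FALSE)
}

#' Classify a primer binding site as STRONG / WEAK / NONE
#'
#' Rule table: `NONE` if the 3'-terminal base (position 1) is mismatched,
#' a gap falls in the 3'-terminal hexamer, or the total mismatch count
#' exceeds the cap; `WEAK` if the 3' terminus matches but some mismatch
#' lies at positions 2..weakWindow from the 3' end (mismatch PCR can
#' still yield a faint product); `STRONG` otherwise (all mismatches, if
#' any, at positions beyond the window).
#'
#' @param mismatchPos3p integer vector of mismatch positions counted from
#'   the 3' end (1 = 3'-terminal base).
#' @param gapIn3PrimeHexamer logical flag.
#' @param maxMismatches total-mismatch cap.
#' @param weakWindow 3'-proximal window size.
#' @return one of `"STRONG"`, `"WEAK"`, `"NONE"`.
#' @examples
#' classifyPrimerBinding(integer(0))  # STRONG
#' classifyPrimerBinding(5L)          # WEAK
#' classifyPrimerBinding(1L)          # NONE
#' @export
classifyPrimerBinding <- function(mismatchPos3p,
                                  gapIn3PrimeHexamer = FALSE,
                                  maxMismatches = pcrParams()$maxMismatches,
                                  weakWindow = pcrParams()$weakWindow) {
  if (gapIn3PrimeHexamer) return("NONE")
  if (length(mismatchPos3p) > maxMismatches) return("NONE")
  if (any(mismatchPos3p == 1L)) return("NONE")
  if (any(mismatchPos3p >= 2L & mismatchPos3p <= weakWindow)) return("WEAK")
  "STRONG"
}

.CLASS_RANK <- c(NONE = 0L, WEAK = 1L, STRONG = 2L)

#' Predict PCR products of a primer pair on template sequences
#'
#' For every template, every compatible pair of binding sites — one
#' primer on the `+` strand, the other on the `-` strand, converging,
#' with product size at most `maxProductBp` — is reported as a predicted
#' amplicon. The product interval runs from the 5' end of the
#' plus-strand (forward-acting) site to the 5' end of the minus-strand
#' (reverse-acting) site, inclusive, so predicted sizes are directly
#' comparable to gel-called product sizes. The amplicon class is the
#' weaker of the two per-primer classes (NONE < WEAK < STRONG);
#' class-NONE amplicons are suppressed unless `keepNone`.
#'
#' @param fwd,rev primer sequences 5'->3'.
#' @param templates named character vector / DNAStringSet of templates.
#' @param params [pcrParams()].
#' @param keepNone keep class-NONE products in the output.
#' @return data.frame: `template`, `start`, `end` (1-based closed),
#'   `size_bp`, `class`, `fwd_primer` ("fwd"/"rev": which input primer
#'   acts forward), `fwd_mismatch_pos_3p`, `rev_mismatch_pos_3p`,
#'   `fwd_n_mismatch`, `rev_n_mismatch`.
#' @export
insilicoPCR <- function(fwd, rev, templates, params = pcrParams(),
                        keepNone = FALSE) {
  templates <- .asTemplateList(templates)
  out <- list()
  for (tn in names(templates)) {
    tpl <- templates[[tn]]
    fh <- scanBindingSites(fwd, tpl, params$maxMismatches)
    rh <- scanBindingSites(rev, tpl, params$maxMismatches)
    # (plus-strand site, minus-strand site) with plus start <= minus end
    combos <- list(list(fh[fh$strand == "+", , drop = FALSE],
                        rh[rh$strand == "-", , drop = FALSE], "fwd"),
                   list(rh[rh$strand == "+", , drop = FALSE],
                        fh[fh$strand == "-", , drop = FALSE], "rev"))
    for (cb in combos) {
      ph <- cb[[1L]]; mh <- cb[[2L]]
      if (!nrow(ph) || !nrow(mh)) next
      for (i in seq_len(nrow(ph))) for (j in seq_len(nrow(mh))) {
        s <- ph$start[i]; e <- mh$end[j]
        size <- e - s + 1L
        if (size < max(ph$end[i] - s + 1L, e - mh$start[j] + 1L)) next
        if (ph$end[i] > mh$start[j]) next  # 3' ends must converge
        if (size > params$maxProductBp) next
        cls <- names(.CLASS_RANK)[1L + min(.CLASS_RANK[ph$class[i]],
                                           .CLASS_RANK[mh$class[j]])]
        if (!keepNone && cls == "NONE") next
        fwdActs <- cb[[3L]] == "fwd"
        out[[length(out) + 1L]] <- data.frame(
          template = tn, start = s, end = e, size_bp = size, class = cls,
          fwd_primer = cb[[3L]],
          fwd_mismatch_pos_3p = if (fwdActs) ph$mismatch_pos_3p[i]
                                else mh$mismatch_pos_3p[j],
          rev_mismatch_pos_3p = if (fwdActs) mh$mismatch_pos_3p[j]
                                else ph$mismatch_pos_3p[i],
          fwd_n_mismatch = if (fwdActs) ph$n_mismatch[i] else mh$n_mismatch[j],
          rev_n_mismatch = if (fwdActs) mh$n_mismatch[j] else ph$n_mismatch[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(template = character(), start = integer(),
                      end = integer(), size_bp = integer(),
                      class = character(), fwd_primer = character(),
                      fwd_mismatch_pos_3p = character(),
                      rev_mismatch_pos_3p = character(),
                      fwd_n_mismatch = integer(),
                      rev_n_mismatch = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$template, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.asTemplateList <- function(templates) {
  if (methods::is(templates, "DNAStringSet") ||
      methods::is(templates, "DNAString"))
    templates <- as.character(templates)
  if (is.character(templates) && is.null(names(templates)))
    names(templates) <- paste0("template", seq_along(templates))
  if (methods::is(templates, "GeneCopy"))
    templates <- stats::setNames(as.character(templates@sequence),
                                 genomeId(templates))
  if (is.list(templates)) {
    templates <- vapply(templates, function(x) {
      if (methods::is(x, "GeneCopy")) as.character(x@sequence)
      else as.character(x)
    }, character(1))
  }
  as.list(toupper(templates))
}

#' Decide genome specificity of a primer pair
#'
#' A pair is genome-specific iff it yields exactly one STRONG product on
#' the target template and no STRONG-or-WEAK product on any off-target
#' template. Off-target WEAK products — the faint mismatch-PCR failure
#' mode of a pair whose discriminating mismatch sits internal to the 3'
#' window rather than at the terminus — disqualify the pair, and are
#' enumerated in the report.
#'
#' @param fwd,rev primer sequences 5'->3'.
#' @param target named single template (the genome the pair should
#'   amplify); a named character, DNAString or [GeneCopy-class].
#' @param offtargets templates of the other genomes (named vector/list).
#' @param params [pcrParams()].
#' @return list: `specific` (logical), `target_strong_n`,
#'   `target_amplicons` (data.frame), `offtarget_hits` (data.frame of all
#'   STRONG/WEAK off-target products, empty when specific).
#' @export
isGenomeSpecific <- function(fwd, rev, target, offtargets,
                             params = pcrParams()) {
  tgt <- .asTemplateList(target)
  if (length(tgt) != 1L) stop("exactly one target template is required")
  onT <- insilicoPCR(fwd, rev, tgt, params)
  offT <- insilicoPCR(fwd, rev, .asTemplateList(offtargets), params)
  offBad <- offT[offT$class %in% c("STRONG", "WEAK"), , drop = FALSE]
  strongN <- sum(onT$class == "STRONG")
  list(specific = strongN == 1L && nrow(offBad) == 0L,
       target_strong_n = strongN,
       target_amplicons = onT,
       offtarget_hits = offBad)
}
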