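#' Build a presence/absence diagnostic panel
#'
#' One genome-specific primer pair per locus, plus the mapping from
#' presence/absence patterns to genotype labels and numeric type codes.
#' For a three-locus panel (the waxy-gene case: loci on the A, B and D
#' subgenomes) the canonical eight-type code map is generated from the
#' locus names: all present = wild type (1); single nulls = 2, 3, 4 in
#' locus order; double nulls = 5, 6, 7; triple null = 8. The two double
#' null codes never observed in the source germplasm (5 and 6) are
#' marked `inferred`. For other panel sizes, only the all-present (1) and
#' all-absent pattern codes are pre-filled; unlisted patterns classify to
#' code `"other"` with locus-wise calls.
#'
#' If `reference` templates are supplied, every panel entry is checked to
#' amplify the wild-type reference ([predictPresence()] must be
#' "present"), otherwise construction fails — a panel that cannot detect
#' the wild type is invalid.
#'
#' @param entries data.frame with columns `locus`, `fwd_name`, `fwd_seq`,
#'   `rev_name`, `rev_seq` and optionally `expected_size_bp`.
#' @param codeMap optional custom map (data.frame `pattern`, `label`,
#'   `code`, `inferred`); overrides the generated one.
#' @param reference optional named list of wild-type templates, one per
#'   locus (names = locus labels).
#' @param params [pcrParams()].
#' @return a [DiagnosticPanel-class].
#' @export
diagnosticPanel <- function(entries, codeMap = NULL, reference = NULL,
                            params = pcrParams()) {
  if (!"expected_size_bp" %in% names(entries))
    entries$expected_size_bp <- NA_integer_
  if (is.null(codeMap)) codeMap <- .defaultCodeMap(entries$locus)
  panel <- methods::new("DiagnosticPanel", entries = entries,
                        codeMap = codeMap)
  if (!is.null(reference)) {
    for (i in seq_len(nrow(entries))) {
      loc <- entries$locus[i]
      tpl <- reference[[loc]]
      if (is.null(tpl))
        stop("no reference template for locus '", loc, "'")
      pres <- predictPresence(entries$fwd_seq[i], entries$rev_seq[i],
                              tpl, params)
      if (pres != "present")
        stop("panel entry for locus '", loc,
             "' fails to amplify the wild-type reference")
    }
  }
  panel
}

.defaultCodeMap <- function(loci) {
  k <- length(loci)
  # multi-locus null labels drop the shared locus-name prefix after the
  # first allele, the conventional shorthand (e.g. "null (Wx-A1b & B1b)")
  pre <- sub("^(.*-).*$", "\\1", loci[1L])
  sharedPrefix <- nzchar(pre) && all(startsWith(loci, pre))
  nullLab <- function(idx) {
    alleles <- paste0(loci[idx], "b")
    if (sharedPrefix && length(idx) > 1L)
      alleles[-1L] <- sub(pre, "", alleles[-1L], fixed = TRUE)
    paste0("null (", paste(alleles, collapse = " & "), ")")
  }
  if (k == 3L) {
    pats <- c("+++", "-++", "+-+", "++-", "+--", "-+-", "--+", "---")
    labs <- c("Wild type", nullLab(1L), nullLab(2L), nullLab(3L),
              nullLab(c(2L, 3L)), nullLab(c(1L, 3L)), nullLab(c(1L, 2L)),
              "Triple null alleles")
    data.frame(pattern = pats, label = labs, code = 1:8,
               inferred = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                            FALSE, FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pattern = c(strrep("+", k), strrep("-", k)),
               label = c("Wild type", "All-locus null"),
               code = c(1L, 2L^k),
               inferred = c(FALSE, TRUE),
               stringsAsFactors = FALSE)
  }
}

#' Predict presence/absence of a diagnostic product on an allele
#'
#' An allele scores "present" iff the pair yields at least one STRONG
#' product on it. Deletion-based null alleles lose the product because
#' the deletion removes or disrupts a primer site (or the whole gene);
#' faint mismatch-PCR products (class WEAK) are deliberately not counted
#' as presence, matching how diagnostic gels are scored.
#'
#' @param fwd,rev primer sequences 5'->3'.
#' @param allele allele genomic sequence (character, DNAString or
#'   [GeneCopy-class]); may be empty (whole-gene deletion).
#' @param params [pcrParams()].
#' @return `"present"` or `"absent"`.
#' @export
predictPresence <- function(fwd, rev, allele, params = pcrParams()) {
  tpl <- .asTemplateList(allele)
  if (nchar(tpl[[1L]]) == 0L) return("absent")
  amps <- insilicoPCR(fwd, rev, tpl, params)
  if (any(amps$class == "STRONG")) "present" else "absent"
}

#' Classify a presence/absence pattern into a genotype
#'
#' @param pattern character vector of `"+"`/`"-"` calls, one per panel
#'   locus (in panel order), or a single pattern string like `"-−+"`.
#' @param panel a [DiagnosticPanel-class].
#' @return list: `pattern` (string), `label`, `code` (integer or
#'   `"other"`), `inferred` (logical), `null_loci` (character vector of
#'   loci called null).
#' @export
classifyGenotype <- function(pattern, panel) {
  if (length(pattern) == 1L && nchar(pattern) > 1L)
    pattern <- strsplit(pattern, "")[[1L]]
  k <- nrow(panel@entries)
  if (length(pattern) != k)
    stop("pattern length ", length(pattern),
         " does not match panel with ", k, " loci")
  if (!all(pattern %in% c("+", "-")))
    stop("pattern entries must be '+' or '-'")
  pat <- paste(pattern, collapse = "")
  nullLoci <- panel@entries$locus[pattern == "-"]
  hit <- match(pat, panel@codeMap$pattern)
  if (is.na(hit)) {
    list(pattern = pat,
         label = if (length(nullLoci))
           paste0("null (", paste(paste0(nullLoci, "b"), collapse = " & "),
                  ")") else "Wild type",
         code = "other", inferred = TRUE, null_loci = nullLoci)
  } else {
    list(pattern = pat, label = panel@codeMap$label[hit],
         code = panel@codeMap$code[hit],
         inferred = panel@codeMap$inferred[hit], null_loci = nullLoci)
  }
}

#' Genotype allele sets against a diagnostic panel
#'
#' Runs [predictPresence()] for every panel locus on every sample and
#' classifies the resulting patterns. A sample is a named list mapping
#' locus label -> allele sequence for that locus (an empty sequence
#' encodes a whole-gene deletion).
#'
#' @param panel a [DiagnosticPanel-class].
#' @param samples named list of samples; each sample a named list/vector
#'   of allele sequences keyed by locus.
#' @param params [pcrParams()].
#' @return data.frame: `sample`, one `+`/`-` column per locus, `label`,
#'   `code`.
#' @export
typeAlleles <- function(panel, samples, params = pcrParams()) {
  loci <- panel@entries$locus
  rows <- lapply(names(samples), function(sn) {
    sample <- samples[[sn]]
    calls <- vapply(seq_along(loci), function(i) {
      allele <- sample[[loci[i]]]
      if (is.null(allele)) "-" else {
        if (predictPresence(panel@entries$fwd_seq[i],
                            panel@entries$rev_seq[i], allele,
                            params) == "present") "+" else "-"
      }
    }, character(1))
    cls <- classifyGenotype(calls, panel)
    out <- data.frame(sample = sn, stringsAsFactors = FALSE)
    for (i in seq_along(loci)) out[[loci[i]]] <- calls[i]
    out$label <- cls$label
    out$code <- as.character(cls$code)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

setMethod("show", "DiagnosticPanel", function(object) {
  cat(sprintf("DiagnosticPanel: %d loci (%s), %d coded patterns\n",
              nrow(object@entries),
              paste(object@entries$locus, collapse = ", "),
              nrow(object@codeMap)))
})
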