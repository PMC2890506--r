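#' Thermodynamic / reaction parameters for primer Tm calculation
#'
#' Defaults mirror a standard PCR mix for this assay family: 50 mM
#' monovalent cation, 1.5 mM Mg2+, 0.2 mM total dNTP, 0.6 uM of each
#' primer, and a target melting-temperature window of 59-61 degrees C.
#'
#' @param monovalent_mM monovalent cation concentration (mM).
#' @param divalent_mM divalent cation (Mg2+) concentration (mM).
#' @param dntp_mM total dNTP concentration (mM); chelates Mg2+ and is
#'   subtracted before the divalent correction.
#' @param primer_uM primer concentration (uM).
#' @param tm_min_C,tm_max_C accepted Tm window (degrees C).
#' @return a validated named list of class `ThermoParams`.
#' @export
thermoParams <- function(monovalent_mM = 50, divalent_mM = 1.5,
                         dntp_mM = 0.2, primer_uM = 0.6,
                         tm_min_C = 59, tm_max_C = 61) {
  stopifnot(tm_min_C < tm_max_C,
            monovalent_mM >= 0, divalent_mM >= 0, dntp_mM >= 0,
            primer_uM > 0)
  structure(list(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
                 dntp_mM = dntp_mM, primer_uM = primer_uM,
                 tm_min_C = tm_min_C, tm_max_C = tm_max_C),
            class = "ThermoParams")
}

# Unified nearest-neighbor stack parameters (duplex DNA, 1 M NaCl):
# dH in kcal/mol, dS in cal/(mol K), keyed by the 5'->3' top-strand
# dinucleotide. Initiation terms are per terminal base pair.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
.NN_INIT_DS <- c(GC = -2.8, AT = 4.1)
.GAS_R <- 1.9872  # cal/(mol K)

#' Primer melting temperature (nearest-neighbor model)
#'
#' Computes the duplex melting temperature of a primer against its
#' perfect complement using unified nearest-neighbor thermodynamics with
#' per-terminal initiation terms, an entropic monovalent-salt correction
#' of 0.368 * (N-1) * ln[Na+eq] and the divalent/dNTP monovalent
#' equivalence Na+eq = monovalent + 120 * sqrt(max(divalent - dNTP, 0))
#' (concentrations in mM). The primer (non-self-complementary oligo)
#' concentration enters as CT/4.
#'
#' @param primer primer sequence 5'->3' (character or DNAString), strictly
#'   over A,C,G,T, length >= 8. Ambiguous bases are rejected.
#' @param params a [thermoParams()] list.
#' @return melting temperature in degrees C (a single numeric).
#' @examples
#' meltingTemperature("GTAAGCTTGCGCCACTGC")
#' @export
meltingTemperature <- function(primer, params = thermoParams()) {
  s <- toupper(as.character(primer))
  if (nchar(s) < 8L) stop("primer must be at least 8 nt")
  ch <- strsplit(s, "")[[1L]]
  if (!all(ch %in% c("A", "C", "G", "T")))
    stop("primer contains ambiguous or non-DNA letters: ",
         paste(setdiff(unique(ch), c("A", "C", "G", "T")), collapse = ","))
  n <- length(ch)
  stacks <- paste0(ch[-n], ch[-1L])
  dH <- sum(.NN_DH[stacks])
  dS <- sum(.NN_DS[stacks])
  for (term in ch[c(1L, n)]) {
    cls <- if (term %in% c("G", "C")) "GC" else "AT"
    dH <- dH + .NN_INIT_DH[[cls]]
    dS <- dS + .NN_INIT_DS[[cls]]
  }
  naEq <- (params$monovalent_mM +
             120 * sqrt(max(params$divalent_mM - params$dntp_mM, 0))) / 1000
  if (naEq <= 0) stop("effective monovalent concentration must be positive")
  dS <- dS + 0.368 * (n - 1L) * log(naEq)
  ct <- params$primer_uM * 1e-6
  dH * 1000 / (dS + .GAS_R * log(ct / 4)) - 273.15
}

#' Fit a primer into the Tm window by editing its 5' terminus
#'
#' The 3'-terminal base stays fixed on the anchor position (the
#' discriminative site); the primer is grown base by base at the 5' end
#' until its melting temperature enters the target window. The shortest
#' length within `[lenMin, lenMax]` whose Tm lies in
#' `[tm_min_C, tm_max_C]` wins, which makes repeated calls
#' deterministic. Reverse-orientation primers are reverse-complemented
#' template substrings whose leftmost template base is the anchor.
#'
#' @param template target template sequence (character or DNAString),
#'   ungapped.
#' @param anchorPos 1-based template position of the fixed 3'-terminal
#'   base.
#' @param orientation `"forward"` (primer = template[anchorPos-L+1 ..
#'   anchorPos]) or `"reverse"` (primer = reverse complement of
#'   template[anchorPos .. anchorPos+L-1]).
#' @param params [thermoParams()].
#' @param lenMin,lenMax primer length window; the default floor of 16
#'   admits published 16-mers while lengths of 17-25 are typical, and
#'   accepted primers shorter than 17 are flagged in the result.
#' @return list with `status` ("ok" or "rejected"); when ok: `sequence`,
#'   `start`, `end` (template interval, 1-based closed), `length`,
#'   `tm_C`, `short` (TRUE if below 17 nt); when rejected: `reason` and
#'   `nearest_tm_C`, the achievable Tm closest to the window.
#' @export
adjustTmBy5Prime <- function(template, anchorPos,
                             orientation = c("forward", "reverse"),
                             params = thermoParams(),
                             lenMin = 16L, lenMax = 25L) {
  orientation <- match.arg(orientation)
  tpl <- toupper(as.character(template))
  n <- nchar(tpl)
  stopifnot(anchorPos >= 1L, anchorPos <= n, lenMin >= 8L, lenMin <= lenMax)
  nearest <- NA_real_
  for (L in lenMin:lenMax) {
    if (orientation == "forward") {
      s <- anchorPos - L + 1L; e <- anchorPos
      if (s < 1L) break
      primer <- substr(tpl, s, e)
    } else {
      s <- anchorPos; e <- anchorPos + L - 1L
      if (e > n) break
      primer <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(substr(tpl, s, e))))
    }
    if (grepl("[^ACGT]", primer)) next
    tm <- meltingTemperature(primer, params)
    if (is.na(nearest) ||
        .windowDistance(tm, params) < .windowDistance(nearest, params))
      nearest <- tm
    if (tm >= params$tm_min_C && tm <= params$tm_max_C) {
      return(list(status = "ok", sequence = primer, start = s, end = e,
                  length = L, tm_C = tm, short = L < 17L))
    }
  }
  list(status = "rejected", reason = "no_length_reaches_tm_window",
       nearest_tm_C = nearest)
}

.windowDistance <- function(tm, params) {
  if (is.na(tm)) return(Inf)
  if (tm < params$tm_min_C) params$tm_min_C - tm
  else if (tm > params$tm_max_C) tm - params$tm_max_C
  else 0
}
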