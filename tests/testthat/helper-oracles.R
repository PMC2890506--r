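# Independent oracle implementations used to pin the package's
# computations. These deliberately share no code with the package: the Tm
# oracle re-types the published unified NN table and loops base by base,
# the binding-site oracle slides over every offset of both strands, the
# union oracle counts a per-base bitmap, and the tiling oracle enumerates
# all subsets.

ORACLE_NN <- list(
  dh = c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
         CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
         GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
         TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9),
  ds = c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
         CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
         GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
         TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
)

oracleTm <- function(seq, monovalent_mM = 50, divalent_mM = 1.5,
                     dntp_mM = 0.2, primer_uM = 0.6) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  dh <- 0; ds <- 0
  for (i in seq_len(length(ch) - 1L)) {
    key <- paste0(ch[i], ch[i + 1L])
    dh <- dh + ORACLE_NN$dh[[key]]
    ds <- ds + ORACLE_NN$ds[[key]]
  }
  for (b in c(ch[1L], ch[length(ch)])) {
    if (b == "G" || b == "C") { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  na_eq <- (monovalent_mM + 120 * sqrt(max(divalent_mM - dntp_mM, 0))) / 1000
  ds <- ds + 0.368 * (length(ch) - 1L) * log(na_eq)
  dh * 1000 / (ds + 1.9872 * log(primer_uM * 1e-6 / 4)) - 273.15
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracleRevcomp <- function(seq) {
  paste(rev(DNA_COMP[strsplit(toupper(seq), "")[[1L]]]), collapse = "")
}

# all gapless alignments of the primer to either strand, <= maxMM
# mismatches, mismatch positions counted from the primer 3' end
oracleScan <- function(primer, template, maxMM) {
  p <- strsplit(toupper(primer), "")[[1L]]
  tch <- strsplit(toupper(template), "")[[1L]]
  L <- length(p)
  out <- list()
  for (s in seq_len(length(tch) - L + 1L)) {
    win <- tch[s:(s + L - 1L)]
    mmPlus <- which(p != win)
    if (length(mmPlus) <= maxMM) {
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = s + L - 1L, strand = "+",
        n_mismatch = length(mmPlus),
        mismatch_pos_3p = paste(sort(L - mmPlus + 1L), collapse = ","),
        stringsAsFactors = FALSE)
    }
    # '-' hit: primer anneals to the top strand; primer base k pairs with
    # template position s + L - k
    mmMinus <- integer(0)
    for (k in seq_len(L)) {
      if (DNA_COMP[[p[k]]] != win[L - k + 1L]) mmMinus <- c(mmMinus, k)
    }
    if (length(mmMinus) <= maxMM) {
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = s + L - 1L, strand = "-",
        n_mismatch = length(mmMinus),
        mismatch_pos_3p = paste(sort(L - mmMinus + 1L), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), n_mismatch = integer(),
                      mismatch_pos_3p = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), , drop = FALSE]
}

oracleClassify <- function(pos3p, maxMM = 3L, weakWindow = 5L) {
  if (length(pos3p) > maxMM) return("NONE")
  if (1L %in% pos3p) return("NONE")
  if (any(pos3p >= 2L & pos3p <= weakWindow)) return("WEAK")
  "STRONG"
}

# brute-force specificity oracle: apply the class rules to every
# converging (+,-) binding-site combination on every template
oracleSpecific <- function(fwd, rev, target, offtargets, maxMM = 3L,
                           maxProduct = 3000L) {
  classedProducts <- function(tpl) {
    fh <- oracleScan(fwd, tpl, maxMM)
    rh <- oracleScan(rev, tpl, maxMM)
    res <- character(0)
    for (cb in list(list(fh, rh), list(rh, fh))) {
      ph <- cb[[1L]][cb[[1L]]$strand == "+", , drop = FALSE]
      mh <- cb[[2L]][cb[[2L]]$strand == "-", , drop = FALSE]
      if (!nrow(ph) || !nrow(mh)) next
      for (i in seq_len(nrow(ph))) for (j in seq_len(nrow(mh))) {
        if (ph$end[i] > mh$start[j]) next
        if (mh$end[j] - ph$start[i] + 1L > maxProduct) next
        parse3p <- function(x) if (nzchar(x)) as.integer(
          strsplit(x, ",")[[1L]]) else integer(0)
        c1 <- oracleClassify(parse3p(ph$mismatch_pos_3p[i]), maxMM)
        c2 <- oracleClassify(parse3p(mh$mismatch_pos_3p[j]), maxMM)
        rank <- c(NONE = 0L, WEAK = 1L, STRONG = 2L)
        res <- c(res, names(rank)[1L + min(rank[c1], rank[c2])])
      }
    }
    res
  }
  onT <- classedProducts(target)
  offBad <- 0L
  for (tpl in offtargets) {
    offBad <- offBad + sum(classedProducts(tpl) != "NONE")
  }
  sum(onT == "STRONG") == 1L && offBad == 0L
}

oracleUnionBp <- function(starts, ends, L) {
  hit <- logical(L)
  for (i in seq_along(starts)) hit[starts[i]:ends[i]] <- TRUE
  sum(hit)
}

# exhaustive subset search: maximum attainable union, and the minimum
# subset size achieving it
oracleBestTiling <- function(starts, ends, L) {
  n <- length(starts)
  bestCover <- 0L
  minCount <- n
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    cov <- oracleUnionBp(starts[idx], ends[idx], L)
    if (cov > bestCover) {
      bestCover <- cov
      minCount <- length(idx)
    } else if (cov == bestCover && length(idx) < minCount) {
      minCount <- length(idx)
    }
  }
  list(cover = bestCover, count = minCount)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
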