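#' Parameters for simulating a homoeologous gene family
#'
#' The defaults emulate the divergence structure of homoeologous starch
#' genes in hexaploid wheat: three subgenome copies of a multi-exon gene
#' whose exons stay nearly identical while introns accumulate
#' substitutions and indels. Divergence values are *pairwise* target
#' substitution fractions between any two copies; each copy receives
#' half that divergence from the common ancestor, so the default intron
#' divergence of 0.25 realizes pairwise intron identities around 77%,
#' inside the empirically observed 65-85% band, and the default exon
#' divergence of 0.03 keeps exon identity above 95%. Indels are
#' restricted to introns, where they are usable for genome-specific
#' design without disturbing the reading frame.
#'
#' @param n_copies number of genome copies (default 3).
#' @param genome_ids labels, default `c("A","B","D")` (recycled/truncated
#'   to `n_copies`).
#' @param n_exons exon count; the default 11-exon / 10-intron structure
#'   mirrors the waxy gene architecture.
#' @param exon_length_range,intron_length_range inclusive sampling ranges
#'   (bp) for exon and intron lengths.
#' @param exon_divergence,intron_divergence target pairwise substitution
#'   fractions.
#' @param intron_indel_rate indel events per intron bp per copy.
#' @param indel_length_range inclusive range of indel lengths (bp).
#' @param seed integer RNG seed; identical params give identical output.
#' @return named list of class `SimulationParams`.
#' @export
simulationParams <- function(n_copies = 3L,
                             genome_ids = c("A", "B", "D"),
                             n_exons = 11L,
                             exon_length_range = c(100L, 200L),
                             intron_length_range = c(70L, 130L),
                             exon_divergence = 0.03,
                             intron_divergence = 0.25,
                             intron_indel_rate = 0.02,
                             indel_length_range = c(1L, 30L),
                             seed = 1L) {
  stopifnot(n_copies >= 2L, n_exons >= 1L,
            exon_divergence >= 0, exon_divergence <= 1,
            intron_divergence >= 0, intron_divergence <= 1,
            intron_indel_rate >= 0,
            indel_length_range[1L] >= 1L,
            indel_length_range[1L] <= indel_length_range[2L])
  if (length(genome_ids) < n_copies)
    genome_ids <- paste0("G", seq_len(n_copies))
  structure(list(n_copies = as.integer(n_copies),
                 genome_ids = genome_ids[seq_len(n_copies)],
                 n_exons = as.integer(n_exons),
                 exon_length_range = as.integer(exon_length_range),
                 intron_length_range = as.integer(intron_length_range),
                 exon_divergence = exon_divergence,
                 intron_divergence = intron_divergence,
                 intron_indel_rate = intron_indel_rate,
                 indel_length_range = as.integer(indel_length_range),
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

.sampleLen <- function(range, n) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

#' Simulate a homoeologous gene family with known ground truth
#'
#' Samples an ancestral gene (alternating exons and introns), then
#' derives each genome copy by region-specific substitution
#' (half the pairwise divergence per branch, uniform replacement base)
#' and intron-confined indels. Returns the copies, the true gapped
#' alignment, and the ground-truth list of fully discriminative columns
#' (computed by a direct per-column scan of the true alignment,
#' independent of [findDiscriminativeSites()]).
#'
#' @param params a [simulationParams()] list.
#' @return list with elements `copies` (named list of
#'   [GeneCopy-class]), `trueAlignment` (named character vector of
#'   gapped rows), `sites` (data.frame `target_genome`, `column`,
#'   `region` of every fully discriminative column), `ancestorRegions`
#'   (per-column EXON/INTRON label), `params`.
#' @examples
#' fam <- simulateFamily(simulationParams(seed = 42))
#' fam$copies[[1]]
#' @export
simulateFamily <- function(params = simulationParams()) {
  if (params$n_exons < 1L) stop("degenerate structure: need >= 1 exon")
  set.seed(params$seed)
  nE <- params$n_exons
  exLen <- .sampleLen(params$exon_length_range, nE)
  inLen <- if (nE > 1L) .sampleLen(params$intron_length_range, nE - 1L)
           else integer(0)
  pieces <- integer(0)
  isExon <- logical(0)
  for (i in seq_len(nE)) {
    pieces <- c(pieces, exLen[i]); isExon <- c(isExon, TRUE)
    if (i < nE) { pieces <- c(pieces, inLen[i]); isExon <- c(isExon, FALSE) }
  }
  L <- sum(pieces)
  region <- rep(ifelse(isExon, "EXON", "INTRON"), pieces)
  ends <- cumsum(pieces)
  starts <- ends - pieces + 1L
  exonAncestor <- IRanges::IRanges(starts[isExon], ends[isExon])
  bases <- c("A", "C", "G", "T")
  ancestor <- sample(bases, L, replace = TRUE)

  n <- params$n_copies
  branchEx <- params$exon_divergence / 2
  branchIn <- params$intron_divergence / 2
  copyChars <- vector("list", n)
  insAt <- vector("list", n)      # insAt[[i]][[j]]: string inserted after pos j-1
  for (i in seq_len(n)) {
    ch <- ancestor
    rate <- ifelse(region == "EXON", branchEx, branchIn)
    # position-wise pre-drawn randomness: at a fixed seed, raising a
    # divergence parameter adds substitution sites without reshuffling
    # the ones already present (common random numbers)
    u <- stats::runif(L)
    repl <- sample.int(3L, L, replace = TRUE)
    hit <- which(u < rate)
    for (p in hit) ch[p] <- setdiff(bases, ch[p])[repl[p]]
    # intron indels
    intronPos <- which(region == "INTRON")
    del <- rep(FALSE, L)
    ins <- rep("", L + 1L)
    nEvents <- stats::rbinom(1L, length(intronPos), params$intron_indel_rate)
    if (nEvents > 0L && length(intronPos)) {
      at <- sample(intronPos, nEvents, replace = TRUE)
      for (p in at) {
        len <- sample(params$indel_length_range[1L]:
                        params$indel_length_range[2L], 1L)
        if (stats::runif(1L) < 0.5) {
          # deletion: clip to the intron containing p
          run <- .intronRun(region, p)
          e <- min(p + len - 1L, run[2L])
          del[p:e] <- TRUE
        } else {
          ins[p + 1L] <- paste0(ins[p + 1L],
                                paste(sample(bases, len, replace = TRUE),
                                      collapse = ""))
        }
      }
    }
    ch[del] <- "-"
    copyChars[[i]] <- ch
    insAt[[i]] <- ins
  }
  # splice per-copy private insertion blocks into shared columns
  buf <- vector("list", n)
  for (i in seq_len(n)) buf[[i]] <- list()
  regOut <- list()
  for (j in 0L:L) {
    if (j >= 1L) {
      for (ii in seq_len(n))
        buf[[ii]][[length(buf[[ii]]) + 1L]] <- copyChars[[ii]][j]
      regOut[[length(regOut) + 1L]] <- region[j]
    }
    # insert blocks keyed j + 1 sit between ancestor positions j and j + 1
    for (i in seq_len(n)) {
      w <- nchar(insAt[[i]][j + 1L])
      if (w > 0L) {
        for (ii in seq_len(n)) {
          buf[[ii]][[length(buf[[ii]]) + 1L]] <-
            if (ii == i) insAt[[i]][j + 1L] else strrep("-", w)
        }
        regOut[[length(regOut) + 1L]] <- rep("INTRON", w)
      }
    }
  }
  rows <- vapply(buf, function(x) paste0(unlist(x), collapse = ""),
                 character(1))
  names(rows) <- params$genome_ids
  colRegion <- unlist(regOut)

  # per-copy GeneCopy with exon intervals mapped through the alignment
  rowMat <- do.call(rbind, strsplit(rows, ""))
  copies <- list()
  for (i in seq_len(n)) {
    ungapped <- rowMat[i, ] != "-"
    posOfCol <- cumsum(ungapped)
    seq_i <- paste0(rowMat[i, ungapped], collapse = "")
    exCols <- which(colRegion == "EXON")  # exon columns are never gapped
    # contiguous exon blocks in column space -> copy coordinates
    blocks <- split(exCols, cumsum(c(1L, diff(exCols) != 1L)))
    exIR <- IRanges::IRanges(
      start = vapply(blocks, function(b) posOfCol[b[1L]], integer(1)),
      end = vapply(blocks, function(b) posOfCol[b[length(b)]], integer(1)))
    copies[[params$genome_ids[i]]] <-
      geneCopy(params$genome_ids[i], seq_i, exIR,
               sourceId = sprintf("simulated:seed%d", params$seed))
  }

  # ground truth: direct scan for fully discriminative columns
  sites <- list()
  for (i in seq_len(n)) {
    tb <- rowMat[i, ]
    ob <- rowMat[-i, , drop = FALSE]
    full <- tb != "-" & tb != "N" &
      colSums(ob == "N") == 0L &
      colSums(sweep(ob, 2L, tb, FUN = "!=")) == (n - 1L)
    w <- which(full)
    if (length(w)) {
      sites[[length(sites) + 1L]] <- data.frame(
        target_genome = params$genome_ids[i], column = w,
        region = colRegion[w], stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(target_genome = character(), column = integer(),
               region = character(), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  list(copies = copies, trueAlignment = rows, sites = sites,
       ancestorRegions = colRegion, params = params)
}

.intronRun <- function(region, p) {
  s <- p
  while (s > 1L && region[s - 1L] == "INTRON") s <- s - 1L
  e <- p
  while (e < length(region) && region[e + 1L] == "INTRON") e <- e + 1L
  c(s, e)
}

#' Derive a deletion-based null allele from a gene copy
#'
#' Reproduces the three deletion mechanisms behind non-amplifying (null)
#' alleles: loss of an intron (removing an intron-anchored primer site),
#' loss of a terminal or internal exon, or loss of the entire gene. The
#' excised allele has its exon structure re-indexed; a whole-gene
#' deletion returns an empty-sequence sentinel copy.
#'
#' @param copy a [GeneCopy-class].
#' @param mode `"intron_deletion"`, `"exon_deletion"` or
#'   `"whole_gene_deletion"`.
#' @param index 1-based intron or exon index for the partial modes.
#' @return a [GeneCopy-class] (empty sequence for whole-gene deletion).
#' @export
simulateNullAllele <- function(copy,
                               mode = c("intron_deletion", "exon_deletion",
                                        "whole_gene_deletion"),
                               index = 1L) {
  mode <- match.arg(mode)
  if (mode == "whole_gene_deletion") {
    return(methods::new("GeneCopy", genomeId = genomeId(copy),
                        sequence = Biostrings::DNAString(""),
                        exons = IRanges::IRanges(),
                        sourceId = paste0(sourceId(copy),
                                          ":whole_gene_deletion")))
  }
  iv <- if (mode == "intron_deletion") introns(copy) else exons(copy)
  if (index < 1L || index > length(iv))
    stop(mode, ": index ", index, " out of range (1..", length(iv), ")")
  s <- IRanges::start(iv)[index]
  e <- IRanges::end(iv)[index]
  seq <- as.character(copy@sequence)
  newSeq <- paste0(substr(seq, 1L, s - 1L),
                   substr(seq, e + 1L, nchar(seq)))
  w <- e - s + 1L
  ex <- exons(copy)
  if (mode == "exon_deletion") ex <- ex[-index]
  ns <- IRanges::start(ex); ne <- IRanges::end(ex)
  shift <- ns > e
  ns[shift] <- ns[shift] - w; ne[shift] <- ne[shift] - w
  geneCopy(genomeId(copy), newSeq, IRanges::IRanges(ns, ne),
           sourceId = paste0(sourceId(copy), ":", mode, index))
}

#' Write a simulated family to disk (FASTA + GFF3 + truth)
#'
#' Writes `family.fasta`, `family.gff3`, the true alignment as
#' `family.aln.fasta` and the ground-truth site list plus parameters as
#' `family.truth.json`. Output is byte-stable for fixed parameters.
#'
#' @param fam result of [simulateFamily()].
#' @param dir output directory.
#' @return invisibly, the vector of file paths.
#' @export
writeSimulatedFamily <- function(fam, dir) {
  paths <- writeGeneFamily(fam$copies, dir)
  alnPath <- file.path(dir, "family.aln.fasta")
  aln <- Biostrings::DNAStringSet(fam$trueAlignment)
  Biostrings::writeXStringSet(aln, alnPath, width = 70L)
  truthPath <- file.path(dir, "family.truth.json")
  jsonlite::write_json(
    list(params = unclass(fam$params), sites = fam$sites),
    truthPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, aln = alnPath, truth = truthPath))
}
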