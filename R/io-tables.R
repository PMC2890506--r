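#' Read a primer table (published-table dialect)
#'
#' Reads a tab-separated primer table in the layout of published
#' genome-specific primer tables: columns `name`, `sequence`, `tm_c`,
#' `size_bp`, `genome`, one row per primer, where each forward primer row
#' (annealing temperature / size / genome left blank) is immediately
#' followed by its reverse partner carrying the pair's annotation.
#' Alternatively a fully explicit dialect with columns `pair`,
#' `fwd_name`, `fwd_seq`, `rev_name`, `rev_seq`, `genome`[, `size_bp`] is
#' accepted as-is.
#'
#' @param path TSV path (optionally gzipped). Lines starting `#` are
#'   comments.
#' @return data.frame in the explicit pair dialect (one row per pair).
#' @export
readPrimerTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (all(c("fwd_seq", "rev_seq") %in% names(df))) {
    if (!"pair" %in% names(df))
      df$pair <- paste(df$fwd_name, df$rev_name, sep = "/")
    return(df)
  }
  need <- c("name", "sequence")
  if (!all(need %in% names(df)))
    stop("unrecognized primer table dialect: need columns ",
         paste(need, collapse = ", "))
  if (nrow(df) %% 2L != 0L)
    stop("primer rows must come in forward/reverse pairs")
  fi <- seq(1L, nrow(df), by = 2L)
  ri <- fi + 1L
  out <- data.frame(
    pair = paste(df$name[fi], df$name[ri], sep = "/"),
    fwd_name = df$name[fi], fwd_seq = toupper(df$sequence[fi]),
    rev_name = df$name[ri], rev_seq = toupper(df$sequence[ri]),
    genome = if ("genome" %in% names(df)) df$genome[ri] else NA_character_,
    stringsAsFactors = FALSE)
  if ("size_bp" %in% names(df)) out$size_bp <- as.integer(df$size_bp[ri])
  if ("tm_c" %in% names(df)) out$annealing_C <- as.numeric(df$tm_c[ri])
  out
}

#' Write chosen primer pairs as a published-table-style TSV
#'
#' One row per primer (forward then reverse), with the pair's annealing
#' temperature, product size and genome on the reverse row — the layout
#' of conventional primer tables. Coordinates are 1-based inclusive.
#'
#' @param solutions list of [TilingSolution-class] or a single solution.
#' @param path output TSV path.
#' @param annealing_C annealing temperature to print (default 60).
#' @return invisibly, `path`.
#' @export
writePrimerTable <- function(solutions, path, annealing_C = 60) {
  if (methods::is(solutions, "TilingSolution")) solutions <- list(solutions)
  rows <- list()
  for (sol in solutions) {
    prs <- chosenPairs(sol)
    for (i in seq_len(nrow(prs))) {
      nm <- sprintf("%s-set%d", genomeId(sol), i)
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(nm, "-F"), sequence = prs$fwd_seq[i],
        tm_c = "", size_bp = "", genome = "",
        template_start = prs$fwd_start[i], template_end = prs$fwd_end[i],
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(nm, "-R"), sequence = prs$rev_seq[i],
        tm_c = annealing_C, size_bp = prs$size_bp[i],
        genome = genomeId(sol),
        template_start = prs$rev_start[i], template_end = prs$rev_end[i],
        stringsAsFactors = FALSE)
    }
  }
  hdr <- "# primer table; coordinates 1-based inclusive on the target template"
  con <- file(path, "w")
  writeLines(hdr, con)
  if (length(rows)) {
    utils::write.table(do.call(rbind, rows), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    writeLines(paste(c("name", "sequence", "tm_c", "size_bp", "genome",
                       "template_start", "template_end"), collapse = "\t"),
               con)
  }
  close(con)
  invisible(path)
}

#' Write predicted amplicons as BED
#'
#' BED intervals are 0-based half-open (the conversion from the package's
#' 1-based closed coordinates is done by the exporter); the score column
#' encodes the amplification class (NONE 0, WEAK 500, STRONG 1000).
#'
#' @param amplicons data.frame from [insilicoPCR()] or the `pairs` slot
#'   of a [TilingSolution-class] (needs `template`/`genome`, `start`/
#'   `amplicon_start`, `end`/`amplicon_end`, optionally `class`).
#' @param path output BED path.
#' @return invisibly, `path`.
#' @export
writeAmpliconBED <- function(amplicons, path) {
  seqn <- if ("template" %in% names(amplicons)) amplicons$template
          else amplicons$genome
  s <- if ("start" %in% names(amplicons)) amplicons$start
       else amplicons$amplicon_start
  e <- if ("end" %in% names(amplicons)) amplicons$end
       else amplicons$amplicon_end
  cls <- if ("class" %in% names(amplicons)) amplicons$class
         else rep("STRONG", nrow(amplicons))
  if (!nrow(amplicons)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqn, ranges = IRanges::IRanges(start = s, end = e),
    score = c(NONE = 0L, WEAK = 500L, STRONG = 1000L)[cls],
    name = sprintf("amplicon%02d", seq_len(nrow(amplicons))))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write the per-genome coverage table as TSV
#'
#' @param coverage data.frame from [coverageReport()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeCoverageTSV <- function(coverage, path) {
  con <- file(path, "w")
  writeLines("# union coverage of chosen amplicons per genome", con)
  utils::write.table(coverage, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write all outputs of a design run
#'
#' Writes the primer table (TSV), chosen amplicons (BED), coverage table
#' (TSV) and a JSON run report with per-stage counts into `dir`.
#'
#' @param result list returned by [designPrimers()].
#' @param dir output directory (created if missing).
#' @return invisibly, named vector of file paths.
#' @export
writeDesignOutputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  primerPath <- file.path(dir, "primers.tsv")
  writePrimerTable(result$solutions, primerPath)
  amps <- do.call(rbind, lapply(result$solutions, function(sol) {
    prs <- chosenPairs(sol)
    if (!nrow(prs)) return(NULL)
    data.frame(genome = genomeId(sol), amplicon_start = prs$amplicon_start,
               amplicon_end = prs$amplicon_end, class = "STRONG",
               stringsAsFactors = FALSE)
  }))
  bedPath <- file.path(dir, "amplicons.bed")
  writeAmpliconBED(if (is.null(amps)) .emptyPairs()[0, ] else amps, bedPath)
  covPath <- file.path(dir, "coverage.tsv")
  writeCoverageTSV(result$coverage, covPath)
  reportPath <- file.path(dir, "report.json")
  report <- list(
    genomes = names(result$solutions),
    stage_counts = lapply(stats::setNames(names(result$solutions),
                                          names(result$solutions)),
                          function(g) list(
                            sites = nrow(result$sites[[g]]),
                            candidates = nrow(result$candidates[[g]]),
                            specific_pairs = nrow(result$pairs[[g]]),
                            tiled_pairs = nrow(chosenPairs(
                              result$solutions[[g]])))),
    coverage = result$coverage,
    seed = result$config$seed)
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(primers = primerPath, bed = bedPath, coverage = covPath,
              report = reportPath))
}
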