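test_that("identical homoeologs produce no candidates", {
  s <- randomDNA(300)
  aln <- toyAlignment(c(A = s, B = s, C = s))
  sites <- findDiscriminativeSites(aln, "A")
  cand <- enumerateAnchoredCandidates(aln, "A", sites)
  expect_equal(nrow(cand), 0L)
})

test_that("anchors near a template edge keep only the feasible orientation", {
  set.seed(21)
  base <- randomDNA(60)
  mkTrio <- function(col, tBase, oBase) {
    rowA <- base; substr(rowA, col, col) <- tBase
    rowB <- base; substr(rowB, col, col) <- oBase
    c(A = rowA, B = rowB, C = rowB)
  }
  # a relaxed Tm window so short toy templates can host primers
  loose <- thermoParams(tm_min_C = 40, tm_max_C = 80)
  # anchor 10 bp from the left edge: a forward primer would need to
  # extend past position 1, so only the reverse candidate survives
  alnL <- toyAlignment(mkTrio(10, "A", "G"))
  sitesL <- findDiscriminativeSites(alnL, "A")
  candL <- enumerateAnchoredCandidates(alnL, "A", sitesL, thermo = loose)
  expect_identical(unique(candL$orientation), "reverse")
  # anchor 10 bp from the right edge: only the forward candidate fits
  alnR <- toyAlignment(mkTrio(51, "A", "G"))
  sitesR <- findDiscriminativeSites(alnR, "A")
  candR <- enumerateAnchoredCandidates(alnR, "A", sitesR, thermo = loose)
  expect_identical(unique(candR$orientation), "forward")
  # both candidates match the brute-force template substring
  expect_identical(candR$sequence,
                   substr(gsub("-", "", mkTrio(51, "A", "G")[["A"]]),
                          candR$start, candR$end))
})

test_that("simulated families yield a usable candidate pool", {
  fam <- defaultFamily()
  aln <- buildAlignment(fam$copies, precomputed = fam$trueAlignment)
  sites <- findDiscriminativeSites(aln, "A")
  expect_gt(nrow(sites[sites$kind == "SNP", ]), 50L)
  cand <- enumerateAnchoredCandidates(aln, "A", sites)
  expect_gte(nrow(cand), 20L)
  expect_true(all(cand$status == "ok"))
  expect_true(all(cand$tm_C >= 59 & cand$tm_C <= 61))
  expect_false(any(grepl("[-N]", cand$sequence)))
  # re-check anchoring independently of site discovery: the 3' base of
  # every candidate differs from both off-target residues at its column
  rows <- alignmentRows(aln)
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- names(rows)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(cand))) {
    col <- cand$anchor_column[i]
    tb <- mat["A", col]
    ob <- mat[c("B", "D"), col]
    expect_true(all(ob != tb))
    last <- substr(cand$sequence[i], cand$length[i], cand$length[i])
    if (cand$orientation[i] == "forward") expect_identical(last, unname(tb))
    else expect_identical(last, unname(comp[tb]))
  }
})

test_that("quality filters reject by reason and are idempotent", {
  mk <- function(seq) data.frame(
    genome = "A", orientation = "forward", sequence = seq,
    start = 1L, end = nchar(seq), length = nchar(seq), tm_C = 60,
    anchor_pos = nchar(seq), anchor_column = nchar(seq),
    anchor_kind = "SNP", region = "INTRON", short = FALSE,
    status = "ok", reason = NA_character_, stringsAsFactors = FALSE)
  homo <- filterCandidates(mk("AAAAAAAAAAAAAAAAA"), keepRejected = TRUE)
  expect_identical(homo$status, "rejected")
  expect_true(homo$reason %in% c("gc_out_of_range", "homopolymer_run"))
  # 5 G/C in 17 nt = 0.294, just under the floor
  lowGC <- filterCandidates(mk("ATTAGTATCGATATCGA"), keepRejected = TRUE)
  expect_identical(lowGC$reason, "gc_out_of_range")
  run6 <- filterCandidates(mk("ACGTACCCCCCGTACGT"), keepRejected = TRUE)
  expect_identical(run6$reason, "homopolymer_run")
  # reverse-complement of the 3' pentamer planted upstream
  dimer <- filterCandidates(mk("TGCAGGATCTAGATCCTGCA"),
                            keepRejected = TRUE)
  expect_identical(dimer$status, "rejected")
  good <- mk("TCAACAACACCCAGCAGCTA")
  once <- filterCandidates(good)
  twice <- filterCandidates(once)
  expect_identical(once, twice)
  expect_identical(once$status, "ok")
})

test_that("all published primers pass the default quality filters", {
  panel <- printedPrimerPanel()
  primers <- c(panel$fwd_seq, panel$rev_seq)
  expect_equal(length(primers), 42L)
  reasons <- vapply(primers, function(p)
    PolyPrime:::.qualityReason(p, qualityParams()), character(1))
  expect_true(all(is.na(reasons)))
})
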