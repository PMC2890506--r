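pairwiseIdentity <- function(rowX, rowY, cols) {
  x <- strsplit(rowX, "")[[1L]][cols]
  y <- strsplit(rowY, "")[[1L]][cols]
  keep <- x != "-" & y != "-"
  sum(x[keep] == y[keep]) / sum(keep)
}

test_that("simulation is seed deterministic down to the written bytes", {
  p <- simulationParams(seed = 123, n_exons = 4L)
  f1 <- simulateFamily(p)
  f2 <- simulateFamily(p)
  expect_identical(f1$trueAlignment, f2$trueAlignment)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulatedFamily(f1, d1)
  writeSimulatedFamily(f2, d2)
  for (f in c("family.fasta", "family.gff3", "family.aln.fasta")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  f3 <- simulateFamily(simulationParams(seed = 124, n_exons = 4L))
  expect_false(identical(f1$trueAlignment, f3$trueAlignment))
})

test_that("zero divergence gives identical copies and no planted sites", {
  fam <- simulateFamily(simulationParams(seed = 8, n_exons = 3L,
                                         exon_divergence = 0,
                                         intron_divergence = 0,
                                         intron_indel_rate = 0))
  seqs <- vapply(fam$copies, function(x) as.character(x@sequence),
                 character(1))
  expect_equal(length(unique(seqs)), 1L)
  expect_equal(nrow(fam$sites), 0L)
  expect_error(simulateFamily(simulationParams(n_exons = 0L)))
})

test_that("realized divergence lands in the intended bands", {
  fam <- defaultFamily()
  rows <- fam$trueAlignment
  exCols <- which(fam$ancestorRegions == "EXON")
  inCols <- which(fam$ancestorRegions == "INTRON")
  combos <- combn(names(rows), 2)
  for (k in seq_len(ncol(combos))) {
    exId <- pairwiseIdentity(rows[[combos[1, k]]], rows[[combos[2, k]]],
                             exCols)
    inId <- pairwiseIdentity(rows[[combos[1, k]]], rows[[combos[2, k]]],
                             inCols)
    # exon identity: binomial band around 1 - exon_divergence
    expect_gt(exId, 0.97 - 0.015)
    expect_lt(exId, 0.97 + 0.015 + 0.008)  # + coincident-hit correction
    expect_gt(exId, 0.95)                  # stays in the ">95%" regime
    # intron identity brackets the empirical homoeolog band
    expect_gt(inId, 0.65)
    expect_lt(inId, 0.85)
  }
})

test_that("site discovery recovers nearly all planted sites", {
  recovered <- total <- 0
  for (seed in 1:20) {
    fam <- simulateFamily(simulationParams(seed = seed, n_exons = 4L))
    aln <- buildAlignment(fam$copies, precomputed = fam$trueAlignment)
    for (g in names(fam$copies)) {
      planted <- fam$sites$column[fam$sites$target_genome == g]
      got <- findDiscriminativeSites(
        aln, g, regions = c("EXON", "INTRON", "JUNCTION"))$column
      recovered <- recovered + length(intersect(planted, got))
      total <- total + length(planted)
    }
  }
  expect_gt(total, 0)
  expect_gte(recovered / total, 0.95)
})

test_that("the end-to-end pipeline designs specific, covering sets", {
  fam <- defaultFamily()
  res <- defaultDesign()
  for (g in names(fam$copies)) {
    prs <- chosenPairs(res$solutions[[g]])
    expect_gte(nrow(prs), 1L)
    expect_gt(coverageFraction(res$solutions[[g]]), 0)
    offs <- fam$copies[setdiff(names(fam$copies), g)]
    for (i in seq_len(nrow(prs))) {
      v <- isGenomeSpecific(prs$fwd_seq[i], prs$rev_seq[i],
                            fam$copies[g], offs)
      expect_true(v$specific)
    }
  }
  # coverage table is consistent with the solutions
  cov <- res$coverage
  expect_setequal(cov$genome, names(fam$copies))
  expect_true(all(cov$coverage_fraction > 0 & cov$coverage_fraction <= 1))
})
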