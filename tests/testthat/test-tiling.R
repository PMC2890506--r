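test_that("staggered amplicons tile with union coverage", {
  pairs <- fakePairs(c(1L, 801L, 1701L), c(950L, 1838L, 2450L))
  sol <- tileGene(pairs, geneLength = 2781L)
  expect_equal(coveredBp(sol), 2450L)
  expect_equal(nrow(chosenPairs(sol)), 3L)
  expect_equal(sol@junctionOverlaps, c(150L, 138L))
  expect_equal(coverageFraction(sol), 2450 / 2781)
  # single pair
  one <- tileGene(fakePairs(101L, 1050L), geneLength = 2000L)
  expect_equal(coveredBp(one), 950L)
  expect_equal(coverageFraction(one), 950 / 2000)
  # empty input
  none <- tileGene(fakePairs(integer(0), integer(0)), geneLength = 2000L)
  expect_equal(coveredBp(none), 0L)
  expect_equal(nrow(chosenPairs(none)), 0L)
})

test_that("union coverage equals a per-base bitmap oracle", {
  set.seed(55)
  for (trial in 1:50) {
    n <- sample(1:10, 1)
    starts <- sample(1:1500, n)
    ends <- pmin(starts + sample(200:900, n, replace = TRUE), 2000L)
    sol <- tileGene(fakePairs(starts, ends), geneLength = 2000L)
    prs <- chosenPairs(sol)
    expect_equal(coveredBp(sol),
                 oracleUnionBp(prs$amplicon_start, prs$amplicon_end, 2000L))
  }
})

test_that("the optimizer matches exhaustive subset search on small instances", {
  set.seed(1234)
  for (trial in 1:50) {
    n <- sample(3:12, 1)
    starts <- sample(1:1200, n)
    ends <- pmin(starts + sample(150:800, n, replace = TRUE), 2000L)
    sol <- tileGene(fakePairs(starts, ends,
                              margin = sample(1:5, n, replace = TRUE)),
                    geneLength = 2000L)
    best <- oracleBestTiling(starts, ends, 2000L)
    expect_equal(coveredBp(sol), best$cover)
    expect_equal(nrow(chosenPairs(sol)), best$count)
  }
})

test_that("adding a candidate pair never decreases coverage", {
  set.seed(321)
  for (trial in 1:20) {
    n <- sample(2:8, 1)
    starts <- sample(1:1200, n + 1L)
    ends <- pmin(starts + sample(150:700, n + 1L, replace = TRUE), 2000L)
    without <- tileGene(fakePairs(starts[1:n], ends[1:n]), 2000L)
    with <- tileGene(fakePairs(starts, ends), 2000L)
    expect_gte(coveredBp(with), coveredBp(without))
  }
})

test_that("tiling is deterministic and order independent", {
  set.seed(9)
  starts <- sample(1:1200, 8)
  ends <- pmin(starts + sample(300:900, 8, replace = TRUE), 2000L)
  margins <- sample(1:4, 8, replace = TRUE)
  p1 <- fakePairs(starts, ends, margins)
  shuffle <- sample(8)
  p2 <- p1[shuffle, ]
  s1 <- tileGene(p1, 2000L)
  s2 <- tileGene(p2, 2000L)
  prs1 <- chosenPairs(s1); prs2 <- chosenPairs(s2)
  rownames(prs1) <- rownames(prs2) <- NULL
  expect_identical(prs1, prs2)
})

test_that("specific pairs exist only where discrimination exists", {
  s <- randomDNA(400)
  aln <- toyAlignment(c(A = s, B = s, C = s))
  cand <- enumerateAnchoredCandidates(
    aln, "A", findDiscriminativeSites(aln, "A"))
  pairs <- enumerateSpecificPairs(cand, c(A = s), c(B = s, C = s))
  expect_equal(nrow(pairs), 0L)
})

test_that("planted distant anchors give pairs spanning them", {
  set.seed(64)
  base <- randomDNA(1200)
  mut <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  # plant discriminative columns ~900 bp apart; off-targets share a
  # different base so the sites are fully discriminative for A
  rowA <- base
  rowB <- mut(mut(base, 150, "G"), 1050, "T")
  rowC <- rowB
  rowA <- mut(mut(rowA, 150, "A"), 1050, "C")
  aln <- toyAlignment(c(A = rowA, B = rowB, C = rowC))
  sites <- findDiscriminativeSites(aln, "A")
  expect_setequal(sites$column, c(150L, 1050L))
  loose <- thermoParams(tm_min_C = 45, tm_max_C = 75)
  cand <- enumerateAnchoredCandidates(aln, "A", sites, thermo = loose)
  pairs <- enumerateSpecificPairs(
    cand, c(A = gsub("-", "", rowA)),
    c(B = gsub("-", "", rowB), C = gsub("-", "", rowC)))
  expect_gt(nrow(pairs), 0L)
  # every pair anchors the forward primer at 150 and the reverse at 1050
  expect_true(all(pairs$fwd_anchor_pos == 150L &
                    pairs$rev_anchor_pos == 1050L))
  # product spans 5' end of the forward primer to 5' end of the reverse
  expect_identical(pairs$amplicon_start, pairs$fwd_start)
  expect_identical(pairs$amplicon_end, pairs$rev_end)
  expect_identical(pairs$size_bp, pairs$rev_end - pairs$fwd_start + 1L)
})
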