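test_that("exact and planted-mismatch binding sites are reported", {
  set.seed(5)
  tpl <- randomDNA(300)
  primer <- substr(tpl, 101, 118)
  hits <- scanBindingSites(primer, tpl, maxMismatches = 0)
  plus <- hits[hits$strand == "+", ]
  expect_true(nrow(plus) >= 1L)
  expect_true(any(plus$start == 101 & plus$end == 118 &
                    plus$n_mismatch == 0))
  # flip the 3'-terminal base: one mismatch at position 1 from the 3' end
  flipped <- primer
  last <- substr(flipped, 18, 18)
  substr(flipped, 18, 18) <- setdiff(c("A", "C", "G", "T"), last)[1L]
  hits1 <- scanBindingSites(flipped, tpl, maxMismatches = 1)
  h <- hits1[hits1$start == 101 & hits1$strand == "+", ]
  expect_identical(h$mismatch_pos_3p, "1")
  expect_identical(h$class, "NONE")
  # primer longer than template
  expect_equal(nrow(scanBindingSites(randomDNA(30), "ACGT")), 0L)
})

test_that("binding-site scan equals the brute-force oracle", {
  set.seed(600)
  for (trial in 1:100) {
    tpl <- randomDNA(500)
    # half the trials embed a mutated copy of a template substring so
    # near-matches exist; the rest use unrelated primers
    if (trial %% 2 == 0) {
      s <- sample(1:(500 - 18), 1)
      primer <- substr(tpl, s, s + 17)
      nmut <- sample(0:3, 1)
      for (p in sample(1:18, nmut)) {
        old <- substr(primer, p, p)
        substr(primer, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    } else {
      primer <- randomDNA(18)
    }
    got <- scanBindingSites(primer, tpl, maxMismatches = 3)
    want <- oracleScan(primer, tpl, maxMM = 3)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      key <- function(d) paste(d$start, d$strand, d$n_mismatch,
                               d$mismatch_pos_3p)
      expect_setequal(key(got), key(want))
    }
  }
})

test_that("the amplification class rule table holds", {
  expect_identical(classifyPrimerBinding(integer(0)), "STRONG")
  expect_identical(classifyPrimerBinding(c(9L, 14L)), "STRONG")
  expect_identical(classifyPrimerBinding(6L), "STRONG")
  expect_identical(classifyPrimerBinding(2L), "WEAK")
  expect_identical(classifyPrimerBinding(5L), "WEAK")
  expect_identical(classifyPrimerBinding(1L), "NONE")
  expect_identical(classifyPrimerBinding(c(1L, 9L)), "NONE")
  expect_identical(classifyPrimerBinding(c(6L, 9L, 12L, 15L)), "NONE")
  expect_identical(classifyPrimerBinding(integer(0),
                                         gapIn3PrimeHexamer = TRUE), "NONE")
})

test_that("adding a mismatch never upgrades the class", {
  rank <- c(NONE = 0, WEAK = 1, STRONG = 2)
  set.seed(8)
  for (i in 1:200) {
    pos <- sort(sample(1:20, sample(0:3, 1)))
    extra <- sample(setdiff(1:20, pos), 1)
    before <- classifyPrimerBinding(pos)
    after <- classifyPrimerBinding(sort(c(pos, extra)))
    expect_lte(rank[[after]], rank[[before]])
  }
})

test_that("in-silico PCR pairs converging hits with oracle sizes", {
  set.seed(23)
  fwd <- randomDNA(18)
  rev <- randomDNA(18)
  revSite <- oracleRevcomp(rev)
  # two forward sites and one reverse site within range
  tpl <- paste0(randomDNA(50), fwd, randomDNA(200), fwd, randomDNA(300),
                revSite, randomDNA(50))
  amps <- insilicoPCR(fwd, rev, c(T1 = tpl))
  expect_equal(nrow(amps), 2L)
  expect_identical(amps$class, c("STRONG", "STRONG"))
  # oracle interval arithmetic: 5' end of forward to 5' end of reverse
  f1 <- 51L; f2 <- 51L + 18L + 200L
  revStart <- 50L + 18L + 200L + 18L + 300L + 1L
  expect_setequal(amps$size_bp,
                  c(revStart + 17L - f1 + 1L, revStart + 17L - f2 + 1L))
  expect_equal(amps$size_bp, amps$end - amps$start + 1L)
  # templates with neither primer
  expect_equal(nrow(insilicoPCR(fwd, rev, c(T2 = randomDNA(400)))), 0L)
})

test_that("amplicons mirror on the reverse-complemented template", {
  set.seed(77)
  fwd <- randomDNA(18); rev <- randomDNA(18)
  tpl <- paste0(randomDNA(40), fwd, randomDNA(400), oracleRevcomp(rev),
                randomDNA(40))
  L <- nchar(tpl)
  a1 <- insilicoPCR(fwd, rev, c(T = tpl))
  a2 <- insilicoPCR(fwd, rev, c(T = oracleRevcomp(tpl)))
  expect_equal(nrow(a1), nrow(a2))
  expect_setequal(a1$size_bp, a2$size_bp)
  expect_setequal(paste(L - a1$end + 1L, L - a1$start + 1L),
                  paste(a2$start, a2$end))
})

test_that("specificity verdicts match a brute-force oracle on random trios", {
  set.seed(424)
  agree <- 0L
  for (trial in 1:100) {
    tgt <- randomDNA(400)
    fwd <- substr(tgt, 21, 38)
    rev <- oracleRevcomp(substr(tgt, 351, 368))
    # off-targets: mutated copies of the target (sometimes none mutated,
    # so the pair must be called unspecific)
    mutate <- function(s, n) {
      for (p in sample(nchar(s), n)) {
        old <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
      s
    }
    offs <- list(B = mutate(tgt, sample(0:25, 1)),
                 C = mutate(tgt, sample(0:25, 1)))
    got <- isGenomeSpecific(fwd, rev, c(A = tgt), offs)
    want <- oracleSpecific(fwd, rev, tgt, offs)
    expect_identical(got$specific, want)
    if (got$specific == want) agree <- agree + 1L
  }
  expect_equal(agree, 100L)
})
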