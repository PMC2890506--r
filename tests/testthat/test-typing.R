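test_that("all published genotype rows classify to their printed labels", {
  panel <- waxyPanelForClassification()
  tab <- printedGenotypeTable()
  expect_equal(nrow(tab), 10L)
  for (i in seq_len(nrow(tab))) {
    got <- classifyGenotype(c(tab$wx7A[i], tab$wx4A[i], tab$wx7D[i]),
                            panel)
    expect_identical(got$label, tab$null_allele[i])
    expect_equal(got$code, tab$type[i])
  }
})

test_that("the never-printed double-null codes are flagged as inferred", {
  panel <- waxyPanelForClassification()
  c5 <- classifyGenotype("+--", panel)
  expect_equal(c5$code, 5L)
  expect_true(c5$inferred)
  c6 <- classifyGenotype("-+-", panel)
  expect_equal(c6$code, 6L)
  expect_true(c6$inferred)
  c2 <- classifyGenotype("-++", panel)
  expect_false(c2$inferred)
  expect_setequal(c6$null_loci, c("Wx-A1", "Wx-D1"))
  expect_error(classifyGenotype("+-", panel), "does not match")
  expect_error(classifyGenotype("+?+", panel), "must be")
})

test_that("deletion mechanisms silence the expected primer sets", {
  set.seed(404)
  # wild-type gene: 4 exons / 3 introns, all pieces 120 bp
  pieces <- replicate(7, randomDNA(120))
  wt <- paste(pieces, collapse = "")
  ex <- cbind(c(1, 241, 481, 721), c(120, 360, 600, 840))
  copy <- geneCopy("A", wt, exons = ex)
  loose <- pcrParams()
  # pair 1: forward anchored at the start of intron 1, reverse in exon 2
  fwd1 <- substr(wt, 125, 142)
  rev1 <- oracleRevcomp(substr(wt, 301, 318))
  # pair 2: forward in exon 3, reverse inside the terminal exon
  fwd2 <- substr(wt, 500, 517)
  rev2 <- oracleRevcomp(substr(wt, 801, 818))
  expect_identical(predictPresence(fwd1, rev1, copy), "present")
  expect_identical(predictPresence(fwd2, rev2, copy), "present")

  # intron 1 deletion removes the fwd1 site only
  noIntron1 <- simulateNullAllele(copy, "intron_deletion", 1)
  expect_equal(geneLength(noIntron1), 840L - 120L)
  expect_identical(predictPresence(fwd1, rev1, noIntron1), "absent")
  expect_identical(predictPresence(fwd2, rev2, noIntron1), "present")

  # terminal-exon deletion removes the rev2 site only
  noLastExon <- simulateNullAllele(copy, "exon_deletion", 4)
  expect_identical(predictPresence(fwd1, rev1, noLastExon), "present")
  expect_identical(predictPresence(fwd2, rev2, noLastExon), "absent")
  expect_equal(length(exons(noLastExon)), 3L)

  # whole-gene deletion removes everything
  gone <- simulateNullAllele(copy, "whole_gene_deletion")
  expect_equal(geneLength(gone), 0L)
  expect_identical(predictPresence(fwd1, rev1, gone), "absent")
  expect_identical(predictPresence(fwd2, rev2, gone), "absent")
  expect_error(simulateNullAllele(copy, "intron_deletion", 9),
               "out of range")
})

test_that("typeAlleles reproduces patterns and is order invariant", {
  set.seed(515)
  mkGene <- function() {
    s <- randomDNA(700)
    geneCopy("L", s, exons = cbind(c(1, 401), c(200, 700)))
  }
  genes <- list(`Wx-A1` = mkGene(), `Wx-B1` = mkGene(),
                `Wx-D1` = mkGene())
  entry <- function(locus) {
    s <- as.character(genes[[locus]]@sequence)
    data.frame(locus = locus, fwd_name = paste0(locus, "-F"),
               fwd_seq = substr(s, 211, 230),
               rev_name = paste0(locus, "-R"),
               rev_seq = oracleRevcomp(substr(s, 561, 580)),
               stringsAsFactors = FALSE)
  }
  panel <- diagnosticPanel(do.call(rbind, lapply(names(genes), entry)),
                           reference = genes)
  nullify <- function(locus) simulateNullAllele(genes[[locus]],
                                                "whole_gene_deletion")
  samples <- list(
    wildtype = genes,
    a_null = modifyList(genes, list(`Wx-A1` = nullify("Wx-A1"))),
    double = modifyList(genes, list(`Wx-A1` = nullify("Wx-A1"),
                                    `Wx-B1` = nullify("Wx-B1"))),
    triple = lapply(genes, function(g)
      simulateNullAllele(g, "whole_gene_deletion")))
  res <- typeAlleles(panel, samples)
  expect_identical(res$code, c("1", "2", "7", "8"))
  expect_identical(res$`Wx-A1`, c("+", "-", "-", "-"))
  shuffled <- typeAlleles(panel, samples[c(3, 1, 4, 2)])
  expect_identical(shuffled$code[match(res$sample, shuffled$sample)],
                   res$code)

  # a panel that cannot amplify its wild-type reference is invalid
  badEntry <- entry("Wx-A1")
  badEntry$fwd_seq <- randomDNA(20)
  expect_error(diagnosticPanel(rbind(badEntry, entry("Wx-B1"),
                                     entry("Wx-D1"))[c(1, 2, 3), ],
                               reference = genes),
               "fails to amplify")
})
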