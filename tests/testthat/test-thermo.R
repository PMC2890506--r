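test_that("Tm agrees with an independent nearest-neighbor oracle", {
  # a published 18-mer plus random primers across the length range
  expect_equal(meltingTemperature("GTAAGCTTGCGCCACTGC"),
               oracleTm("GTAAGCTTGCGCCACTGC"), tolerance = 0.01)
  set.seed(314)
  for (i in 1:25) {
    p <- randomDNA(sample(16:25, 1))
    expect_equal(meltingTemperature(p), oracleTm(p), tolerance = 0.01)
  }
  # non-default reaction conditions
  pars <- thermoParams(monovalent_mM = 100, divalent_mM = 3,
                       dntp_mM = 0.8, primer_uM = 0.25)
  p <- "ACCGTTAGCATCGGATCAAT"
  expect_equal(meltingTemperature(p, pars),
               oracleTm(p, 100, 3, 0.8, 0.25), tolerance = 0.01)
})

test_that("Tm rises under 5'-terminal G/C extension and is strand symmetric", {
  set.seed(11)
  for (i in 1:20) {
    s <- randomDNA(sample(15:24, 1))
    expect_gt(meltingTemperature(paste0("G", s)), meltingTemperature(s))
    expect_gt(meltingTemperature(paste0("C", s)), meltingTemperature(s))
    expect_equal(meltingTemperature(oracleRevcomp(s)),
                 meltingTemperature(s), tolerance = 1e-9)
  }
})

test_that("invalid primers are rejected explicitly", {
  expect_error(meltingTemperature("ACGTACG"), "at least 8")
  expect_error(meltingTemperature("ACGTACGTNACGTACGT"), "ambiguous")
  expect_error(meltingTemperature("ACGTACGTRACGTACGT"), "ambiguous")
})

test_that("5'-terminal adjustment fixes the 3' anchor and hits the window", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(99)
  tpl <- randomDNA(4000)
  pars <- thermoParams()
  accepted <- 0L
  for (i in 1:1000) {
    anchor <- sample(30:3970, 1)
    orient <- sample(c("forward", "reverse"), 1)
    fit <- adjustTmBy5Prime(tpl, anchor, orient, pars)
    if (fit$status != "ok") next
    accepted <- accepted + 1L
    expect_gte(fit$tm_C, 59); expect_lte(fit$tm_C, 61)
    expect_gte(fit$length, 16L); expect_lte(fit$length, 25L)
    tplBase <- substr(tpl, anchor, anchor)
    last <- substr(fit$sequence, fit$length, fit$length)
    if (orient == "forward") expect_identical(last, tplBase)
    else expect_identical(last, unname(comp[tplBase]))
    # shortest-satisfying: every shorter in-range length misses the window
    if (fit$length > 16L) {
      for (L in 16L:(fit$length - 1L)) {
        sub <- if (orient == "forward")
          substr(tpl, anchor - L + 1L, anchor)
        else oracleRevcomp(substr(tpl, anchor, anchor + L - 1L))
        tm <- meltingTemperature(sub, pars)
        expect_true(tm < 59 || tm > 61)
      }
    }
  }
  expect_gt(accepted, 200L)  # the window is reachable for most anchors
})

test_that("unreachable windows are rejected with the nearest achievable Tm", {
  atRich <- paste(rep("AT", 40), collapse = "")
  fit <- adjustTmBy5Prime(atRich, 40, "forward")
  expect_identical(fit$status, "rejected")
  expect_lt(fit$nearest_tm_C, 59)
  gcRich <- paste(rep("GC", 40), collapse = "")
  fitGC <- adjustTmBy5Prime(gcRich, 40, "forward")
  # a GC-rich anchor either fits near the minimum length or overshoots
  if (fitGC$status == "ok") expect_lte(fitGC$length, 18L)
  else expect_gt(fitGC$nearest_tm_C, 61)
  # determinism
  f1 <- adjustTmBy5Prime("ACGTACGTACGTACGTACGTACGTACGTACGT", 30, "forward")
  f2 <- adjustTmBy5Prime("ACGTACGTACGTACGTACGTACGTACGTACGT", 30, "forward")
  expect_identical(f1, f2)
})
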