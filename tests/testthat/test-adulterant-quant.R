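test_that("copy fraction applies the target-copy correction", {
  aa <- equalAssayPair()
  # 10 vs 990 copies, all corrections 1 -> 1.0%
  e10 <- estimateLambda(dropletCall(20000, 10))
  # counts here are positives; use direct copy construction via lambda
  mk <- function(copies) {
    lam <- copies / 20000
    nNeg <- round(20000 * exp(-lam))
    # build an estimate with exactly the wanted copiesPerReaction
    est <- estimateLambda(dropletCall(20000, 20000 - nNeg))
    est
  }
  cfA <- copyFraction(mk(10), mk(990), aa$adulterant, aa$ingredient)
  expect_equal(copyPct(cfA), 1.0, tolerance = 0.05)

  # 200 copies with 2 targets/haploid vs 900 with 1 -> GE 100 vs 900 -> 10%
  ad2 <- speciesAssay("olive", 1, targetCopiesPerHaploid = 2,
                      classLabel = "adulterant")
  cfB <- copyFraction(mk(200), mk(900), ad2, aa$ingredient)
  expect_equal(copyPct(cfB), 100 * 100 / 1000, tolerance = 0.25)
})

test_that("copy fraction is scale invariant and monotone", {
  aa <- equalAssayPair()
  mk <- function(nPos, n = 20000L) estimateLambda(dropletCall(n, nPos))
  base <- copyPct(copyFraction(mk(100), mk(5000), aa$adulterant,
                               aa$ingredient))
  # scaling both wells (same lambda, bigger reaction) leaves copy% fixed
  scaled <- copyPct(copyFraction(mk(300, 60000L), mk(15000, 60000L),
                                 aa$adulterant, aa$ingredient))
  expect_equal(scaled, base, tolerance = 1e-9)

  # monotone in adulterant copies at fixed ingredient copies
  pcts <- vapply(c(10, 100, 500, 2000), function(np)
    copyPct(copyFraction(mk(np), mk(5000), aa$adulterant, aa$ingredient)),
    numeric(1))
  expect_true(all(diff(pcts) > 0))
})

test_that("detection edge cases: both zero, trace below LOD", {
  aa <- equalAssayPair()
  z <- estimateLambda(dropletCall(20000, 0))
  cf0 <- copyFraction(z, z, aa$adulterant, aa$ingredient)
  expect_true("not_detected" %in% qualityFlags(cf0))
  expect_true(is.na(copyPct(cf0)))

  tr <- copyFraction(estimateLambda(dropletCall(20000, 2)),
                     estimateLambda(dropletCall(20000, 5000)),
                     aa$adulterant, aa$ingredient)
  expect_true("trace_not_quantifiable" %in% qualityFlags(tr))
})

test_that("mass fraction converts via genome sizes", {
  aa <- equalAssayPair()
  mk <- function(nPos) estimateLambda(dropletCall(20000, nPos))
  cf <- copyFraction(mk(1000), mk(1000), aa$adulterant, aa$ingredient)
  cf <- massFraction(cf, aa$adulterant, aa$ingredient)
  # equal genome sizes: mass% == copy%
  expect_equal(massPct(cf), copyPct(cf))

  # adulterant genome twice the ingredient's, copy% 33.33 -> mass% 50
  adBig <- speciesAssay("olive", 2, classLabel = "adulterant")
  cf2 <- copyFraction(mk(1000), mk(2000), adBig, aa$ingredient)
  expect_equal(copyPct(cf2), 100 / 3, tolerance = 1)
  cf2 <- massFraction(cf2, adBig, aa$ingredient)
  expect_equal(massPct(cf2), 50, tolerance = 1)
})

test_that("mass fraction inverts the mixture generator exactly (noise-free)", {
  assays <- list(
    oregano = speciesAssay("oregano", 1.05),
    olive = speciesAssay("olive", 1.46, classLabel = "adulterant"))
  for (f in c(0.01, 0.05, 0.3)) {
    cp <- simulateMixtureCopies(
      mixtureSpec(stats::setNames(c(f, 1 - f), c("olive", "oregano"))),
      assays)
    mkExact <- function(copies) new("CopyEstimate",
      lambdaHat = copies / 20000, copiesPerReaction = copies,
      copiesPerUl = 1, ciLow = copies / 20000, ciHigh = copies / 20000,
      dropletVolume = 0.85, nTotal = 20000L, nNegative = 1L,
      flags = character(0))
    cf <- massFraction(
      copyFraction(mkExact(cp[["olive"]]), mkExact(cp[["oregano"]]),
                   assays$olive, assays$oregano),
      assays$olive, assays$oregano)
    expect_equal(massPct(cf), 100 * f, tolerance = 1e-9)
  }
})

test_that("parameter recovery: 5% olive mixture through the full chain", {
  # equal genome sizes so gravimetric 5% equals copy 5%
  aa <- equalAssayPair()
  assays <- list(olive = aa$adulterant, oregano = aa$ingredient)
  withr::with_seed(55, {
    pcts <- vapply(1:20, function(i) {
      cp <- simulateMixtureCopies(
        mixtureSpec(c(olive = 0.05, oregano = 0.95)), assays)
      sim <- function(copies) estimateLambda(callDroplets(
        simulateDroplets(dropletSimParams(20000,
                                          lambdaTrue = copies / 20000))))
      copyPct(copyFraction(sim(cp[["olive"]]), sim(cp[["oregano"]]),
                           assays$olive, assays$oregano))
    }, numeric(1))
    expect_true(all(pcts >= 3.5 & pcts <= 6.5))
  })
})
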