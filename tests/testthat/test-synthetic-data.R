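test_that("droplet simulation follows Poisson occupancy", {
  # no template -> no positives
  ds0 <- simulateDroplets(dropletSimParams(1000, lambdaTrue = 0, seed = 1))
  expect_false(any(trueLabels(ds0)))

  # P(occupancy = 0) = e^{-lambda}; at lambda = ln 2 the negative
  # fraction is 0.5 within 5 binomial sd at n = 1e5
  n <- 100000L
  ds <- simulateDroplets(dropletSimParams(n, lambdaTrue = log(2), seed = 2))
  negFrac <- mean(!trueLabels(ds))
  expect_lt(abs(negFrac - 0.5), 5 * sqrt(0.25 / n))

  # negative-fraction convergence across lambda (property)
  for (lam in c(0.1, 1, 2)) {
    d <- simulateDroplets(dropletSimParams(n, lambdaTrue = lam,
                                           seed = 10 + lam * 10))
    p <- exp(-lam)
    expect_lt(abs(mean(!trueLabels(d)) - p), 5 * sqrt(p * (1 - p) / n))
  }
})

test_that("droplet simulation is reproducible and validates input", {
  p <- dropletSimParams(20000, lambdaTrue = 0.1, seed = 99)
  expect_identical(amplitudes(simulateDroplets(p)),
                   amplitudes(simulateDroplets(p)))
  expect_error(dropletSimParams(lambdaTrue = -1), "lambdaTrue")
  expect_error(dropletSimParams(negMean = 9000, posMean = 8000), "negMean")
  expect_error(dropletSimParams(rainFraction = 1), "rainFraction")
  expect_error(dropletSimParams(nDroplets = 0), "nDroplets")
})

test_that("rain droplets sit between the population means with labels kept", {
  p <- dropletSimParams(20000, lambdaTrue = 0.5, rainFraction = 0.1,
                        seed = 5)
  ds <- simulateDroplets(p)
  mid <- amplitudes(ds) > p$negMean & amplitudes(ds) < p$posMean
  # roughly rainFraction of droplets land strictly between the means
  expect_gt(mean(mid), 0.05)
  expect_length(trueLabels(ds), 20000)
})

test_that("fluorometry replicates are mean-unbiased with the stated CV", {
  # zero noise: all four replicates equal the true concentration
  f0 <- simulateFluorometry(10, cv = 0, seed = 1)
  expect_equal(f0$replicates, rep(10, 4))
  expect_equal(f0$mean, 10)

  # Monte-Carlo unbiasedness: mean of replicate means within 0.5% of 10
  means <- withr::with_seed(42, vapply(1:10000, function(i)
    simulateFluorometry(10, cv = 0.05)$mean, numeric(1)))
  expect_lt(abs(mean(means) - 10) / 10, 0.005)
  # per-replicate CV close to requested
  reps <- withr::with_seed(43,
    simulateFluorometry(10, cv = 0.05, nReplicates = 20000)$replicates)
  expect_lt(abs(stats::sd(reps) / mean(reps) - 0.05), 0.005)

  expect_error(simulateFluorometry(0, cv = 0.05), "trueConc")
  expect_error(simulateFluorometry(10, cv = -0.1), "cv")
  # truncated-normal variant stays positive
  ft <- simulateFluorometry(0.5, cv = 0.8, seed = 3, model = "truncnorm")
  expect_true(all(ft$replicates > 0))
})

test_that("mixture copy arithmetic matches hand-computed oracles", {
  a1 <- list(oregano = unitAssay("oregano"))
  expect_equal(
    simulateMixtureCopies(mixtureSpec(c(oregano = 1), 18), a1)[["oregano"]],
    18000)

  # equal genome sizes: copy share equals mass share
  a2 <- list(oregano = unitAssay("oregano"),
             olive = unitAssay("olive", "adulterant"))
  cp <- simulateMixtureCopies(mixtureSpec(c(olive = 0.05, oregano = 0.95),
                                          18), a2)
  expect_equal(cp[["olive"]] / sum(cp), 0.05)

  # olive 1C = 2 pg vs oregano 1 pg: copy fraction 0.05/2 / (0.05/2+0.95)
  a3 <- list(oregano = unitAssay("oregano"),
             olive = speciesAssay("olive", genomeSize1C = 2,
                                  classLabel = "adulterant"))
  cp3 <- simulateMixtureCopies(mixtureSpec(c(olive = 0.05, oregano = 0.95),
                                           18), a3)
  expect_equal(cp3[["olive"]] / sum(cp3), 0.025 / 0.975, tolerance = 1e-12)

  expect_error(simulateMixtureCopies(
    mixtureSpec(c(olive = 0.05, oregano = 0.95)), a1), "no assay entry")
  expect_error(mixtureSpec(c(a = 0.5, b = 0.6)), "sum to 1")
  expect_error(mixtureSpec(c(a = 1), totalTemplateMass = 0), "> 0")
})

test_that("read tables honour bias, dropout and misattribution", {
  # unbiased multinomial: each 50/50 share within 5 sd of 0.5
  rt <- simulateReadTable(c(A = 1, B = 1),
                          readSimParams(totalReads = 1e6, seed = 1))
  df <- readCounts(rt)
  expect_identical(sum(df$reads), 1000000L)
  expect_lt(abs(df$reads[df$taxon == "A"] / 1e6 - 0.5),
            5 * sqrt(0.25 / 1e6))

  # total dropout: zero reads regardless of abundance
  rtd <- simulateReadTable(c(sumac = 10, oregano = 90),
                           readSimParams(totalReads = 10000,
                                         dropout = c(sumac = 1), seed = 2))
  expect_identical(readCounts(rtd)$reads[
    readCounts(rtd)$taxon == "sumac"], 0L)

  # 30x bias on a 1% weed: read share far above 1%
  rtb <- simulateReadTable(c(weed = 1, oregano = 99),
                           readSimParams(totalReads = 1e5,
                                         bias = c(weed = 30), seed = 3))
  dfb <- readCounts(rtb)
  weedPct <- 100 * dfb$reads[dfb$taxon == "weed"] / sum(dfb$reads)
  expect_gt(weedPct, 15)  # expected 100 * 0.3/1.29 ~ 23%

  # misattribution conserves total reads (row-stochastic)
  m <- neighbourLeakMatrix(c("oregano", "thyme"), c(oregano = "thyme"),
                           leak = 0.2)
  expect_equal(rowSums(m), c(oregano = 1, thyme = 1))
  rtm <- simulateReadTable(c(oregano = 1),
                           readSimParams(totalReads = 5000,
                                         misattribution = m, seed = 4))
  dfm <- readCounts(rtm)
  expect_identical(sum(dfm$reads), 5000L)
  expect_gt(dfm$reads[dfm$taxon == "thyme"], 0L)

  bad <- matrix(c(0.5, 0.2, 0.5, 0.5), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(readSimParams(misattribution = bad), "sum to 1")
  expect_error(simulateReadTable(c(A = 0, B = 0), readSimParams()),
               "not all zero")
})

test_that("read table generation is bit-reproducible under a seed", {
  p <- readSimParams(totalReads = 20000, bias = c(A = 2),
                     dropout = c(B = 0.5), seed = 77)
  r1 <- readCounts(simulateReadTable(c(A = 1, B = 1, C = 2), p))
  r2 <- readCounts(simulateReadTable(c(A = 1, B = 1, C = 2), p))
  expect_identical(r1, r2)
})
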