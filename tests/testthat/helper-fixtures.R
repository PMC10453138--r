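# shared in-code fixtures

# unit assay: genome 1 pg, 1 target/haploid -> copies == pg of DNA
unitAssay <- function(species = "x", class = "ingredient")
  speciesAssay(species, genomeSize1C = 1, targetCopiesPerHaploid = 1,
               classLabel = class)

equalAssayPair <- function() list(
  adulterant = unitAssay("olive", "adulterant"),
  ingredient = unitAssay("oregano", "ingredient"))

# count-level ddPCR draw: droplet partitioning without the amplitude layer
countLevelEstimate <- function(lambda, n = 20000L) {
  nNeg <- stats::rbinom(1, n, exp(-lambda))
  estimateLambda(dropletCall(n, n - nNeg))
}

# well-separated bimodal amplitude set with known labels
bimodalSet <- function(n, nPos, negMean = 2000, sepSd = 10, sd = 100) {
  labels <- c(rep(FALSE, n - nPos), rep(TRUE, nPos))
  amp <- ifelse(labels, stats::rnorm(n, negMean + sepSd * sd, sd),
                stats::rnorm(n, negMean, sd))
  DropletSet(amp, trueLabels = labels)
}
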