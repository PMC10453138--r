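## Poisson absolute quantification: droplets are independent equal-volume
## partitions, so occupancy is Poisson and the negative fraction
## estimates e^{-lambda}. Everything downstream consumes
## copiesPerReaction = lambdaHat * nTotal, which is independent of the
## droplet-volume constant.

#' Construct a DropletCall from counts
#'
#' Convenience constructor for building calls directly from positive /
#' total counts (e.g. instrument summary exports) without raw
#' amplitudes.
#'
#' @param nTotal total droplets.
#' @param nPositive positive droplets.
#' @param threshold amplitude threshold (NA when unknown).
#' @param qualityFlags optional character flags.
#' @return A [DropletCall-class].
#' @examples
#' dropletCall(20000, 150)
#' @export
dropletCall <- function(nTotal, nPositive, threshold = NA_real_,
                        qualityFlags = character(0)) {
  nTotal <- as.integer(nTotal); nPositive <- as.integer(nPositive)
  new("DropletCall", nTotal = nTotal, nPositive = nPositive,
      nNegative = nTotal - nPositive, threshold = threshold,
      nRainReassigned = 0L, qualityFlags = qualityFlags)
}

#' Estimate copies per droplet and per reaction from a droplet call
#'
#' The Poisson point estimate is `lambdaHat = -ln(nNegative / nTotal)`.
#' The confidence interval comes from a Wilson score interval on the
#' negative fraction mapped through -ln (the upper fraction bound gives
#' the lower lambda bound and vice versa); Wald is available for
#' comparison. `copiesPerReaction = lambdaHat * nTotal` and
#' `copiesPerUl = lambdaHat / dropletVolume`.
#'
#' A well with no negative droplets is above the dynamic range and
#' raises a saturation error (condition class `"ddPurity_saturation"`).
#' A well with no positive droplets returns `lambdaHat = 0` with a
#' one-sided interval and flag `"not_detected"`.
#'
#' @param call a [DropletCall-class].
#' @param dropletVolume droplet volume in nL (default 0.85, the
#'   instrument-class standard; only `copiesPerUl` depends on it).
#' @param conf confidence level (default 0.95).
#' @param ciMethod "wilson" (default) or "wald".
#' @return A [CopyEstimate-class].
#' @examples
#' estimateLambda(dropletCall(10000, 5000))  # lambda = ln 2
#' @export
estimateLambda <- function(call, dropletVolume = 0.85, conf = 0.95,
                           ciMethod = c("wilson", "wald")) {
  ciMethod <- match.arg(ciMethod)
  stopifnot(is(call, "DropletCall"))
  n <- nTotal(call); nNeg <- nNegative(call)
  if (n < 1L) stop("empty droplet call")
  if (nNeg == 0L)
    stop(structure(class = c("ddPurity_saturation", "error", "condition"),
                   list(message = paste0(
                     "no negative droplets in well: concentration above ",
                     "the dynamic range, dilute and re-run"),
                     call = sys.call())))
  pHat <- nNeg / n
  lam <- -log(pHat)
  flags <- qualityFlags(call)
  if (ciMethod == "wilson") {
    ci <- stats::prop.test(nNeg, n, conf.level = conf,
                           correct = FALSE)$conf.int
  } else {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    half <- z * sqrt(pHat * (1 - pHat) / n)
    ci <- c(max(0, pHat - half), min(1, pHat + half))
  }
  if (nNeg == n) {           # no positives: one-sided, not detected
    lam <- 0
    ciLow <- 0
    ciHigh <- -log(ci[1])
    flags <- union(flags, "not_detected")
  } else {
    ciLow <- -log(min(1, ci[2]))
    ciHigh <- -log(ci[1])
  }
  new("CopyEstimate", lambdaHat = lam, copiesPerReaction = lam * n,
      copiesPerUl = lam / (dropletVolume * 1e-3),
      ciLow = max(0, ciLow), ciHigh = ciHigh,
      dropletVolume = dropletVolume, nTotal = n, nNegative = nNeg,
      flags = flags)
}

#' Pool replicate wells into one estimate
#'
#' Merges replicate wells by summing negative and total droplet counts
#' before re-estimating (the merged-partition estimator), which is both
#' simpler and tighter than averaging per-well estimates. Quality flags
#' are unioned; a saturated member raises the same saturation error as
#' [estimateLambda()].
#'
#' @param estimates non-empty list of [CopyEstimate-class] sharing one
#'   dropletVolume.
#' @param conf confidence level.
#' @param ciMethod passed to [estimateLambda()].
#' @return A [CopyEstimate-class].
#' @examples
#' e <- estimateLambda(dropletCall(20000, 1000))
#' poolWells(list(e, e))
#' @export
poolWells <- function(estimates, conf = 0.95,
                      ciMethod = c("wilson", "wald")) {
  if (!length(estimates)) stop("no estimates to pool")
  vols <- vapply(estimates, function(e) e@dropletVolume, numeric(1))
  if (diff(range(vols)) > 1e-12)
    stop("all pooled estimates must share one dropletVolume")
  nNegEach <- vapply(estimates, nNegative, integer(1))
  if (any(nNegEach == 0L))
    stop(structure(class = c("ddPurity_saturation", "error", "condition"),
                   list(message = "saturated member well in pool",
                        call = sys.call())))
  n <- sum(vapply(estimates, nTotal, integer(1)))
  nNeg <- sum(nNegEach)
  flags <- Reduce(union, lapply(estimates, qualityFlags))
  pooled <- dropletCall(n, n - nNeg,
                        qualityFlags = setdiff(flags, "not_detected"))
  estimateLambda(pooled, dropletVolume = vols[1], conf = conf,
                 ciMethod = match.arg(ciMethod))
}
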