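## One-dimensional droplet calling: kernel-density estimation of the
## amplitude distribution, valley detection between the two dominant
## modes, then reassignment of intermediate "rain" droplets by distance
## to the robust (median/MAD) population centres.

#' Construct a DropletSet
#'
#' @param amplitudes numeric vector of finite fluorescence amplitudes.
#' @param wellId well identifier.
#' @param channel channel index (1 or 2).
#' @param trueLabels optional logical ground-truth labels (simulation).
#' @return A [DropletSet-class].
#' @examples
#' DropletSet(c(1, 1, 9), wellId = "B02")
#' @export
DropletSet <- function(amplitudes, wellId = "A01", channel = 1L,
                       trueLabels = logical(0)) {
  new("DropletSet", wellId = wellId, channel = as.integer(channel),
      amplitudes = as.numeric(amplitudes), trueLabels = trueLabels)
}

#' Calling options
#'
#' @param minDroplets minimum droplet count required for density
#'   estimation (default 100).
#' @param rainK rain band width in MAD units around each population's
#'   robust centre (default 5): droplets between
#'   `median(neg) + rainK * mad(neg)` and `median(pos) - rainK * mad(pos)`
#'   are treated as rain and reassigned to the nearer robust centre.
#' @param relModeHeight minimum kernel-density height of a mode, relative
#'   to the global maximum, for it to count as a population (default
#'   1e-3; small enough to keep a ~0.1% positive cluster, large enough to
#'   ignore single-droplet bumps).
#' @param minValleyRatio minimum prominence of the secondary population:
#'   its mode density must exceed `minValleyRatio` times the density at
#'   the valley separating it from the dominant mode (default 1.5).
#'   Shoulder ripples of a single population fail this and the well is
#'   called unimodal.
#' @param minSideCount minimum droplets on the minority side of the
#'   threshold for a two-population call (default 3, mirroring the
#'   trace limit of detection); a couple of coincident outliers do not
#'   constitute a population.
#' @param negativeBand amplitude interval `c(lo, hi)`; a unimodal well
#'   whose single mode falls inside it is called all-negative, otherwise
#'   all-positive. NULL (default) treats any unimodal well as
#'   all-negative (conservative for contamination claims) with a quality
#'   flag.
#' @param densityN number of KDE grid points (default 1024).
#' @return list of options for [callDroplets()].
#' @export
callOptions <- function(minDroplets = 100L, rainK = 5,
                        relModeHeight = 1e-3, minValleyRatio = 1.5,
                        minSideCount = 3L, negativeBand = NULL,
                        densityN = 1024L) {
  stopifnot(minDroplets >= 1, rainK >= 0, relModeHeight > 0,
            relModeHeight < 1, minValleyRatio >= 1, minSideCount >= 1)
  list(minDroplets = as.integer(minDroplets), rainK = rainK,
       relModeHeight = relModeHeight, minValleyRatio = minValleyRatio,
       minSideCount = as.integer(minSideCount),
       negativeBand = negativeBand, densityN = as.integer(densityN))
}

.localMaxima <- function(y) {
  n <- length(y)
  which(y >= c(-Inf, y[-n]) & y > c(y[-1], -Inf))
}

#' Call droplets positive or negative from 1-D amplitudes
#'
#' Estimates the amplitude density with a Gaussian kernel, locates the
#' two dominant, well-separated modes (the negative and positive droplet
#' populations), and places the threshold at the density minimum between
#' them. Droplets strictly above the threshold are positive; droplets at
#' the threshold are called negative (conservative). Intermediate
#' "rain" droplets — outside both populations' `median +/- rainK * MAD`
#' bands — are then reassigned to the nearer robust centre.
#'
#' Degenerate wells never crash: constant-amplitude wells are called as
#' a single population with flag `"constant_amplitude"`, unimodal wells
#' with flag `"unimodal"` (class decided by `negativeBand`, see
#' [callOptions()]).
#'
#' @param droplets a [DropletSet-class].
#' @param options a [callOptions()] list.
#' @return A [DropletCall-class]. The per-droplet classification is
#'   available via attribute `"classes"` (logical, TRUE = positive).
#' @examples
#' ds <- simulateDroplets(dropletSimParams(lambdaTrue = 0.3, seed = 7))
#' callDroplets(ds)
#' @export
callDroplets <- function(droplets, options = callOptions()) {
  stopifnot(is(droplets, "DropletSet"))
  amp <- amplitudes(droplets)
  n <- length(amp)
  if (n < options$minDroplets)
    stop(sprintf("too few droplets: %d < %d (configurable floor)",
                 n, options$minDroplets))

  finishCall <- function(pos, thr, nRain = 0L, flags = character(0)) {
    cl <- new("DropletCall", nTotal = n, nPositive = sum(pos),
              nNegative = sum(!pos), threshold = thr,
              nRainReassigned = as.integer(nRain), qualityFlags = flags)
    attr(cl, "classes") <- pos
    cl
  }
  singlePopulation <- function(flags) {
    centre <- stats::median(amp)
    band <- options$negativeBand
    neg <- is.null(band) || (centre >= band[1] && centre <= band[2])
    finishCall(rep(!neg, n), thr = if (neg) max(amp) else min(amp) - 1,
               flags = flags)
  }

  if (diff(range(amp)) == 0)
    return(singlePopulation(c("constant_amplitude", "unimodal")))

  ## bandwidth capped at range/8 so small printed sets stay bimodal
  bw <- min(stats::bw.nrd0(amp), diff(range(amp)) / 8)
  d <- stats::density(amp, bw = bw, n = options$densityN)
  peaks <- .localMaxima(d$y)
  peaks <- peaks[d$y[peaks] >= options$relModeHeight * max(d$y)]
  if (length(peaks) < 2L) return(singlePopulation("unimodal"))

  ## dominant mode + the most prominent secondary mode: the candidate
  ## whose density most exceeds the deepest valley separating it from
  ## the dominant mode (shoulder ripples have no such valley)
  m1 <- peaks[which.max(d$y[peaks])]
  cand <- setdiff(peaks, m1)
  valleyOf <- function(p) {
    i <- min(m1, p):max(m1, p)
    i[which.min(d$y[i])]
  }
  scores <- vapply(cand, function(p)
    d$y[p] / max(d$y[valleyOf(p)], .Machine$double.eps), numeric(1))
  if (max(scores) < options$minValleyRatio)
    return(singlePopulation("unimodal"))
  m2 <- cand[which.max(scores)]
  thr <- d$x[valleyOf(m2)]

  pos <- amp > thr
  if (min(sum(pos), sum(!pos)) < options$minSideCount)
    return(singlePopulation("unimodal"))

  ## rain: reassign intermediate droplets to the nearer robust centre
  negMed <- stats::median(amp[!pos]); negMad <- stats::mad(amp[!pos])
  posMed <- stats::median(amp[pos]);  posMad <- stats::mad(amp[pos])
  rainLo <- negMed + options$rainK * negMad
  rainHi <- posMed - options$rainK * posMad
  nRain <- 0L
  if (rainLo < rainHi) {
    isRain <- amp > rainLo & amp < rainHi
    if (any(isRain)) {
      toPos <- (posMed - amp[isRain]) < (amp[isRain] - negMed)
      nRain <- sum(toPos != pos[isRain])
      pos[isRain] <- toPos
    }
  }
  finishCall(pos, thr, nRain)
}

#' Brute-force minimum within-class variance threshold (test oracle)
#'
#' Scans every midpoint between consecutive sorted unique amplitudes and
#' returns the split minimizing the total within-class sum of squares.
#' Exhaustive and O(k^2) in the number of unique values — intended as an
#' independent oracle for validating [callDroplets()] on small
#' instances, not for production calling.
#'
#' @param amplitudes numeric vector, length >= 2.
#' @return list with `threshold` (droplets above it are positive),
#'   `ssWithin` (minimized criterion) and `degenerate` (TRUE when fewer
#'   than 2 distinct values; threshold is then NA).
#' @examples
#' thresholdOracle(c(0, 10))$threshold  # 5
#' @export
thresholdOracle <- function(amplitudes) {
  stopifnot(length(amplitudes) >= 2)
  u <- sort(unique(amplitudes))
  if (length(u) < 2L)
    return(list(threshold = NA_real_, ssWithin = 0, degenerate = TRUE))
  mids <- (u[-1] + u[-length(u)]) / 2
  ss <- vapply(mids, function(t) {
    lo <- amplitudes[amplitudes <= t]
    hi <- amplitudes[amplitudes > t]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  list(threshold = mids[which.min(ss)], ssWithin = min(ss),
       degenerate = FALSE)
}

#' Amplitude CSV I/O
#'
#' The documented on-disk dialect for raw droplet amplitudes: a header
#' row and one row per droplet with columns `well`, `channel`,
#' `amplitude`. [writeAmplitudeCsv()] serialises one or more
#' [DropletSet-class] objects; [readAmplitudeCsv()] reads the file back
#' as a list of DropletSets, one per (well, channel) pair.
#'
#' @param droplets a [DropletSet-class] or list of them.
#' @param path file path.
#' @return `readAmplitudeCsv`: named list of [DropletSet-class];
#'   `writeAmplitudeCsv`: the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeAmplitudeCsv(DropletSet(c(1, 2, 9)), f)
#' readAmplitudeCsv(f)
#' @export
writeAmplitudeCsv <- function(droplets, path) {
  if (is(droplets, "DropletSet")) droplets <- list(droplets)
  df <- do.call(rbind, lapply(droplets, function(ds) {
    data.frame(well = wellId(ds), channel = ds@channel,
               amplitude = amplitudes(ds))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAmplitudeCsv
#' @export
readAmplitudeCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "channel", "amplitude")
  if (!all(need %in% names(df)))
    stop("amplitude CSV must have columns well, channel, amplitude")
  key <- paste(df$well, df$channel, sep = "/")
  lapply(split(df, key), function(g)
    DropletSet(g$amplitude, wellId = g$well[1], channel = g$channel[1]))
}

#' Summarise droplet calls as a data.frame
#'
#' @param calls a [DropletCall-class] or list of them (names become the
#'   `well` column).
#' @return data.frame with one row per call.
#' @export
callSummary <- function(calls) {
  if (is(calls, "DropletCall")) calls <- list(calls)
  wells <- names(calls)
  if (is.null(wells)) wells <- sprintf("well%02d", seq_along(calls))
  do.call(rbind, Map(function(w, cl) {
    data.frame(well = w, n_total = nTotal(cl), n_positive = nPositive(cl),
               n_negative = nNegative(cl), threshold = threshold(cl),
               n_rain_reassigned = cl@nRainReassigned,
               flags = paste(qualityFlags(cl), collapse = ";"))
  }, wells, calls))
}
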