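## Synthetic-data generators. These define the study conditions every
## downstream module is validated against: Poisson droplet partitioning,
## replicate fluorometry noise, gravimetric mixtures converted to copy
## numbers, and species-biased / misattributed metabarcoding read tables.

.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Simulation parameter bundles
#'
#' Validated parameter sets for the synthetic-data generators.
#'
#' `mixtureSpec()` describes a gravimetric blend of species (mass
#' fractions summing to 1) and the total DNA template mass per reaction.
#' `dropletSimParams()` describes one simulated ddPCR well: the true mean
#' occupancy (copies per droplet) and the amplitude distributions of the
#' negative and positive droplet populations, plus an optional fraction
#' of intermediate-amplitude "rain". `readSimParams()` describes the
#' distortions applied to a metabarcoding read table: per-species
#' amplification/recovery bias multipliers, per-species dropout
#' probabilities (total failure to yield reads, as seen for sumac), and a
#' row-stochastic misattribution matrix emulating cross-talk between
#' phylogenetic neighbours.
#'
#' @param components named numeric vector of mass fractions in [0,1]
#'   (names are species), summing to 1 within 1e-9.
#' @param totalTemplateMass total DNA template mass per reaction (ng),
#'   > 0. Default 18 ng, the routine PCR input for this assay family.
#' @param nDroplets number of droplets in the well (default 20000,
#'   typical for the instrument class).
#' @param lambdaTrue true mean copies per droplet, >= 0.
#' @param negMean,posMean negative/positive population mean amplitudes;
#'   posMean > negMean.
#' @param negSd,posSd population standard deviations, > 0.
#' @param rainFraction fraction of droplets given an intermediate
#'   ("rain") amplitude, in [0, 1).
#' @param totalReads total sequencing reads for the sample.
#' @param bias named positive multipliers (species missing from the map
#'   default to 1).
#' @param dropout named dropout probabilities in [0, 1].
#' @param misattribution square row-stochastic matrix with identical row
#'   and column names (taxa); entry [i, j] is the probability a read from
#'   taxon i is attributed to taxon j. NULL = identity.
#' @param seed integer RNG seed or NULL.
#' @return A validated list of class "MixtureSpec", "DropletSimParams" or
#'   "ReadSimParams".
#' @examples
#' mixtureSpec(c(oregano = 0.95, olive = 0.05))
#' dropletSimParams(lambdaTrue = 0.5)
#' @export
mixtureSpec <- function(components, totalTemplateMass = 18, seed = NULL) {
  stopifnot(is.numeric(components), length(components) >= 1,
            !is.null(names(components)), all(nzchar(names(components))))
  if (any(!is.finite(components)) || any(components < 0) ||
      any(components > 1))
    stop("mass fractions must be finite and in [0, 1]")
  if (abs(sum(components) - 1) > 1e-9)
    stop("mass fractions must sum to 1 (within 1e-9)")
  if (!is.finite(totalTemplateMass) || totalTemplateMass <= 0)
    stop("totalTemplateMass must be > 0 ng")
  structure(list(components = components,
                 totalTemplateMass = totalTemplateMass,
                 seed = seed),
            class = "MixtureSpec")
}

#' @rdname mixtureSpec
#' @export
dropletSimParams <- function(nDroplets = 20000L, lambdaTrue = 0.1,
                             negMean = 2000, posMean = 8000,
                             negSd = 200, posSd = 300,
                             rainFraction = 0, seed = NULL) {
  nDroplets <- as.integer(nDroplets)
  if (is.na(nDroplets) || nDroplets < 1L) stop("nDroplets must be >= 1")
  if (!is.finite(lambdaTrue) || lambdaTrue < 0)
    stop("lambdaTrue must be finite and >= 0")
  if (!is.finite(negMean) || !is.finite(posMean) || posMean <= negMean)
    stop("posMean must exceed negMean")
  if (!is.finite(negSd) || !is.finite(posSd) || negSd <= 0 || posSd <= 0)
    stop("amplitude sds must be > 0")
  if (!is.finite(rainFraction) || rainFraction < 0 || rainFraction >= 1)
    stop("rainFraction must be in [0, 1)")
  structure(list(nDroplets = nDroplets, lambdaTrue = lambdaTrue,
                 negMean = negMean, posMean = posMean,
                 negSd = negSd, posSd = posSd,
                 rainFraction = rainFraction, seed = seed),
            class = "DropletSimParams")
}

#' @rdname mixtureSpec
#' @export
readSimParams <- function(totalReads = 10000L, bias = numeric(0),
                          dropout = numeric(0), misattribution = NULL,
                          seed = NULL) {
  totalReads <- as.integer(totalReads)
  if (is.na(totalReads) || totalReads < 1L) stop("totalReads must be >= 1")
  if (length(bias) && (is.null(names(bias)) || any(bias <= 0) ||
                       any(!is.finite(bias))))
    stop("bias must be a named vector of positive multipliers")
  if (length(dropout) && (is.null(names(dropout)) || any(dropout < 0) ||
                          any(dropout > 1)))
    stop("dropout probabilities must be named and in [0, 1]")
  if (!is.null(misattribution)) {
    m <- as.matrix(misattribution)
    if (nrow(m) != ncol(m) || is.null(rownames(m)) ||
        !identical(rownames(m), colnames(m)))
      stop("misattribution must be square with matching row/col names")
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
      stop("misattribution rows must be non-negative and sum to 1")
    misattribution <- m
  }
  structure(list(totalReads = totalReads, bias = bias, dropout = dropout,
                 misattribution = misattribution, seed = seed),
            class = "ReadSimParams")
}

#' Simulate a ddPCR well as per-droplet fluorescence amplitudes
#'
#' Draws each droplet's target occupancy from a Poisson law with mean
#' `lambdaTrue`, assigns amplitudes from the positive population
#' (occupancy >= 1) or the negative population (occupancy 0), and
#' optionally replaces a random `rainFraction` of droplets with an
#' amplitude uniform between the two population means ("rain",
#' emulating partly amplified droplets). Ground-truth labels (occupancy
#' >= 1) are retained regardless of rain, so callers can be scored.
#'
#' @param params a [dropletSimParams()] object.
#' @param wellId,channel identifiers carried into the [DropletSet-class].
#' @return A [DropletSet-class].
#' @examples
#' ds <- simulateDroplets(dropletSimParams(lambdaTrue = log(2), seed = 1))
#' mean(!trueLabels(ds))  # ~ e^{-lambda} = 0.5
#' @export
simulateDroplets <- function(params, wellId = "A01", channel = 1L) {
  stopifnot(inherits(params, "DropletSimParams"))
  .with_seed(params$seed, {
    n <- params$nDroplets
    occ <- stats::rpois(n, params$lambdaTrue)
    pos <- occ >= 1L
    amp <- numeric(n)
    amp[!pos] <- stats::rnorm(sum(!pos), params$negMean, params$negSd)
    amp[pos]  <- stats::rnorm(sum(pos),  params$posMean, params$posSd)
    if (params$rainFraction > 0) {
      isRain <- stats::runif(n) < params$rainFraction
      amp[isRain] <- stats::runif(sum(isRain), params$negMean,
                                  params$posMean)
    }
    new("DropletSet", wellId = wellId, channel = as.integer(channel),
        amplitudes = amp, trueLabels = pos)
  })
}

#' Simulate replicate fluorometric DNA quantification
#'
#' Emulates the routine fluorometric workflow: two independent dilutions
#' each quantified twice, i.e. four replicate measurements per sample,
#' averaged to give the concentration estimate. Noise is multiplicative
#' lognormal with the requested coefficient of variation (concentrations
#' are positive and fluorometric error scales with signal); a
#' truncated-normal alternative is available.
#'
#' @param trueConc true concentration in ng/uL, > 0.
#' @param cv coefficient of variation of a single measurement, >= 0.
#' @param seed integer seed or NULL.
#' @param nReplicates number of measurements (default 4).
#' @param model "lognormal" (default, mean-unbiased) or "truncnorm"
#'   (normal truncated at zero by resampling).
#' @return list with `replicates` (numeric vector), `mean` and `sd`.
#' @examples
#' simulateFluorometry(10, cv = 0.05, seed = 1)
#' @export
simulateFluorometry <- function(trueConc, cv, seed = NULL,
                                nReplicates = 4L,
                                model = c("lognormal", "truncnorm")) {
  model <- match.arg(model)
  if (!is.finite(trueConc) || trueConc <= 0)
    stop("trueConc must be > 0 ng/uL")
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0")
  nReplicates <- as.integer(nReplicates)
  stopifnot(nReplicates >= 1L)
  reps <- .with_seed(seed, {
    if (cv == 0) rep(trueConc, nReplicates)
    else if (model == "lognormal") {
      sdlog <- sqrt(log1p(cv^2))
      stats::rlnorm(nReplicates, meanlog = log(trueConc) - sdlog^2 / 2,
                    sdlog = sdlog)
    } else {
      x <- stats::rnorm(nReplicates, trueConc, cv * trueConc)
      while (any(x <= 0))
        x[x <= 0] <- stats::rnorm(sum(x <= 0), trueConc, cv * trueConc)
      x
    }
  })
  list(replicates = reps, mean = mean(reps), sd = stats::sd(reps))
}

#' Convert a gravimetric mixture to true target copies per reaction
#'
#' Deterministic copy arithmetic: species s contributes
#' `fraction_s * totalMass(pg) / genomeSize1C_s` haploid genomes, each
#' carrying `targetCopiesPerHaploid_s` target sequences. This is the
#' inverse of the ploidy/target correction applied when estimating an
#' adulterant's copy percentage from measurements.
#'
#' @param spec a [mixtureSpec()].
#' @param assays named list of [SpeciesAssay-class] objects covering
#'   every component species.
#' @return named numeric vector of true target copies per reaction.
#' @examples
#' a <- list(oregano = speciesAssay("oregano", genomeSize1C = 1))
#' simulateMixtureCopies(mixtureSpec(c(oregano = 1), 18), a)  # 18000
#' @export
simulateMixtureCopies <- function(spec, assays) {
  stopifnot(inherits(spec, "MixtureSpec"))
  species <- names(spec$components)
  missing <- setdiff(species, names(assays))
  if (length(missing))
    stop("no assay entry for: ", paste(missing, collapse = ", "))
  totalPg <- spec$totalTemplateMass * 1000
  vapply(species, function(s) {
    a <- assays[[s]]
    stopifnot(is(a, "SpeciesAssay"))
    spec$components[[s]] * totalPg / a@genomeSize1C *
      a@targetCopiesPerHaploid
  }, numeric(1))
}

#' Simulate a biased, misattributed metabarcoding read table
#'
#' Expected read share of each taxon is proportional to its abundance
#' proxy times its bias multiplier; taxa hit by dropout are zeroed and
#' the shares renormalized. `totalReads` reads are drawn multinomially,
#' then each taxon's reads are redistributed across taxa according to
#' the row-stochastic misattribution matrix (so the total read count is
#' conserved exactly). This reproduces, at the count level, the
#' systematic over-/under-reporting and neighbour cross-talk seen in
#' real plant metabarcoding, without simulating sequences.
#'
#' @param composition named non-negative abundance proxies (not all 0).
#' @param params a [readSimParams()].
#' @param sampleId sample identifier for the output table.
#' @param kingdom kingdom annotation applied to all simulated taxa
#'   (default "Plantae").
#' @return A [ReadTable-class]; rows cover the union of composition taxa
#'   and misattribution targets, including zero-read taxa.
#' @examples
#' rt <- simulateReadTable(c(A = 1, B = 1),
#'                         readSimParams(totalReads = 1000, seed = 1))
#' sum(readCounts(rt)$reads)  # exactly 1000
#' @export
simulateReadTable <- function(composition, params, sampleId = "S1",
                              kingdom = "Plantae") {
  stopifnot(inherits(params, "ReadSimParams"))
  if (any(!is.finite(composition)) || any(composition < 0) ||
      all(composition == 0) || is.null(names(composition)))
    stop("composition must be named, non-negative, not all zero")
  taxa <- names(composition)
  .with_seed(params$seed, {
    mult <- rep(1, length(taxa)); names(mult) <- taxa
    hit <- intersect(names(params$bias), taxa)
    mult[hit] <- params$bias[hit]
    w <- composition * mult
    for (s in intersect(names(params$dropout), taxa))
      if (stats::runif(1) < params$dropout[[s]]) w[[s]] <- 0
    if (all(w == 0)) w[] <- 0  # total dropout: zero-read table
    allTaxa <- taxa
    m <- params$misattribution
    if (!is.null(m)) allTaxa <- union(taxa, rownames(m))
    counts <- stats::setNames(integer(length(allTaxa)), allTaxa)
    if (sum(w) > 0) {
      drawn <- stats::rmultinom(1, params$totalReads, w / sum(w))[, 1]
      counts[taxa] <- drawn
      if (!is.null(m)) {
        out <- stats::setNames(integer(length(allTaxa)), allTaxa)
        for (i in allTaxa) {
          ci <- counts[[i]]
          if (ci == 0) next
          if (i %in% rownames(m)) {
            redis <- stats::rmultinom(1, ci, m[i, ])[, 1]
            out[colnames(m)] <- out[colnames(m)] + redis
          } else out[[i]] <- out[[i]] + ci
        }
        counts <- out
      }
    }
    new("ReadTable", sampleId = sampleId,
        reads = data.frame(taxon = names(counts), kingdom = kingdom,
                           reads = as.integer(counts),
                           stringsAsFactors = FALSE))
  })
}

#' Build a misattribution matrix with neighbour leak
#'
#' Identity matrix over `taxa` plus, for each entry of `neighbours`, a
#' probability `leak` of a read leaking to the named neighbour taxon —
#' a minimal model of cross-talk between close phylogenetic relatives.
#'
#' @param taxa character vector of taxa.
#' @param neighbours named character vector: names are source taxa,
#'   values the neighbour each leaks to.
#' @param leak per-read leak probability in [0, 1).
#' @return row-stochastic matrix suitable for [readSimParams()].
#' @examples
#' neighbourLeakMatrix(c("oregano", "thyme"), c(oregano = "thyme"), 0.05)
#' @export
neighbourLeakMatrix <- function(taxa, neighbours = character(0),
                                leak = 0.05) {
  stopifnot(leak >= 0, leak < 1)
  all <- union(taxa, unname(neighbours))
  m <- diag(length(all))
  dimnames(m) <- list(all, all)
  for (src in names(neighbours)) {
    dst <- neighbours[[src]]
    m[src, src] <- 1 - leak
    m[src, dst] <- m[src, dst] + leak
  }
  m
}
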