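#' @import methods
NULL

## Central S4 containers. Slot access from user code goes through the
## accessors in AllGenerics.R / the module files, never via @.

#' DropletSet: raw per-droplet fluorescence amplitudes for one well
#'
#' One well of a one-dimensional (single channel) droplet digital PCR
#' experiment: a vector of end-point fluorescence amplitudes, one per
#' droplet. When the set was simulated, the Poisson ground truth
#' (occupancy >= 1) is retained in `trueLabels` so callers can be scored
#' against it.
#'
#' @slot wellId single character well identifier (e.g. "A01").
#' @slot channel integer channel index (1 or 2).
#' @slot amplitudes numeric vector of finite fluorescence amplitudes
#'   (arbitrary units), length >= 1.
#' @slot trueLabels logical vector parallel to `amplitudes` (TRUE =
#'   template-containing droplet) or length 0 when unknown.
#'
#' @seealso [simulateDroplets()], [callDroplets()]
#' @export
setClass("DropletSet",
  representation(
    wellId     = "character",
    channel    = "integer",
    amplitudes = "numeric",
    trueLabels = "logical"
  ),
  prototype(wellId = "A01", channel = 1L, trueLabels = logical(0))
)

setValidity("DropletSet", function(object) {
  msg <- character(0)
  if (length(object@wellId) != 1L) msg <- c(msg, "wellId must be length 1")
  if (length(object@channel) != 1L || !object@channel %in% c(1L, 2L))
    msg <- c(msg, "channel must be 1 or 2")
  if (length(object@amplitudes) < 1L)
    msg <- c(msg, "need at least one droplet")
  if (!all(is.finite(object@amplitudes)))
    msg <- c(msg, "amplitudes must be finite")
  if (length(object@trueLabels) > 0L &&
      length(object@trueLabels) != length(object@amplitudes))
    msg <- c(msg, "trueLabels must be empty or parallel to amplitudes")
  if (length(msg)) msg else TRUE
})

#' DropletCall: positive/negative classification of one well
#'
#' @slot nTotal,nPositive,nNegative droplet counts;
#'   nPositive + nNegative == nTotal.
#' @slot threshold amplitude threshold applied (droplets strictly above it
#'   are positive; droplets at the threshold are called negative).
#' @slot nRainReassigned number of intermediate-amplitude ("rain") droplets
#'   whose class was changed by the robust-centre reassignment step.
#' @slot qualityFlags character vector of quality codes, e.g. "unimodal",
#'   "constant_amplitude".
#'
#' @seealso [callDroplets()], [estimateLambda()]
#' @export
setClass("DropletCall",
  representation(
    nTotal          = "integer",
    nPositive       = "integer",
    nNegative       = "integer",
    threshold       = "numeric",
    nRainReassigned = "integer",
    qualityFlags    = "character"
  ),
  prototype(nRainReassigned = 0L, qualityFlags = character(0))
)

setValidity("DropletCall", function(object) {
  msg <- character(0)
  if (object@nPositive < 0L || object@nNegative < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (object@nPositive + object@nNegative != object@nTotal)
    msg <- c(msg, "nPositive + nNegative must equal nTotal")
  if (length(msg)) msg else TRUE
})

#' CopyEstimate: absolute target quantification for one well or pool
#'
#' Poisson copy estimate from a droplet call: `lambdaHat` is the mean
#' number of target copies per droplet, estimated as -ln(fraction of
#' negative droplets). `copiesPerReaction` (= lambdaHat * nTotal) is the
#' droplet-volume-independent quantity consumed by all downstream modules.
#'
#' @slot lambdaHat copies per droplet (>= 0).
#' @slot copiesPerReaction lambdaHat * nTotal.
#' @slot copiesPerUl copies per microlitre (depends on dropletVolume).
#' @slot ciLow,ciHigh confidence bounds on lambdaHat.
#' @slot dropletVolume droplet volume in nL used for copiesPerUl.
#' @slot nTotal,nNegative droplet counts behind the estimate.
#' @slot flags character codes: "not_detected" (zero positives),
#'   "saturated" never occurs here (saturation is an error), plus any
#'   flags propagated from the droplet call.
#'
#' @seealso [estimateLambda()], [poolWells()]
#' @export
setClass("CopyEstimate",
  representation(
    lambdaHat         = "numeric",
    copiesPerReaction = "numeric",
    copiesPerUl       = "numeric",
    ciLow             = "numeric",
    ciHigh            = "numeric",
    dropletVolume     = "numeric",
    nTotal            = "integer",
    nNegative         = "integer",
    flags             = "character"
  ),
  prototype(flags = character(0))
)

setValidity("CopyEstimate", function(object) {
  msg <- character(0)
  if (object@lambdaHat < 0) msg <- c(msg, "lambdaHat must be >= 0")
  if (!(object@ciLow <= object@lambdaHat + 1e-12 &&
        object@lambdaHat <= object@ciHigh + 1e-12))
    msg <- c(msg, "ciLow <= lambdaHat <= ciHigh required")
  if (abs(object@copiesPerReaction - object@lambdaHat * object@nTotal) >
      1e-6 * max(1, object@copiesPerReaction))
    msg <- c(msg, "copiesPerReaction must equal lambdaHat * nTotal")
  if (object@dropletVolume <= 0) msg <- c(msg, "dropletVolume must be > 0")
  if (length(msg)) msg else TRUE
})

#' SpeciesAssay: per-species constants for copy arithmetic
#'
#' Converts between DNA mass and genome copies for one species/assay:
#' the 1C genome size (picograms per haploid genome, C-value scale),
#' ploidy, the number of target sequences per haploid genome, and the
#' decision class the species carries in the read-classification scheme.
#'
#' @slot species species (or genus) name.
#' @slot genomeSize1C haploid (1C) genome size in pg; > 0.
#' @slot ploidy integer >= 1.
#' @slot targetCopiesPerHaploid integer >= 1; target sequences per 1C.
#' @slot classLabel one of "ingredient", "adulterant", "contaminant",
#'   "noise".
#'
#' @seealso [expectedCopies()], [copyFraction()], [loadAssayTable()]
#' @export
setClass("SpeciesAssay",
  representation(
    species                = "character",
    genomeSize1C           = "numeric",
    ploidy                 = "integer",
    targetCopiesPerHaploid = "integer",
    classLabel             = "character"
  ),
  prototype(ploidy = 2L, targetCopiesPerHaploid = 1L,
            classLabel = "ingredient")
)

.classLevels <- c("ingredient", "adulterant", "contaminant", "noise")

setValidity("SpeciesAssay", function(object) {
  msg <- character(0)
  if (length(object@species) != 1L || !nzchar(object@species))
    msg <- c(msg, "species must be a non-empty string")
  if (!(length(object@genomeSize1C) == 1L && is.finite(object@genomeSize1C) &&
        object@genomeSize1C > 0))
    msg <- c(msg, "genomeSize1C must be a positive number (pg)")
  if (object@ploidy < 1L) msg <- c(msg, "ploidy must be >= 1")
  if (object@targetCopiesPerHaploid < 1L)
    msg <- c(msg, "targetCopiesPerHaploid must be >= 1")
  if (!object@classLabel %in% .classLevels)
    msg <- c(msg, sprintf("classLabel must be one of %s",
                          paste(.classLevels, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' AccountingResult: outcome of the DNA accounting purity screen
#'
#' Compares the ddPCR-measured target copies of the declared species with
#' the copies expected if all fluorometrically measured DNA mass belonged
#' to that species. A measured value below the expected range indicates
#' foreign DNA diluting the declared species.
#'
#' @slot expectedCopies point expectation (copies per reaction).
#' @slot expectedLow,expectedHigh expected range after propagating the
#'   fluorometric mass uncertainty.
#' @slot measuredCopies ddPCR copies per reaction.
#' @slot ratio measured / expected (unitless).
#' @slot flag "below", "within" or "above".
#'
#' @seealso [account()], [expectedRange()]
#' @export
setClass("AccountingResult",
  representation(
    expectedCopies = "numeric",
    expectedLow    = "numeric",
    expectedHigh   = "numeric",
    measuredCopies = "numeric",
    ratio          = "numeric",
    flag           = "character"
  )
)

setValidity("AccountingResult", function(object) {
  msg <- character(0)
  if (!(object@expectedLow <= object@expectedCopies + 1e-9 &&
        object@expectedCopies <= object@expectedHigh + 1e-9))
    msg <- c(msg, "expectedLow <= expectedCopies <= expectedHigh required")
  ok <- switch(object@flag,
    below  = object@measuredCopies < object@expectedLow,
    within = object@measuredCopies >= object@expectedLow &&
             object@measuredCopies <= object@expectedHigh,
    above  = object@measuredCopies > object@expectedHigh,
    FALSE)
  if (!isTRUE(ok)) msg <- c(msg, "flag inconsistent with interval membership")
  if (length(msg)) msg else TRUE
})

#' CopyFraction: copy-number percentage of a non-declared species
#'
#' Genome-equivalent share of an adulterant relative to the declared
#' ingredient, from the two species' ddPCR copy estimates corrected for
#' target copies per haploid genome.
#'
#' @slot adulterant,ingredient species names.
#' @slot geAdulterant,geIngredient genome equivalents (copies per reaction
#'   divided by target copies per haploid genome).
#' @slot copyPct 100 * geAdulterant / (geAdulterant + geIngredient).
#' @slot massPct optional mass percentage (NA until [massFraction()] is
#'   applied).
#' @slot flags e.g. "trace_not_quantifiable", "not_detected".
#'
#' @seealso [copyFraction()], [massFraction()]
#' @export
setClass("CopyFraction",
  representation(
    adulterant   = "character",
    ingredient   = "character",
    geAdulterant = "numeric",
    geIngredient = "numeric",
    copyPct      = "numeric",
    massPct      = "numeric",
    flags        = "character"
  ),
  prototype(massPct = NA_real_, flags = character(0))
)

setValidity("CopyFraction", function(object) {
  msg <- character(0)
  if (is.finite(object@copyPct) &&
      (object@copyPct < 0 || object@copyPct > 100))
    msg <- c(msg, "copyPct must be in [0, 100]")
  tot <- object@geAdulterant + object@geIngredient
  if (is.finite(object@copyPct) && tot > 0) {
    want <- 100 * object@geAdulterant / tot
    if (abs(want - object@copyPct) > 1e-6)
      msg <- c(msg, "copyPct inconsistent with genome equivalents")
  }
  if (length(msg)) msg else TRUE
})

#' ReadTable: one sample's metabarcoding taxon read counts
#'
#' The per-sample output shape of a metabarcoding attribution pipeline:
#' for each reported taxon, its kingdom annotation and the number of
#' sequencing reads attributed to it.
#'
#' @slot sampleId sample identifier.
#' @slot reads data.frame with columns `taxon` (character, unique),
#'   `kingdom` (character) and `reads` (non-negative integers).
#'
#' @seealso [filterKingdom()], [readPercentages()], [classifyReads()]
#' @export
setClass("ReadTable",
  representation(sampleId = "character", reads = "data.frame")
)

setValidity("ReadTable", function(object) {
  msg <- character(0)
  df <- object@reads
  need <- c("taxon", "kingdom", "reads")
  if (!all(need %in% names(df)))
    msg <- c(msg, sprintf("reads must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(df$taxon)) msg <- c(msg, "taxon names must be unique")
    if (any(df$reads < 0) || any(df$reads != round(df$reads)))
      msg <- c(msg, "read counts must be non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' StudyReport: result of a seeded validation study
#'
#' @slot study study name.
#' @slot nReplicates number of Monte-Carlo replicates.
#' @slot seed RNG seed used.
#' @slot metrics named list of recorded metrics.
#' @slot tolerances named list of declared tolerances the metrics are
#'   judged against.
#' @slot passed logical; NA when the study was skipped (e.g. required
#'   input data unavailable).
#' @slot status free-text status ("ok", "skipped: ...").
#'
#' @seealso [studyLambdaRecovery()], [studyMixtureRecovery()],
#'   [studyTable5()]
#' @export
setClass("StudyReport",
  representation(
    study       = "character",
    nReplicates = "integer",
    seed        = "integer",
    metrics     = "list",
    tolerances  = "list",
    passed      = "logical",
    status      = "character"
  ),
  prototype(status = "ok")
)
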