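## Copy-percentage of a non-declared species: ddPCR measures target
## copies; dividing by the assay's target copies per haploid genome
## converts to genome equivalents, the common currency in which the two
## species are compared. Ploidy enters only if per-cell units are
## requested (one cell = ploidy haploid genomes).

#' Copy-number percentage of an adulterant in the declared matrix
#'
#' Converts each species' copies per reaction to genome equivalents
#' `GE = copiesPerReaction / targetCopiesPerHaploid` (divided further by
#' ploidy when `perCell = TRUE`) and reports
#' `copyPct = 100 * GE_adulterant / (GE_adulterant + GE_ingredient)`.
#'
#' Results with fewer than `lodPositives` positive droplets for the
#' adulterant are flagged `"trace_not_quantifiable"` (the percentage is
#' still reported for transparency). If both species are zero the
#' result is an explicit not-detected record with `copyPct = NA`.
#'
#' @param adulterantEst,ingredientEst [CopyEstimate-class] objects from
#'   the same DNA extract.
#' @param adulterantAssay,ingredientAssay [SpeciesAssay-class] objects.
#' @param perCell express genome equivalents per cell (divide by ploidy)
#'   instead of per haploid genome; default FALSE.
#' @param lodPositives limit of detection in adulterant positive
#'   droplets (default 3).
#' @return A [CopyFraction-class].
#' @examples
#' ad <- estimateLambda(dropletCall(20000, 100))
#' ing <- estimateLambda(dropletCall(20000, 9000))
#' copyFraction(ad, ing, speciesAssay("olive", 1.46),
#'              speciesAssay("oregano", 1.0))
#' @export
copyFraction <- function(adulterantEst, ingredientEst, adulterantAssay,
                         ingredientAssay, perCell = FALSE,
                         lodPositives = 3L) {
  stopifnot(is(adulterantEst, "CopyEstimate"),
            is(ingredientEst, "CopyEstimate"),
            is(adulterantAssay, "SpeciesAssay"),
            is(ingredientAssay, "SpeciesAssay"))
  ge <- function(est, assay) {
    g <- copiesPerReaction(est) / assay@targetCopiesPerHaploid
    if (perCell) g <- g / assay@ploidy
    g
  }
  geA <- ge(adulterantEst, adulterantAssay)
  geI <- ge(ingredientEst, ingredientAssay)
  flags <- character(0)
  if (geA + geI == 0) {
    return(new("CopyFraction", adulterant = adulterantAssay@species,
               ingredient = ingredientAssay@species, geAdulterant = 0,
               geIngredient = 0, copyPct = NA_real_,
               flags = "not_detected"))
  }
  nPosAd <- nTotal(adulterantEst) - nNegative(adulterantEst)
  if (nPosAd < lodPositives) flags <- c(flags, "trace_not_quantifiable")
  new("CopyFraction", adulterant = adulterantAssay@species,
      ingredient = ingredientAssay@species, geAdulterant = geA,
      geIngredient = geI, copyPct = 100 * geA / (geA + geI),
      flags = flags)
}

#' Convert a copy fraction to a DNA mass fraction
#'
#' Genome equivalents weighted by 1C genome size give each species' DNA
#' mass; the adulterant's share of the summed mass is the mass
#' percentage. With equal genome sizes, mass% equals copy%. This is the
#' exact inverse of [simulateMixtureCopies()] in the noise-free case,
#' enabling comparison with gravimetrically prepared mixtures.
#'
#' @param cf a [CopyFraction-class].
#' @param adulterantAssay,ingredientAssay [SpeciesAssay-class] providing
#'   the genome sizes.
#' @return The input [CopyFraction-class] with `massPct` filled in.
#' @examples
#' # copyPct 33.33% with adulterant genome twice the size -> massPct 50%
#' @export
massFraction <- function(cf, adulterantAssay, ingredientAssay) {
  stopifnot(is(cf, "CopyFraction"),
            is(adulterantAssay, "SpeciesAssay"),
            is(ingredientAssay, "SpeciesAssay"))
  if (!is.finite(cf@copyPct)) return(cf)
  mA <- cf@geAdulterant * adulterantAssay@genomeSize1C
  mI <- cf@geIngredient * ingredientAssay@genomeSize1C
  cf@massPct <- 100 * mA / (mA + mI)
  validObject(cf)
  cf
}

#' Tabulate copy fractions as a tidy data.frame
#'
#' One row per sample/adulterant pair: sample id, species, NGS read
#' percentage (if supplied) and ddPCR copy percentage — the paired
#' layout consumed by the concordance module.
#'
#' @param sampleIds character vector.
#' @param fractions list of [CopyFraction-class], parallel to sampleIds.
#' @param readPcts optional numeric vector of NGS read percentages.
#' @return data.frame with columns sample, species, read_pct, copy_pct,
#'   mass_pct, flags.
#' @export
copyFractionTable <- function(sampleIds, fractions, readPcts = NULL) {
  stopifnot(length(sampleIds) == length(fractions))
  if (is.null(readPcts)) readPcts <- rep(NA_real_, length(fractions))
  do.call(rbind, Map(function(id, cf, rp) {
    data.frame(sample = id, species = cf@adulterant, read_pct = rp,
               copy_pct = cf@copyPct, mass_pct = cf@massPct,
               flags = paste(cf@flags, collapse = ";"))
  }, sampleIds, fractions, readPcts))
}
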