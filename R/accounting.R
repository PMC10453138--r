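## "DNA accounting": if a sample labelled as a single species is pure,
## every picogram of its DNA belongs to that species, so the ddPCR
## target copy count must match the copy number implied by the
## fluorometric DNA mass and the species' genome size. A measurement
## below the expected range indicates foreign DNA.

#' Construct a SpeciesAssay
#'
#' @param species species (or genus) name.
#' @param genomeSize1C haploid (1C) genome size in pg (C-value scale).
#' @param ploidy integer ploidy (default 2).
#' @param targetCopiesPerHaploid target sequences per haploid genome
#'   (default 1).
#' @param classLabel decision class: "ingredient", "adulterant",
#'   "contaminant" or "noise".
#' @return A [SpeciesAssay-class].
#' @examples
#' speciesAssay("Olea europaea", 1.46, classLabel = "adulterant")
#' @export
speciesAssay <- function(species, genomeSize1C, ploidy = 2L,
                         targetCopiesPerHaploid = 1L,
                         classLabel = "ingredient") {
  new("SpeciesAssay", species = species, genomeSize1C = genomeSize1C,
      ploidy = as.integer(ploidy),
      targetCopiesPerHaploid = as.integer(targetCopiesPerHaploid),
      classLabel = classLabel)
}

#' Load a species assay table from TSV
#'
#' Expects tab-separated columns `species`, `genome_size_1c_pg`,
#'   `ploidy`, `target_copies_per_haploid`, `class`.
#' The packaged default (`system.file("extdata",
#' "species_assays_synthetic.tsv", package = "ddPurity")`) carries
#' synthetic, representative C-value-scale constants for the oregano
#' assay panel — suitable for simulation and demonstration, not a
#' transcription of any laboratory's calibration.
#'
#' @param path TSV path; default the packaged synthetic table.
#' @return named list of [SpeciesAssay-class], keyed by species.
#' @examples
#' assays <- loadAssayTable()
#' names(assays)
#' @export
loadAssayTable <- function(path = system.file("extdata",
                                              "species_assays_synthetic.tsv",
                                              package = "ddPurity")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "genome_size_1c_pg", "ploidy",
            "target_copies_per_haploid", "class")
  if (!all(need %in% names(df)))
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    speciesAssay(df$species[i], df$genome_size_1c_pg[i], df$ploidy[i],
                 df$target_copies_per_haploid[i], df$class[i]))
  names(out) <- df$species
  out
}

#' Expected target copies from fluorometric DNA mass
#'
#' The copy count if 100% of the template mass belonged to the assayed
#' species: `mass(ng) * 1000 / genomeSize1C(pg) * targetCopiesPerHaploid`.
#' Linear in mass, inversely proportional to genome size.
#'
#' @param templateMass DNA template mass per reaction in ng, > 0.
#' @param assay a [SpeciesAssay-class].
#' @return expected copies per reaction (numeric).
#' @examples
#' expectedCopies(18, speciesAssay("x", genomeSize1C = 1))  # 18000
#' @export
expectedCopies <- function(templateMass, assay) {
  stopifnot(is(assay, "SpeciesAssay"))
  if (!is.finite(templateMass) || templateMass <= 0)
    stop("templateMass must be > 0 ng")
  templateMass * 1000 / assay@genomeSize1C * assay@targetCopiesPerHaploid
}

#' Expected copy range from replicate fluorometry
#'
#' Propagates the fluorometric mass uncertainty through the (linear)
#' expected-copy formula: the range is `expectedCopies(mean - k*sd)` to
#' `expectedCopies(mean + k*sd)`, floored at zero mass. The sd is
#' normally that of the four replicate fluorometric measurements;
#' `k = 2` covers ~95% of pure samples under approximately normal
#' replicate noise.
#'
#' @param templateMassMean,templateMassSd mean and sd of replicate mass
#'   measurements (ng); sd >= 0.
#' @param assay a [SpeciesAssay-class].
#' @param k coverage multiplier, >= 0 (default 2).
#' @return named numeric `c(low, high)` in copies per reaction.
#' @examples
#' expectedRange(18, 1, speciesAssay("x", genomeSize1C = 1), k = 2)
#' @export
expectedRange <- function(templateMassMean, templateMassSd, assay, k = 2) {
  if (!is.finite(templateMassSd) || templateMassSd < 0)
    stop("templateMassSd must be >= 0")
  if (!is.finite(k) || k < 0) stop("k must be >= 0")
  loMass <- templateMassMean - k * templateMassSd
  hiMass <- templateMassMean + k * templateMassSd
  lo <- if (loMass <= 0) 0 else expectedCopies(loMass, assay)
  hi <- expectedCopies(hiMass, assay)
  c(low = lo, high = hi)
}

#' Screen a sample by DNA accounting
#'
#' Flags the measured ddPCR copies per reaction as "below", "within" or
#' "above" the expected range, and reports the measured/expected ratio.
#' On a sample whose DNA is a mass fraction f foreign (similar genome
#' sizes), the ratio is approximately 1 - f, so heavily adulterated
#' samples fall "below".
#'
#' @param measured a [CopyEstimate-class] (or a single numeric copies
#'   per reaction).
#' @param range numeric `c(low, high)` from [expectedRange()].
#' @param expected point expectation; default the midpoint of `range`
#'   (equals [expectedCopies()] at the mass mean, by linearity).
#' @return An [AccountingResult-class].
#' @examples
#' account(9000, expectedRange(18, 1, speciesAssay("x", 1)))
#' @export
account <- function(measured, range, expected = mean(range)) {
  m <- if (is(measured, "CopyEstimate")) copiesPerReaction(measured)
       else as.numeric(measured)
  stopifnot(length(range) == 2, range[1] <= range[2])
  flag <- if (m < range[1]) "below"
          else if (m > range[2]) "above" else "within"
  new("AccountingResult", expectedCopies = expected,
      expectedLow = unname(range[1]), expectedHigh = unname(range[2]),
      measuredCopies = m, ratio = m / expected, flag = flag)
}
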