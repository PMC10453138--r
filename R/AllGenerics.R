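#' Accessors for ddPurity S4 containers
#'
#' Small read-only accessors for the package's S4 classes; user code
#' should use these rather than reaching into slots.
#'
#' @param object a ddPurity S4 object.
#' @return The slot value (scalar or vector as documented per class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setGeneric("wellId", function(object) standardGeneric("wellId"))
#' @rdname accessors
#' @export
setGeneric("nTotal", function(object) standardGeneric("nTotal"))
#' @rdname accessors
#' @export
setGeneric("nPositive", function(object) standardGeneric("nPositive"))
#' @rdname accessors
#' @export
setGeneric("nNegative", function(object) standardGeneric("nNegative"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("qualityFlags", function(object) standardGeneric("qualityFlags"))
#' @rdname accessors
#' @export
setGeneric("lambdaHat", function(object) standardGeneric("lambdaHat"))
#' @rdname accessors
#' @export
setGeneric("copiesPerReaction",
           function(object) standardGeneric("copiesPerReaction"))
#' @rdname accessors
#' @export
setGeneric("confint95", function(object) standardGeneric("confint95"))
#' @rdname accessors
#' @export
setGeneric("copyPct", function(object) standardGeneric("copyPct"))
#' @rdname accessors
#' @export
setGeneric("massPct", function(object) standardGeneric("massPct"))
#' @rdname accessors
#' @export
setGeneric("accountingFlag", function(object) standardGeneric("accountingFlag"))
#' @rdname accessors
#' @export
setGeneric("readCounts", function(object) standardGeneric("readCounts"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))
#' @rdname accessors
#' @export
setGeneric("studyPassed", function(object) standardGeneric("studyPassed"))

#' @rdname accessors
setMethod("amplitudes", "DropletSet", function(object) object@amplitudes)
#' @rdname accessors
setMethod("trueLabels", "DropletSet", function(object) object@trueLabels)
#' @rdname accessors
setMethod("wellId", "DropletSet", function(object) object@wellId)
#' @rdname accessors
setMethod("nTotal", "DropletSet", function(object) length(object@amplitudes))

#' @rdname accessors
setMethod("nTotal", "DropletCall", function(object) object@nTotal)
#' @rdname accessors
setMethod("nPositive", "DropletCall", function(object) object@nPositive)
#' @rdname accessors
setMethod("nNegative", "DropletCall", function(object) object@nNegative)
#' @rdname accessors
setMethod("threshold", "DropletCall", function(object) object@threshold)
#' @rdname accessors
setMethod("qualityFlags", "DropletCall", function(object) object@qualityFlags)

#' @rdname accessors
setMethod("lambdaHat", "CopyEstimate", function(object) object@lambdaHat)
#' @rdname accessors
setMethod("copiesPerReaction", "CopyEstimate",
          function(object) object@copiesPerReaction)
#' @rdname accessors
setMethod("confint95", "CopyEstimate",
          function(object) c(low = object@ciLow, high = object@ciHigh))
#' @rdname accessors
setMethod("nTotal", "CopyEstimate", function(object) object@nTotal)
#' @rdname accessors
setMethod("nNegative", "CopyEstimate", function(object) object@nNegative)
#' @rdname accessors
setMethod("qualityFlags", "CopyEstimate", function(object) object@flags)

#' @rdname accessors
setMethod("copyPct", "CopyFraction", function(object) object@copyPct)
#' @rdname accessors
setMethod("massPct", "CopyFraction", function(object) object@massPct)
#' @rdname accessors
setMethod("qualityFlags", "CopyFraction", function(object) object@flags)

#' @rdname accessors
setMethod("accountingFlag", "AccountingResult", function(object) object@flag)

#' @rdname accessors
setMethod("readCounts", "ReadTable", function(object) object@reads)
#' @rdname accessors
setMethod("sampleId", "ReadTable", function(object) object@sampleId)

#' @rdname accessors
setMethod("metrics", "StudyReport", function(object) object@metrics)
#' @rdname accessors
setMethod("studyPassed", "StudyReport", function(object) object@passed)

setMethod("show", "DropletSet", function(object) {
  cat(sprintf("DropletSet well %s channel %d: %d droplets%s\n",
              object@wellId, object@channel, length(object@amplitudes),
              if (length(object@trueLabels)) " (with ground truth)" else ""))
  a <- object@amplitudes
  cat(sprintf("  amplitude range [%.1f, %.1f], median %.1f\n",
              min(a), max(a), stats::median(a)))
})

setMethod("show", "DropletCall", function(object) {
  cat(sprintf(
    "DropletCall: %d droplets, %d positive / %d negative (threshold %.2f)\n",
    object@nTotal, object@nPositive, object@nNegative, object@threshold))
  if (object@nRainReassigned > 0L)
    cat(sprintf("  rain reassigned: %d\n", object@nRainReassigned))
  if (length(object@qualityFlags))
    cat("  flags:", paste(object@qualityFlags, collapse = ", "), "\n")
})

setMethod("show", "CopyEstimate", function(object) {
  cat(sprintf(
    "CopyEstimate: lambda = %.4g copies/droplet [%.4g, %.4g]\n",
    object@lambdaHat, object@ciLow, object@ciHigh))
  cat(sprintf("  %.4g copies/reaction, %.4g copies/uL (%d droplets)\n",
              object@copiesPerReaction, object@copiesPerUl, object@nTotal))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "SpeciesAssay", function(object) {
  cat(sprintf(
    "SpeciesAssay %s [%s]: 1C = %.3g pg, ploidy %d, %d target(s)/1C\n",
    object@species, object@classLabel, object@genomeSize1C, object@ploidy,
    object@targetCopiesPerHaploid))
})

setMethod("show", "AccountingResult", function(object) {
  cat(sprintf(
    "AccountingResult: measured %.4g vs expected %.4g [%.4g, %.4g] -> %s (ratio %.3f)\n",
    object@measuredCopies, object@expectedCopies, object@expectedLow,
    object@expectedHigh, object@flag, object@ratio))
})

setMethod("show", "CopyFraction", function(object) {
  cat(sprintf("CopyFraction %s in %s: copy%% = %.4f",
              object@adulterant, object@ingredient, object@copyPct))
  if (is.finite(object@massPct)) cat(sprintf(", mass%% = %.4f", object@massPct))
  cat("\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ReadTable", function(object) {
  cat(sprintf("ReadTable sample %s: %d taxa, %d reads\n",
              object@sampleId, nrow(object@reads), sum(object@reads$reads)))
})

setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport '%s' (%d replicates, seed %d): %s\n",
              object@study, object@nReplicates, object@seed,
              if (is.na(object@passed)) object@status
              else if (object@passed) "PASS" else "FAIL"))
  for (nm in names(object@metrics)) {
    v <- object@metrics[[nm]]
    if (is.numeric(v) && length(v) == 1L)
      cat(sprintf("  %s = %.5g\n", nm, v))
  }
})
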