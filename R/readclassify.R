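## Metabarcoding read-table post-processing: kingdom filter, read
## percentages, and the decision rules that turn taxon classes into
## ddPCR confirmation actions — adulterants are always confirmed when
## any read is present; contaminants only at elevated read% (> 5%).

#' Construct a ReadTable
#'
#' @param taxa character vector of unique taxon names.
#' @param reads non-negative integer read counts.
#' @param kingdom kingdom annotations (recycled).
#' @param sampleId sample identifier.
#' @return A [ReadTable-class].
#' @examples
#' readTable(c("Origanum vulgare", "Olea europaea"), c(900, 100))
#' @export
readTable <- function(taxa, reads, kingdom = "Plantae", sampleId = "S1") {
  new("ReadTable", sampleId = sampleId,
      reads = data.frame(taxon = taxa, kingdom = rep_len(kingdom,
                                                         length(taxa)),
                         reads = as.integer(reads),
                         stringsAsFactors = FALSE))
}

.normTaxon <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Keep only rows of one kingdom
#'
#' Removes fungi, bacteria, animals etc. from a raw attribution table,
#' leaving (by default) only Plantae. Counts are unchanged and the
#' operation is idempotent. An empty result is allowed but warned
#' about.
#'
#' @param table a [ReadTable-class].
#' @param kingdom kingdom to retain (default "Plantae").
#' @return A [ReadTable-class] with only the requested kingdom.
#' @examples
#' rt <- readTable(c("A", "B"), c(5, 7), kingdom = c("Plantae", "Fungi"))
#' filterKingdom(rt)
#' @export
filterKingdom <- function(table, kingdom = "Plantae") {
  stopifnot(is(table, "ReadTable"))
  df <- readCounts(table)
  keep <- .normTaxon(df$kingdom) == .normTaxon(kingdom)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out))
    warning(sprintf("no %s rows retained in sample %s", kingdom,
                    sampleId(table)))
  new("ReadTable", sampleId = sampleId(table), reads = out)
}

#' Read percentages per taxon
#'
#' `read_pct = 100 * reads / total`. The default denominator is the sum
#' over the retained (e.g. post-Plantae-filter) rows, so percentages sum
#' to exactly 100; `denominator = "all"` divides by the total of an
#' unfiltered table instead (the convention of attribution pipelines
#' that report against all reads including unlisted ones).
#'
#' @param table a [ReadTable-class].
#' @param denominator "retained" (default) or "all".
#' @param unfiltered the pre-filter [ReadTable-class]; required when
#'   `denominator = "all"`.
#' @return data.frame with columns taxon, kingdom, reads, read_pct,
#'   plus attribute `"denominator"` recording the convention used.
#' @examples
#' readPercentages(readTable(c("A", "B"), c(50, 50)))
#' @export
readPercentages <- function(table, denominator = c("retained", "all"),
                            unfiltered = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(is(table, "ReadTable"))
  df <- readCounts(table)
  total <- if (denominator == "retained") sum(df$reads) else {
    if (is.null(unfiltered))
      stop("denominator = \"all\" requires the unfiltered table")
    sum(readCounts(unfiltered)$reads)
  }
  if (total <= 0) stop("zero total reads in chosen denominator")
  df$read_pct <- 100 * df$reads / total
  attr(df, "denominator") <- denominator
  df
}

#' Load a taxon -> class map
#'
#' Reads a two-column TSV (`taxon`, `class`) into a case-normalized
#' lookup used by [classifyReads()]. Classes must be in
#' ingredient / adulterant / contaminant / noise (case-insensitive).
#' The packaged default is the oregano survey scheme: *Origanum*
#' species as ingredient (marjoram excepted — a known bulking agent),
#' olive, myrtle, cistus and marjoram as adulterants, weeds and
#' co-processed spices as contaminants, and geographically implausible
#' attributions as noise.
#'
#' @param path TSV path; default the packaged map.
#' @return data.frame with columns taxon, class (normalized lower case)
#'   and class "ddPurityClassMap".
#' @examples
#' cm <- loadClassMap()
#' subset(cm, class == "adulterant")
#' @export
loadClassMap <- function(path = system.file("extdata", "class_map.tsv",
                                            package = "ddPurity")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "class") %in% names(df)))
    stop("class map must have columns taxon, class")
  df$class <- tolower(trimws(df$class))
  bad <- setdiff(unique(df$class), .classLevels)
  if (length(bad))
    stop("malformed class label(s): ", paste(bad, collapse = ", "))
  df$taxon_norm <- .normTaxon(df$taxon)
  class(df) <- c("ddPurityClassMap", "data.frame")
  df
}

## Resolve one taxon against the map: exact normalized match, then a
## genus-level "spp." wildcard, then abbreviated-genus resolution
## ("O. majorana" -> unique map species with matching initial+epithet).
.lookupClass <- function(taxon, map) {
  tn <- .normTaxon(taxon)
  i <- match(tn, map$taxon_norm)
  if (!is.na(i)) return(map$class[i])
  words <- strsplit(tn, " ", fixed = TRUE)[[1]]
  genus <- words[1]
  i <- match(paste(genus, "spp."), map$taxon_norm)
  if (!is.na(i)) return(map$class[i])
  if (grepl("^[a-z]\\.$", genus) && length(words) >= 2) {
    initial <- substr(genus, 1, 1)
    parts <- strsplit(map$taxon_norm, " ", fixed = TRUE)
    hit <- which(vapply(parts, function(p)
      length(p) >= 2 && substr(p[1], 1, 1) == initial &&
        p[2] == words[2], logical(1)))
    if (length(hit) == 1L) return(map$class[hit])
  }
  NA_character_
}

#' Apply the classification and confirmation decision rules
#'
#' Attaches a class to every taxon (unknown taxa default to "noise" and
#' are reported via a message) and the ddPCR confirmation action:
#' adulterants with at least one read are always confirmed
#' (`confirm_ddPCR`); contaminants only when their read percentage
#' strictly exceeds `threshold` (default 5%, with `<= 5%` treated as the
#' low-read regime where species attribution may simply be wrong);
#' ingredients and noise are never confirmed.
#'
#' @param pct data.frame from [readPercentages()].
#' @param classMap a [loadClassMap()] object.
#' @param threshold contaminant read% confirmation threshold (default 5;
#'   strictly greater-than).
#' @return The input data.frame with `class` and `action` columns.
#' @examples
#' rt <- readTable(c("Olea europaea", "Origanum vulgare"), c(4, 996))
#' classifyReads(readPercentages(rt), loadClassMap())
#' @export
classifyReads <- function(pct, classMap, threshold = 5) {
  stopifnot(inherits(classMap, "ddPurityClassMap"), threshold > 0)
  cls <- vapply(pct$taxon, .lookupClass, character(1), map = classMap)
  unknown <- pct$taxon[is.na(cls)]
  if (length(unknown))
    message("taxa not in class map, defaulting to noise: ",
            paste(unknown, collapse = ", "))
  cls[is.na(cls)] <- "noise"
  pct$class <- cls
  pct$action <- ifelse(
    cls == "adulterant" & pct$reads >= 1, "confirm_ddPCR",
    ifelse(cls == "contaminant" & pct$read_pct > threshold,
           "confirm_ddPCR", "none"))
  pct
}

#' The ESA quality-control material read-count fixture
#'
#' The packaged read-count table observed by metabarcoding on the
#' European Spice Association oregano quality-control material — a
#' gravimetric blend of oregano (44%), olive, myrtle, cistus, sumac,
#' hazel (10% each), thyme (5%) and bindweed (1%). Sumac yields zero
#' reads (a known extraction failure mode for that matrix), while the
#' 1% bindweed is heavily over-represented among reads.
#'
#' @return A [ReadTable-class] (sample id "ESA-QC").
#' @examples
#' esaReadTable()
#' @export
esaReadTable <- function() {
  path <- system.file("extdata", "esa_reads.tsv", package = "ddPurity")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("ReadTable", sampleId = "ESA-QC",
      reads = data.frame(taxon = df$taxon, kingdom = df$kingdom,
                         reads = as.integer(df$reads),
                         stringsAsFactors = FALSE))
}

#' Declared mass fractions of the ESA quality-control material
#'
#' @return named numeric vector of declared mass percentages.
#' @export
esaDeclaredMass <- function() {
  c("Origanum vulgare" = 22, "Origanum onites" = 22,
    "Olea europaea" = 10, "Myrtus communis" = 10, "Cistus spp." = 10,
    "Rhus coriaria" = 10, "Corylus spp." = 10, "Thymus spp." = 5,
    "Convolvulus arvensis" = 1)
}
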