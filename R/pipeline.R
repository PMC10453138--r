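## End-to-end orchestration of the authentication workflow on a
## (synthetic) cohort: DNA-accounting purity screen for every sample,
## metabarcoding classification, ddPCR copy-percentage quantification
## for flagged taxa with an available assay, then cross-sample
## concordance between read% and copy%.

#' @importFrom rlang hash .data
NULL

#' Pipeline configuration
#'
#' Collects every tunable the pipeline applies, so a run is fully
#' described by (config, cohort, seed).
#'
#' @param assays named list of [SpeciesAssay-class] (see
#'   [loadAssayTable()]).
#' @param classMap a [loadClassMap()] object.
#' @param ingredient declared species name; must have an assay.
#' @param templateMass DNA template mass per reaction (ng, default 18).
#' @param fluorCv coefficient of variation of one fluorometric
#'   measurement (default 0.05).
#' @param accountingK expected-range coverage multiplier (default 2).
#' @param readThreshold contaminant confirmation read% threshold
#'   (default 5, strictly greater-than).
#' @param nDroplets droplets per simulated well (default 20000).
#' @param negMean,posMean,negSd,posSd amplitude populations for
#'   simulated wells.
#' @param totalReads reads per simulated sample (default 10000).
#' @param readBias,readDropout,misattribution passed to
#'   [readSimParams()].
#' @param seed integer seed making the whole run reproducible.
#' @param outputDir directory for result CSVs and the manifest; NULL
#'   returns results in memory only.
#' @return list of class "ddPurityConfig".
#' @export
pipelineConfig <- function(assays = loadAssayTable(),
                           classMap = loadClassMap(),
                           ingredient = "Origanum vulgare",
                           templateMass = 18, fluorCv = 0.05,
                           accountingK = 2, readThreshold = 5,
                           nDroplets = 20000L, negMean = 2000,
                           posMean = 8000, negSd = 200, posSd = 300,
                           totalReads = 10000L, readBias = numeric(0),
                           readDropout = numeric(0),
                           misattribution = NULL, seed = 1L,
                           outputDir = NULL) {
  stopifnot(ingredient %in% names(assays), accountingK > 0,
            readThreshold > 0, templateMass > 0, fluorCv >= 0)
  structure(list(assays = assays, classMap = classMap,
                 ingredient = ingredient, templateMass = templateMass,
                 fluorCv = fluorCv, accountingK = accountingK,
                 readThreshold = readThreshold,
                 nDroplets = as.integer(nDroplets), negMean = negMean,
                 posMean = posMean, negSd = negSd, posSd = posSd,
                 totalReads = as.integer(totalReads),
                 readBias = readBias, readDropout = readDropout,
                 misattribution = misattribution,
                 seed = as.integer(seed), outputDir = outputDir),
            class = "ddPurityConfig")
}

.matchAssay <- function(taxon, assays) {
  nm <- names(assays)
  i <- match(.normTaxon(taxon), .normTaxon(nm))
  if (!is.na(i)) return(assays[[i]])
  genus <- strsplit(.normTaxon(taxon), " ")[[1]][1]
  i <- match(paste(genus, "spp."), .normTaxon(nm))
  if (!is.na(i)) return(assays[[i]])
  NULL
}

.simWell <- function(copies, config) {
  callDroplets(simulateDroplets(dropletSimParams(
    nDroplets = config$nDroplets,
    lambdaTrue = copies / config$nDroplets,
    negMean = config$negMean, posMean = config$posMean,
    negSd = config$negSd, posSd = config$posSd)))
}

#' Run the full authentication pipeline on a cohort
#'
#' For each sample (a [mixtureSpec()] describing the true composition):
#' simulates the fluorometric replicates and the ingredient ddPCR well,
#' screens purity by DNA accounting; simulates and classifies the
#' metabarcoding read table; for every taxon flagged `confirm_ddPCR`
#' with an available non-ingredient assay, simulates the confirmatory
#' well and computes the ddPCR copy percentage (taxa without an assay
#' yield a "no assay available" record and a warning). Finally computes
#' per-species concordance between read% and copy% across the cohort.
#'
#' @param cohort named list of [mixtureSpec()] objects (names are
#'   sample ids).
#' @param config a [pipelineConfig()].
#' @return list with data.frames `accounting`, `classified`,
#'   `copyFractions`, `concordancePoints`, `concordance` and list
#'   `manifest`; written as CSV/JSON under `config$outputDir` when set.
#' @examples
#' cfg <- pipelineConfig(seed = 42, nDroplets = 2000, totalReads = 2000)
#' cohort <- list(S1 = mixtureSpec(c("Origanum vulgare" = 1)))
#' res <- runPipeline(cohort, cfg)
#' res$accounting
#' @export
runPipeline <- function(cohort, config) {
  stopifnot(inherits(config, "ddPurityConfig"), length(cohort) >= 1)
  ids <- names(cohort)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(cohort))
  ingAssay <- config$assays[[config$ingredient]]

  withr::with_seed(config$seed, {
    accounting <- list(); classified <- list(); cfr <- list()
    points <- list(); noAssay <- list()
    for (k in seq_along(cohort)) {
      id <- ids[[k]]; spec <- cohort[[k]]
      trueCopies <- simulateMixtureCopies(spec, config$assays)
      fl <- simulateFluorometry(config$templateMass, config$fluorCv)

      ingCopies <- if (config$ingredient %in% names(trueCopies))
        trueCopies[[config$ingredient]] else 0
      ingEst <- estimateLambda(.simWell(ingCopies, config))
      rng <- expectedRange(fl$mean, fl$sd, ingAssay,
                           k = config$accountingK)
      acc <- account(ingEst, rng,
                     expected = expectedCopies(fl$mean, ingAssay))
      accounting[[id]] <- data.frame(
        sample = id, dna_mass_ng = fl$mean, dna_mass_sd = fl$sd,
        measured_copies = copiesPerReaction(ingEst),
        expected_copies = acc@expectedCopies,
        expected_low = acc@expectedLow, expected_high = acc@expectedHigh,
        ratio = acc@ratio, flag = accountingFlag(acc))

      rt <- simulateReadTable(
        trueCopies,
        readSimParams(totalReads = config$totalReads,
                      bias = config$readBias,
                      dropout = config$readDropout,
                      misattribution = config$misattribution),
        sampleId = id)
      pct <- readPercentages(filterKingdom(rt))
      cls <- suppressMessages(
        classifyReads(pct, config$classMap,
                      threshold = config$readThreshold))
      cls <- cbind(sample = id, cls)
      classified[[id]] <- cls

      flagged <- cls[cls$action == "confirm_ddPCR", , drop = FALSE]
      for (j in seq_len(nrow(flagged))) {
        taxon <- flagged$taxon[j]
        assay <- .matchAssay(taxon, config$assays)
        if (is.null(assay) ||
            .normTaxon(assay@species) ==
            .normTaxon(config$ingredient)) {
          if (is.null(assay)) {
            warning(sprintf("no assay available for flagged taxon %s (sample %s)",
                            taxon, id), call. = FALSE)
            noAssay[[length(noAssay) + 1L]] <-
              data.frame(sample = id, taxon = taxon,
                         status = "no assay available")
          }
          next
        }
        adCopies <- if (assay@species %in% names(trueCopies))
          trueCopies[[assay@species]] else 0
        adEst <- estimateLambda(.simWell(adCopies, config))
        cf <- copyFraction(adEst, ingEst, assay, ingAssay)
        cf <- massFraction(cf, assay, ingAssay)
        cfr[[length(cfr) + 1L]] <-
          cbind(copyFractionTable(id, list(cf), flagged$read_pct[j]))
        points[[length(points) + 1L]] <-
          data.frame(sample = id, species = assay@species,
                     read_pct = flagged$read_pct[j],
                     copy_pct = copyPct(cf))
      }
    }

    pts <- if (length(points)) do.call(rbind, points)
           else data.frame(sample = character(0), species = character(0),
                           read_pct = numeric(0), copy_pct = numeric(0))
    conc <- if (nrow(pts) >= 2) concordanceTable(pts) else NULL
    manifest <- list(
      package = "ddPurity",
      version = as.character(utils::packageVersion("ddPurity")),
      seed = config$seed, n_samples = length(cohort),
      ingredient = config$ingredient,
      thresholds = list(accounting_k = config$accountingK,
                        read_pct_confirm = config$readThreshold,
                        droplet_floor = 100L),
      config_hash = rlang::hash(config[setdiff(names(config),
                                               "outputDir")]))
    out <- list(accounting = do.call(rbind, accounting),
                classified = do.call(rbind, classified),
                copyFractions = if (length(cfr)) do.call(rbind, cfr)
                                else NULL,
                noAssay = if (length(noAssay)) do.call(rbind, noAssay)
                          else NULL,
                concordancePoints = pts, concordance = conc,
                manifest = manifest)
    if (!is.null(config$outputDir)) {
      dir.create(config$outputDir, recursive = TRUE,
                 showWarnings = FALSE)
      w <- function(df, f) if (!is.null(df))
        utils::write.csv(df, file.path(config$outputDir, f),
                         row.names = FALSE)
      w(out$accounting, "accounting.csv")
      w(out$classified, "classified.csv")
      w(out$copyFractions, "copy_fractions.csv")
      w(out$concordancePoints, "concordance_points.csv")
      w(out$concordance, "concordance.csv")
      jsonlite::write_json(manifest,
                           file.path(config$outputDir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    out
  })
}

#' Write a self-contained demo dataset
#'
#' Emulates the quality-control use case: the 9-species ESA-style
#' gravimetric mixture as a YAML spec, the packaged quality-control
#' read-count table (including the zero-read sumac row), the synthetic
#' assay table, and one simulated ddPCR amplitude CSV. The demo runs
#' end-to-end through [runPipeline()].
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the simulated well.
#' @return named list of file paths, invisibly.
#' @examples
#' \dontrun{makeDemo(tempfile("demo"), seed = 1)}
#' @export
makeDemo <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mix <- esaDeclaredMass() / 100
  stopifnot(abs(sum(mix) - 1) < 1e-9)
  mixPath <- file.path(dir, "mixture_esa.yaml")
  yaml::write_yaml(list(total_template_mass_ng = 18,
                        components = as.list(mix)), mixPath)
  rt <- esaReadTable()
  readsPath <- file.path(dir, "esa_reads.tsv")
  utils::write.table(cbind(sample = sampleId(rt), readCounts(rt)),
                     readsPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  assayPath <- file.path(dir, "species_assays_synthetic.tsv")
  file.copy(system.file("extdata", "species_assays_synthetic.tsv",
                        package = "ddPurity"), assayPath,
            overwrite = TRUE)
  ds <- simulateDroplets(dropletSimParams(lambdaTrue = 0.5,
                                          seed = seed))
  ampPath <- file.path(dir, "amplitudes_demo.csv")
  writeAmplitudeCsv(ds, ampPath)
  invisible(list(mixture = mixPath, reads = readsPath,
                 assays = assayPath, amplitudes = ampPath))
}

#' Read a mixture spec from YAML
#'
#' Parses the on-disk mixture format written by [makeDemo()]
#' (`total_template_mass_ng` plus a `components` map of species to mass
#' fraction).
#'
#' @param path YAML file path.
#' @param seed optional seed stored in the spec.
#' @return A [mixtureSpec()].
#' @export
readMixtureYaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  mixtureSpec(unlist(y$components),
              totalTemplateMass = y$total_template_mass_ng, seed = seed)
}
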