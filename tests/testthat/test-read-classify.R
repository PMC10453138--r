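test_that("kingdom filter removes non-plant rows and is idempotent", {
  rt <- readTable(c("Origanum vulgare", "Aspergillus niger", "Homo sapiens"),
                  c(900, 80, 20),
                  kingdom = c("Plantae", "Fungi", "Animalia"))
  f1 <- filterKingdom(rt)
  expect_identical(readCounts(f1)$taxon, "Origanum vulgare")
  expect_identical(readCounts(f1)$reads, 900L)  # counts unchanged
  expect_identical(readCounts(filterKingdom(f1)), readCounts(f1))

  allPlant <- readTable(c("A", "B"), c(1, 2))
  expect_identical(readCounts(filterKingdom(allPlant)),
                   readCounts(allPlant))
  expect_warning(filterKingdom(readTable("X", 5, kingdom = "Fungi")),
                 "no Plantae rows")
})

test_that("read percentages use the documented denominator", {
  expect_equal(readPercentages(readTable(c("A", "B"), c(50, 50)))$read_pct,
               c(50, 50))
  expect_equal(readPercentages(readTable(c("A", "B"), c(1, 0)))$read_pct,
               c(100, 0))
  expect_error(readPercentages(readTable(c("A", "B"), c(0, 0))),
               "zero total")

  # percentages sum to exactly 100 for the retained denominator
  p <- readPercentages(readTable(letters[1:5], c(3, 7, 11, 13, 17)))
  expect_equal(sum(p$read_pct), 100, tolerance = 1e-9)

  # "all" denominator uses the unfiltered total
  raw <- readTable(c("A", "B", "F"), c(50, 25, 25),
                   kingdom = c("Plantae", "Plantae", "Fungi"))
  filt <- filterKingdom(raw)
  pAll <- readPercentages(filt, denominator = "all", unfiltered = raw)
  expect_equal(pAll$read_pct, c(50, 25))
  expect_error(readPercentages(filt, denominator = "all"), "unfiltered")
})

test_that("quality-control fixture reproduces the printed arithmetic", {
  rt <- esaReadTable()
  df <- readCounts(rt)
  expect_identical(sum(df$reads), 13270L)  # listed rows total
  expect_identical(df$reads[df$taxon == "Rhus coriaria"], 0L)
  p <- readPercentages(filterKingdom(rt))
  # bindweed: 3771 / 13270 reads against the retained total
  expect_equal(p$read_pct[p$taxon == "Convolvulus spp."],
               100 * 3771 / 13270, tolerance = 1e-9)
  expect_equal(round(p$read_pct[p$taxon == "Convolvulus spp."], 1), 28.4)
})

test_that("class map lookup normalizes case and falls back to genus", {
  cm <- loadClassMap()
  expect_identical(ddPurity:::.lookupClass("Origanum vulgare", cm),
                   "ingredient")
  expect_identical(ddPurity:::.lookupClass("Origanum majorana", cm),
                   "adulterant")
  expect_identical(ddPurity:::.lookupClass("Chenopodium album", cm),
                   "contaminant")
  expect_identical(ddPurity:::.lookupClass("  chenopodium   ALBUM ", cm),
                   "contaminant")
  # genus fallback through the "spp." wildcard
  expect_identical(ddPurity:::.lookupClass("Cistus ladanifer", cm),
                   "adulterant")
  # abbreviated genus resolves by initial + epithet
  expect_identical(ddPurity:::.lookupClass("O. majorana", cm),
                   "adulterant")
  expect_true(is.na(ddPurity:::.lookupClass("Zea mays", cm)))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tclass", "X\tweird"), bad)
  expect_error(loadClassMap(bad), "malformed class label")
})

test_that("decision rules gate ddPCR confirmation correctly", {
  cm <- loadClassMap()
  rt <- readTable(c("Olea europaea", "Convolvulus spp.", "Origanum vulgare",
                    "Panax stipuleanatus", "Chenopodium album"),
                  c(4, 30, 900, 16, 60))
  cls <- classifyReads(readPercentages(rt), cm)
  row <- function(t) cls[cls$taxon == t, ]
  # adulterant at 0.4%: still confirmed
  expect_identical(row("Olea europaea")$class, "adulterant")
  expect_identical(row("Olea europaea")$action, "confirm_ddPCR")
  # contaminant at 3%: below the 5% rule, no action
  expect_identical(row("Convolvulus spp.")$action, "none")
  # contaminant ~5.9%: above the strictly-greater-than 5% rule
  expect_identical(row("Chenopodium album")$action, "confirm_ddPCR")
  # noise never confirmed regardless of read%
  expect_identical(row("Panax stipuleanatus")$class, "noise")
  expect_identical(row("Panax stipuleanatus")$action, "none")
  expect_identical(row("Origanum vulgare")$action, "none")

  # exactly 5% does not fire (strict inequality)
  rt5 <- readTable(c("Convolvulus spp.", "Origanum vulgare"), c(5, 95))
  cls5 <- classifyReads(readPercentages(rt5), cm)
  expect_identical(cls5$action[cls5$taxon == "Convolvulus spp."], "none")

  # unknown taxa default to noise with a message
  expect_message(
    classifyReads(readPercentages(readTable(c("Zea mays", "A b"),
                                            c(5, 5))), cm),
    "defaulting to noise")
})

test_that("fixture + map yield the expected adulterant detection set", {
  cls <- suppressMessages(
    classifyReads(readPercentages(filterKingdom(esaReadTable())),
                  loadClassMap()))
  detected <- sort(cls$taxon[cls$class == "adulterant" & cls$reads >= 1])
  expect_identical(detected, sort(c("Cistus spp.", "Myrtus communis",
                                    "Olea europaea", "O. majorana")))
  # every detected adulterant is sent to ddPCR confirmation
  expect_true(all(cls$action[cls$class == "adulterant" &
                             cls$reads >= 1] == "confirm_ddPCR"))
  # sumac: declared 10% by mass, zero reads
  expect_identical(cls$reads[cls$taxon == "Rhus coriaria"], 0L)
})

test_that("classification is order-independent", {
  cm <- loadClassMap()
  rt <- esaReadTable()
  df <- readCounts(rt)
  perm <- withr::with_seed(1, sample(nrow(df)))
  rtp <- new("ReadTable", sampleId = "ESA-QC", reads = df[perm, ])
  a <- suppressMessages(classifyReads(readPercentages(filterKingdom(rt)),
                                      cm))
  b <- suppressMessages(classifyReads(readPercentages(filterKingdom(rtp)),
                                      cm))
  b <- b[match(a$taxon, b$taxon), ]
  expect_equal(a$read_pct, b$read_pct)
  expect_identical(a$class, b$class)
  expect_identical(a$action, b$action)
})
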