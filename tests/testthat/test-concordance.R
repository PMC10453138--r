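test_that("concordance statistics on exact and degenerate data", {
  pts <- data.frame(read_pct = c(1, 2, 3, 4, 5),
                    copy_pct = 2 * c(1, 2, 3, 4, 5))
  # copy% ~ read%; lm warns about the perfect fit, which is the point
  s <- suppressWarnings(concordanceStats(pts))
  expect_equal(s$pearson_r, 1)
  expect_equal(s$slope, 2)
  expect_equal(s$intercept, 0)
  # p-values for correlation and slope coincide in simple regression
  sn <- concordanceStats(data.frame(read_pct = c(1, 3, 2, 5, 4),
                                    copy_pct = c(2, 5, 5, 9, 8)))
  expect_equal(sn$p_value, sn$p_value_slope, tolerance = 1e-12)

  # constant response: slope 0, r undefined
  sc <- concordanceStats(data.frame(read_pct = c(2, 2, 2),
                                    copy_pct = c(1, 5, 9)),
                         response = "read_pct")
  expect_true(sc$degenerate)
  expect_equal(sc$slope, 0)
  expect_true(is.na(sc$pearson_r))
  # constant predictor: slope undefined
  sp <- concordanceStats(data.frame(read_pct = c(2, 2, 2),
                                    copy_pct = c(1, 5, 9)))
  expect_true(is.na(sp$slope))

  expect_error(concordanceStats(data.frame(read_pct = 1, copy_pct = 1)),
               "at least 2")
})

test_that("r is affine-invariant while the slope rescales", {
  pts <- withr::with_seed(2, data.frame(read_pct = runif(30, 0, 20)))
  pts$copy_pct <- 1.5 * pts$read_pct + rnorm(30)
  s1 <- concordanceStats(pts)
  pts2 <- transform(pts, read_pct = 10 * read_pct + 3)
  s2 <- concordanceStats(pts2)
  expect_equal(s2$pearson_r, s1$pearson_r, tolerance = 1e-12)
  expect_equal(s2$slope, s1$slope / 10, tolerance = 1e-12)
})

test_that("OLS recovers a known slope within 3 standard errors", {
  withr::with_seed(14, {
    miss <- 0
    for (i in 1:200) {
      x <- runif(40, 1, 30)
      y <- 0.7 + 1.3 * x + rnorm(40, sd = 2)
      s <- concordanceStats(data.frame(read_pct = x, copy_pct = y))
      se <- 2 / sqrt(sum((x - mean(x))^2))
      if (abs(s$slope - 1.3) > 3 * se) miss <- miss + 1
    }
    # P(|slope err| > 3 se) ~ 0.0027; allow a handful in 200
    expect_lte(miss, 5)
  })
})

test_that("reporting bias direction is detected by the sign test", {
  expect_identical(
    reportingBias(data.frame(read_pct = c(9, 8, 7, 9, 8, 9),
                             copy_pct = c(1, 2, 3, 1, 2, 1))), "over")
  expect_identical(
    reportingBias(data.frame(read_pct = c(2, 2, 2),
                             copy_pct = c(2, 2, 2))), "none")
  # under-reported regime: read% = 0.3 * copy% + noise
  withr::with_seed(15, {
    cp <- runif(30, 5, 40)
    rp <- pmax(0, 0.3 * cp + rnorm(30, sd = 1))
    expect_identical(reportingBias(data.frame(read_pct = rp,
                                              copy_pct = cp)), "under")
  })
  expect_error(reportingBias(data.frame(read_pct = 1:2, copy_pct = 2:3)),
               "nrow")
})

test_that("per-species concordance table and injected-bias recovery", {
  withr::with_seed(16, {
    mkSpecies <- function(sp, b, n = 50) {
      cp <- runif(n, 1, 30)
      data.frame(sample = paste0(sp, 1:n), species = sp,
                 read_pct = pmax(0, b * cp + rnorm(n, sd = 0.5)),
                 copy_pct = cp)
    }
    pts <- rbind(mkSpecies("over", 3), mkSpecies("under", 0.3))
    tab <- concordanceTable(pts)
    # copy% ~ read%: slope ~ 1/b
    expect_equal(tab$slope[tab$species == "over"], 1 / 3,
                 tolerance = 0.05)
    expect_equal(tab$slope[tab$species == "under"], 1 / 0.3,
                 tolerance = 0.15 / 0.3)
    expect_true(all(tab$pearson_r > 0.95))
    expect_identical(reportingBias(pts[pts$species == "over", ]), "over")
    expect_identical(reportingBias(pts[pts$species == "under", ]),
                     "under")
  })
})

test_that("scatter export writes figure and conserves rows in the CSV", {
  pts <- data.frame(sample = c("a", "b", "c"), species = "olive",
                    read_pct = c(0, 2, 8), copy_pct = c(1, 4, 16))
  fig <- tempfile(fileext = ".pdf"); csv <- tempfile(fileext = ".csv")
  p <- scatterExport(pts, file = fig, csv = csv)
  expect_true(file.exists(fig))
  expect_identical(nrow(utils::read.csv(csv)), nrow(pts))
  # single point still renders
  expect_s3_class(scatterExport(pts[1, , drop = FALSE]), "ggplot")
})
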