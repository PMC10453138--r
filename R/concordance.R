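## Concordance between the two quantification routes: NGS read% and
## ddPCR copy% for the same species across samples. ddPCR is the
## reference measurement, so the default regression takes copy% as the
## response and read% as the predictor: a slope below 1 then means the
## species is over-reported among reads, a slope above 1 that it is
## under-reported.

#' Per-species concordance statistics between read% and copy%
#'
#' Pearson correlation of the paired percentages, an ordinary
#' least-squares fit on the linear scale (log axes in plots are
#' presentation only), and the two-sided p-value for zero correlation
#' (identical to the slope t-test in simple regression; both are
#' reported).
#'
#' @param points data.frame with columns `read_pct` and `copy_pct`
#'   (optionally `sample`, `species`), n >= 2, one species.
#' @param response which percentage is the regression response:
#'   "copy_pct" (default; ddPCR as reference measurement) or
#'   "read_pct".
#' @return list with n, pearson_r, slope, intercept, p_value,
#'   p_value_slope, response, and `degenerate` (TRUE when either
#'   variable has zero variance, in which case r is NA and the slope is
#'   0 for a constant response or NA for a constant predictor).
#' @examples
#' pts <- data.frame(read_pct = 1:5, copy_pct = 2 * (1:5))
#' concordanceStats(pts)$slope  # copy% = 2 * read%, slope 2
#' @export
concordanceStats <- function(points,
                             response = c("copy_pct", "read_pct")) {
  response <- match.arg(response)
  stopifnot(all(c("read_pct", "copy_pct") %in% names(points)))
  points <- points[is.finite(points$read_pct) &
                   is.finite(points$copy_pct), , drop = FALSE]
  n <- nrow(points)
  if (n < 2) stop("need at least 2 complete points")
  predictor <- setdiff(c("read_pct", "copy_pct"), response)
  y <- points[[response]]; x <- points[[predictor]]
  varX <- stats::var(x); varY <- stats::var(y)
  if (varX == 0 || varY == 0) {
    slope <- if (varY == 0) 0 else NA_real_
    return(list(n = n, pearson_r = NA_real_, slope = slope,
                intercept = if (varY == 0) y[1] else NA_real_,
                p_value = NA_real_, p_value_slope = NA_real_,
                response = response, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(n = n,
       pearson_r = unname(ct$estimate),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = ct$p.value,
       p_value_slope = sm$coefficients[2, 4],
       response = response,
       degenerate = FALSE)
}

#' Concordance summary across species
#'
#' @param points data.frame with columns species, read_pct, copy_pct.
#' @param response passed to [concordanceStats()].
#' @return data.frame, one row per species, with n, pearson_r, slope,
#'   intercept and p_value.
#' @export
concordanceTable <- function(points, response = c("copy_pct",
                                                  "read_pct")) {
  response <- match.arg(response)
  stopifnot("species" %in% names(points))
  do.call(rbind, lapply(split(points, points$species), function(g) {
    if (nrow(g) < 2)
      return(data.frame(species = g$species[1], n = nrow(g),
                        pearson_r = NA, slope = NA, intercept = NA,
                        p_value = NA))
    s <- concordanceStats(g, response = response)
    data.frame(species = g$species[1], n = s$n, pearson_r = s$pearson_r,
               slope = s$slope, intercept = s$intercept,
               p_value = s$p_value)
  }))
}

#' Direction of reporting bias of reads relative to copies
#'
#' Sign test on the per-sample differences read% - copy%: "over" when
#' reads significantly exceed copies (systematic over-reporting of the
#' species among reads), "under" for the reverse, "none" otherwise.
#' Ties are dropped, as usual for the sign test.
#'
#' @param points data.frame with read_pct and copy_pct, n >= 3.
#' @param level significance level (default 0.05).
#' @return "over", "under" or "none".
#' @examples
#' reportingBias(data.frame(read_pct = c(9, 8, 7), copy_pct = c(1, 2, 3)))
#' @export
reportingBias <- function(points, level = 0.05) {
  stopifnot(nrow(points) >= 3)
  d <- points$read_pct - points$copy_pct
  d <- d[d != 0]
  if (!length(d)) return("none")
  bt <- stats::binom.test(sum(d > 0), length(d))
  if (bt$p.value >= level) return("none")
  if (sum(d > 0) > length(d) / 2) "over" else "under"
}

#' Log-log concordance scatter plot and tidy CSV export
#'
#' One panel per species of copy% (x) vs read% (y) on log axes, with
#' the identity line; zero values are placed at a pseudo-count of half
#' the smallest positive value on that axis (annotated in the
#' subtitle). Writes a tidy CSV next to the figure with one row per
#' input point.
#'
#' @param points data.frame with sample, species, read_pct, copy_pct.
#' @param file plot path (extension selects the device, e.g. .pdf,
#'   .png); NULL skips the figure and returns the plot object.
#' @param csv tidy CSV path; NULL skips.
#' @param logAxes use log10 axes (default TRUE).
#' @return the ggplot object, invisibly.
#' @export
scatterExport <- function(points, file = NULL, csv = NULL,
                          logAxes = TRUE) {
  stopifnot(nrow(points) >= 1)
  df <- points
  pseudo <- function(v) {
    p <- v[v > 0]
    if (!length(p)) return(v + 1e-3)
    v[v == 0] <- min(p) / 2
    v
  }
  nZero <- sum(df$read_pct == 0 | df$copy_pct == 0)
  if (logAxes) {
    df$read_pct <- pseudo(df$read_pct)
    df$copy_pct <- pseudo(df$copy_pct)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$copy_pct,
                                        y = .data$read_pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "ddPCR copy %", y = "NGS read %",
                  subtitle = if (logAxes && nZero > 0)
                    sprintf("%d zero value(s) shown at half the smallest positive value",
                            nZero) else NULL)
  if ("species" %in% names(points))
    p <- p + ggplot2::facet_wrap(~species, scales = "free")
  if (logAxes)
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  if (!is.null(file))
    ggplot2::ggsave(file, p, width = 8, height = 6)
  if (!is.null(csv))
    utils::write.csv(points, csv, row.names = FALSE)
  invisible(p)
}
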