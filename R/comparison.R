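#' Annual continental totals and carbon-use efficiency for one product
#'
#' Per year, the domain totals of GPP and NPP (Pg C yr^-1, via
#' [class_statistics()]) and their ratio; the period mean and standard
#' deviation of each column are attached as attributes.
#'
#' @param gpp_by_year,npp_by_year Named lists of [field()]s keyed by year
#'   (e.g. `"2000"`), already mask-harmonized across years and products.
#' @param landcover A [landcover_map()] on the same grid.
#' @return `data.frame` with columns `year`, `gpp_PgC`, `npp_PgC`, `cue`,
#'   and attribute `period` (named vector of means and SDs).
#' @export
annual_totals <- function(gpp_by_year, npp_by_year, landcover) {
  years <- names(gpp_by_year)
  if (is.null(years) || any(!nzchar(years)) ||
      !identical(years, names(npp_by_year))) {
    stop("validation error: year lists must share identical year names")
  }
  if (any(vapply(c(gpp_by_year, npp_by_year), is.null, logical(1)))) {
    stop("validation error: missing year in input list")
  }
  rows <- lapply(years, function(y) {
    gt <- domain_total(class_statistics(gpp_by_year[[y]], landcover))
    nt <- domain_total(class_statistics(npp_by_year[[y]], landcover))
    data.frame(year = as.integer(y), gpp_PgC = gt, npp_PgC = nt,
               cue = if (gt != 0) nt / gt else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.unsorted(out$year, strictly = TRUE)) {
    stop("validation error: years must be strictly increasing")
  }
  attr(out, "period") <- c(
    gpp_mean = mean(out$gpp_PgC), gpp_sd = stats::sd(out$gpp_PgC),
    npp_mean = mean(out$npp_PgC), npp_sd = stats::sd(out$npp_PgC),
    cue_mean = mean(out$cue), cue_sd = stats::sd(out$cue))
  out
}

#' Paired (or Welch) t-test between two co-located samples
#'
#' Thin wrapper over [stats::t.test()] handling the degenerate case of a
#' zero-variance difference: identical samples give `t = 0, p = 1`; a
#' constant non-zero difference gives `p = 0` with a `degenerate` flag
#' (the test statistic is unbounded).
#'
#' @param a_values,b_values Equal-length numeric vectors over the same cells.
#' @param method `"paired"` (default) or `"welch"` (two-sample, unequal
#'   variance).
#' @return List with `t`, `p`, `n`, `df`, `method`, `degenerate`.
#' @export
paired_ttest <- function(a_values, b_values, method = c("paired", "welch")) {
  method <- match.arg(method)
  if (length(a_values) != length(b_values)) {
    stop("validation error: samples must be paired (equal length)")
  }
  n <- length(a_values)
  if (n < 2) stop("validation error: need n >= 2")
  d <- a_values - b_values
  # a constant difference (up to rounding noise) has no usable variance
  if (method == "paired" &&
      stats::sd(d) <= 1e-12 * max(abs(mean(d)), .Machine$double.eps)) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, n = n, df = n - 1, method = method,
                  degenerate = FALSE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, n = n, df = n - 1,
                method = method, degenerate = TRUE))
  }
  ht <- if (method == "paired") {
    stats::t.test(a_values, b_values, paired = TRUE)
  } else {
    stats::t.test(a_values, b_values, paired = FALSE, var.equal = FALSE)
  }
  list(t = unname(ht$statistic), p = ht$p.value, n = n,
       df = unname(ht$parameter), method = method, degenerate = FALSE)
}

period_mean_field <- function(by_year) {
  g <- by_year[[1]]$grid
  n <- length(by_year)
  mask <- Reduce(`&`, lapply(by_year, function(f) f$valid_mask))
  vals <- Reduce(`+`, lapply(by_year, function(f) ifelse(f$valid_mask, f$values, 0))) / n
  field(g, ifelse(mask, vals, NA_real_), mask, units = by_year[[1]]$units)
}

#' Continental and per-class comparison of two productivity products
#'
#' For one variable (GPP or NPP) of two products A and B on the same grid
#' and years: per-class and continental period means and totals, their
#' differences (always A minus B), per-year total differences, and a
#' per-class significance test on co-located cell period means. Cells are
#' the sampling unit of the t-tests; p-values are reported raw, without
#' multiplicity correction across classes (noted in the metadata).
#'
#' @param a_by_year,b_by_year Named lists of [field()]s keyed by the same
#'   years, mask-harmonized.
#' @param landcover A [landcover_map()].
#' @param test `"paired"` or `"welch"` (see [paired_ttest()]).
#' @return List of class `comparison_report`: `per_class` (data.frame),
#'   `continental` (one-row data.frame), `per_year` (data.frame),
#'   `metadata`.
#' @export
difference_report <- function(a_by_year, b_by_year, landcover,
                              test = "paired") {
  years <- names(a_by_year)
  if (!identical(years, names(b_by_year))) {
    stop("validation error: products cover different years")
  }
  for (y in years) {
    stop_if_grid_mismatch(a_by_year[[y]]$grid, b_by_year[[y]]$grid)
  }
  pa <- period_mean_field(a_by_year)
  pb <- period_mean_field(b_by_year)
  if (!identical(pa$valid_mask, pb$valid_mask)) {
    stop("validation error: masks not harmonized between products")
  }
  sa <- class_statistics(pa, landcover)
  sb <- class_statistics(pb, landcover)
  per_class <- data.frame(
    class = sa$class, n_cells = sa$n_cells, area_km2 = sa$area_km2,
    mean_a = sa$mean_kgC_m2_yr, mean_b = sb$mean_kgC_m2_yr,
    mean_diff = sa$mean_kgC_m2_yr - sb$mean_kgC_m2_yr,
    total_a_PgC = sa$total_PgC, total_b_PgC = sb$total_PgC,
    total_diff_PgC = sa$total_PgC - sb$total_PgC,
    t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(per_class))) {
    sel <- landcover$classes == per_class$class[i] & pa$valid_mask
    if (sum(sel) >= 2) {
      tt <- paired_ttest(pa$values[sel], pb$values[sel], method = test)
      per_class$t[i] <- tt$t
      per_class$p[i] <- tt$p
    }
  }
  per_year <- do.call(rbind, lapply(years, function(y) {
    ta <- domain_total(class_statistics(a_by_year[[y]], landcover))
    tb <- domain_total(class_statistics(b_by_year[[y]], landcover))
    data.frame(year = as.integer(y), total_a_PgC = ta, total_b_PgC = tb,
               diff_PgC = ta - tb)
  }))
  continental <- data.frame(
    n_cells = sum(pa$valid_mask),
    total_a_PgC = domain_total(sa), total_b_PgC = domain_total(sb),
    total_diff_PgC = domain_total(sa) - domain_total(sb),
    mean_diff = stats::weighted.mean(per_class$mean_diff, per_class$n_cells,
                                     na.rm = TRUE))
  structure(list(per_class = per_class, continental = continental,
                 per_year = per_year,
                 metadata = list(test = test, sampling_unit = "cells",
                                 multiplicity_correction = "none",
                                 direction = "A minus B")),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (A minus B,", x$metadata$test, "t-test on cell period means)\n")
  cat(sprintf("continental total difference: %.3f Pg C yr-1 over %d cells\n",
              x$continental$total_diff_PgC, x$continental$n_cells))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Per-class and continental carbon-use efficiency of one product
#'
#' CUE per class and for the whole domain as the ratio of period-total NPP
#' to period-total GPP (totals, not an area-weighted mean of cell ratios).
#'
#' @inheritParams annual_totals
#' @return `data.frame` with columns `class`, `gpp_PgC`, `npp_PgC`, `cue`;
#'   the continental value is the last row (`class = "ALL"`).
#' @export
cue_summary <- function(gpp_by_year, npp_by_year, landcover) {
  pg <- period_mean_field(gpp_by_year)
  pn <- period_mean_field(npp_by_year)
  sg <- class_statistics(pg, landcover)
  sn <- class_statistics(pn, landcover)
  out <- data.frame(class = sg$class, gpp_PgC = sg$total_PgC,
                    npp_PgC = sn$total_PgC,
                    cue = ifelse(sg$total_PgC != 0,
                                 sn$total_PgC / sg$total_PgC, NA_real_),
                    stringsAsFactors = FALSE)
  gt <- domain_total(sg); nt <- domain_total(sn)
  if (gt == 0) warning("undefined continental CUE: zero GPP total")
  rbind(out, data.frame(class = "ALL", gpp_PgC = gt, npp_PgC = nt,
                        cue = if (gt != 0) nt / gt else NA_real_))
}

#' Inter-product carbon-use-efficiency ratio, as a percentage
#'
#' `100 * CUE_A / CUE_B`; e.g. CUE 0.46 against 0.58 gives about 79%,
#' meaning product A assumes autotrophic respiration to retain about 79% of
#' product B's NPP share per unit GPP.
#'
#' @param cue_a,cue_b Carbon-use efficiencies (dimensionless).
#' @return Percentage.
#' @export
cue_ratio_percent <- function(cue_a, cue_b) {
  if (any(cue_b == 0)) stop("validation error: zero reference CUE")
  100 * cue_a / cue_b
}

#' Percent deviation of an annual value from its period mean
#'
#' `100 * |annual - mean| / mean`, rounded to one decimal for reporting.
#'
#' @param annual_value Annual value.
#' @param period_mean Period mean (non-zero).
#' @return Percent, one decimal.
#' @export
deviation_from_period_mean <- function(annual_value, period_mean) {
  if (any(period_mean == 0)) stop("undefined deviation: zero period mean")
  round(100 * abs(annual_value - period_mean) / period_mean, 1)
}
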