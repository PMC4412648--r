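#' Multi-year mean carbon-use-efficiency field
#'
#' Per cell, the ratio of the multi-year mean NPP to the multi-year mean GPP
#' (a ratio of means, not a mean of annual ratios — the two differ whenever
#' GPP varies between years). Cells with zero mean GPP, or invalid in any
#' input year, are invalid in the result. Cells where the mean NPP is
#' negative (possible in DVM output) keep their ratio but are flagged.
#'
#' @param gpp_by_year,npp_by_year Equal-length lists of [field()]s on one
#'   grid, one per year.
#' @return A `cue_field`: a [field()] with units `"dimensionless"` and an
#'   extra logical matrix element `flagged_negative`.
#' @export
mean_cue <- function(gpp_by_year, npp_by_year) {
  if (length(gpp_by_year) == 0 || length(gpp_by_year) != length(npp_by_year)) {
    stop("validation error: need equal, non-empty GPP and NPP year lists")
  }
  g <- gpp_by_year[[1]]$grid
  for (f in c(gpp_by_year, npp_by_year)) stop_if_grid_mismatch(g, f$grid)
  n <- length(gpp_by_year)
  acc <- function(lst) {
    vals <- Reduce(`+`, lapply(lst, function(f) ifelse(f$valid_mask, f$values, 0)))
    mask <- Reduce(`&`, lapply(lst, function(f) f$valid_mask))
    list(mean = vals / n, mask = mask)
  }
  mg <- acc(gpp_by_year); mn <- acc(npp_by_year)
  mask <- mg$mask & mn$mask & mg$mean != 0
  ratio <- ifelse(mask, mn$mean / mg$mean, NA_real_)
  out <- field(g, ratio, mask, units = "dimensionless")
  out$flagged_negative <- mask & mn$mean < 0
  class(out) <- c("cue_field", class(out))
  out
}

#' Fuse fine-grid LUE GPP with a DVM carbon-use efficiency
#'
#' `NPP_Combined = GPP_fine * CUE`, cell-wise: the DVM's respired fraction is
#' applied to the fine-resolution satellite GPP, producing an NPP product at
#' the fine grid's spatial resolution. The CUE field must already be on the
#' fine grid (resample first with [resample_nearest()]).
#'
#' @param gpp_fine A [field()] of annual GPP, kg C m^-2 yr^-1.
#' @param cue A `cue_field` (or plain dimensionless field) on the same grid.
#' @param clamp If `TRUE`, ratios are clamped into \[0, 1\] before
#'   multiplying (off by default; a message notes how many cells were
#'   affected when on).
#' @return A [field()] of NPP_Combined, kg C m^-2 yr^-1; invalid wherever
#'   either input is invalid.
#' @export
combine_npp <- function(gpp_fine, cue, clamp = FALSE) {
  stopifnot(inherits(gpp_fine, "field"), inherits(cue, "field"))
  stop_if_grid_mismatch(gpp_fine$grid, cue$grid, "GPP and CUE fields")
  ratio <- cue$values
  if (clamp) {
    n_out <- sum(cue$valid_mask & (ratio < 0 | ratio > 1), na.rm = TRUE)
    if (n_out > 0) message("combine_npp: clamped ", n_out, " CUE cells into [0, 1]")
    ratio <- pmin(1, pmax(0, ratio))
  }
  mask <- gpp_fine$valid_mask & cue$valid_mask
  vals <- ifelse(mask, gpp_fine$values * ratio, NA_real_)
  field(gpp_fine$grid, vals, mask, units = gpp_fine$units)
}
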