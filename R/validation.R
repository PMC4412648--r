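#' Convert aboveground biomass to carbon
#'
#' Dry biomass is assumed to contain 50% carbon; records already expressed
#' as carbon pass through unchanged (no double conversion).
#'
#' @param anpp Aboveground NPP, g m^-2 (vectorized, non-negative).
#' @param is_carbon Logical (recycled): `TRUE` where `anpp` is already
#'   g C m^-2.
#' @return ANPP in g C m^-2.
#' @export
biomass_to_carbon <- function(anpp, is_carbon = FALSE) {
  if (any(anpp < 0, na.rm = TRUE)) {
    stop("validation error: negative ANPP")
  }
  ifelse(rep_len(is_carbon, length(anpp)), anpp, 0.5 * anpp)
}

#' Read a site table of in-situ aboveground NPP
#'
#' @param path CSV with columns `site_id, lon, lat, year, anpp, is_carbon`.
#' @return `data.frame` of site records.
#' @export
read_sites <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site_id", "lon", "lat", "year", "anpp", "is_carbon")
  missing <- setdiff(required, names(s))
  if (length(missing)) stop("site table missing columns: ",
                            paste(missing, collapse = ", "))
  s$is_carbon <- as.logical(s$is_carbon)
  if (any(s$anpp < 0)) stop("validation error: negative ANPP in site table")
  s
}

site_cell <- function(grid, lon, lat) {
  # half-open cell intervals: a point on an edge belongs to the cell whose
  # top-left corner it touches
  col <- floor((lon - grid$origin[1]) / grid$cell_size) + 1
  row <- floor((grid$origin[2] - lat) / grid$cell_size) + 1
  inside <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  data.frame(row = ifelse(inside, row, NA_integer_),
             col = ifelse(inside, col, NA_integer_), inside = inside)
}

#' Extract gridded predictions at point sites
#'
#' Each site (a ~300 x 300 m plot, sub-cell at any grid resolution handled
#' here) is mapped to the single cell containing its coordinate; no
#' interpolation. In `same_year` mode the prediction is the cell value for
#' the site's sampling year; in `period_mean` mode it is the cell mean over
#' all supplied years, and a site is excluded if its cell lacks valid data
#' in any year of the period. Sites outside the grid or on invalid cells
#' are excluded with a reason, never fatally.
#'
#' @param field_by_year Named list of [field()]s keyed by year
#'   (kg C m^-2 yr^-1).
#' @param sites Site table (see [read_sites()]).
#' @param mode `"same_year"` or `"period_mean"`.
#' @return List with `pairs` (`site_id`, `observed_gC`, `predicted_gC`,
#'   units g C m^-2 yr^-1) and `excluded` (`site_id`, `reason`).
#' @export
extract_at_sites <- function(field_by_year, sites,
                             mode = c("same_year", "period_mean")) {
  mode <- match.arg(mode)
  grid <- field_by_year[[1]]$grid
  loc <- site_cell(grid, sites$lon, sites$lat)
  observed <- biomass_to_carbon(sites$anpp, sites$is_carbon)
  predicted <- rep(NA_real_, nrow(sites))
  reason <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (!loc$inside[i]) { reason[i] <- "outside_extent"; next }
    r <- loc$row[i]; cl <- loc$col[i]
    if (mode == "same_year") {
      y <- as.character(sites$year[i])
      if (!y %in% names(field_by_year)) { reason[i] <- "year_not_available"; next }
      f <- field_by_year[[y]]
      if (!f$valid_mask[r, cl]) { reason[i] <- "cell_invalid"; next }
      predicted[i] <- f$values[r, cl] * 1000   # kg -> g C m^-2
    } else {
      vals <- vapply(field_by_year, function(f) {
        if (f$valid_mask[r, cl]) f$values[r, cl] else NA_real_
      }, numeric(1))
      if (anyNA(vals)) { reason[i] <- "incomplete_coverage"; next }
      predicted[i] <- mean(vals) * 1000
    }
  }
  keep <- is.na(reason)
  list(pairs = data.frame(site_id = sites$site_id[keep],
                          observed_gC = observed[keep],
                          predicted_gC = predicted[keep],
                          stringsAsFactors = FALSE),
       excluded = data.frame(site_id = sites$site_id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Agreement statistics between observed and predicted NPP
#'
#' Pearson correlation and the root-mean-square error
#' `RMSE = sqrt(mean((predicted - observed)^2))`, both on g C m^-2 yr^-1.
#'
#' @param observed,predicted Equal-length numeric vectors, n >= 3.
#' @return List of class `validation_result`: `n`, `r`, `rmse`, `pairs`
#'   (data.frame of the two vectors).
#' @export
validate_stats <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("validation error: vectors differ in length")
  }
  n <- length(observed)
  if (n < 3) stop("validation error: need n >= 3")
  r <- if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("undefined correlation: zero variance")
    NA_real_
  } else {
    stats::cor(observed, predicted)
  }
  structure(list(n = n, r = r,
                 rmse = sqrt(mean((predicted - observed)^2)),
                 pairs = data.frame(observed = observed,
                                    predicted = predicted)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("validation_result: n = %d, r = %.2f, RMSE = %.0f g C m-2 yr-1\n",
              x$n, x$r, x$rmse))
  invisible(x)
}
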