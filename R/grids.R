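#' Canonical land-cover class codes
#'
#' UMD-style land-cover classes used throughout the package. The first eleven
#' are vegetated (or potentially vegetated) classes for which the LUE engine
#' carries biome parameters; `Barren`, `Water` and `Urban` are conventionally
#' excluded from productivity statistics (see [harmonize_masks()]).
#'
#' @return Character vector of the fourteen class codes.
#' @export
lc_classes <- function() {
  c("EBF", "ENF", "DBF", "DNF", "MF",
    "CShrub", "OShrub", "WSavanna", "Savanna", "Grass", "Crop",
    "Barren", "Water", "Urban")
}

#' Land-cover classes excluded from productivity statistics by default
#' @return Character vector.
#' @export
default_excluded_classes <- function() c("Barren", "Water", "Urban")

#' Define a raster grid
#'
#' A `grid_spec` describes a regular, equal-area raster grid: origin at the
#' top-left corner, row-major storage, cell-center registration. The grids of
#' the source products live in an equal-area-style projection which is carried
#' only as a free-text `crs_label`; the package never reprojects.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in ground units (e.g. metres).
#' @param cell_area Area of one cell in m^2. Defaults to `cell_size^2`.
#' @param origin Numeric length-2: (x, y) of the top-left corner of the
#'   top-left cell. y decreases downward (southward).
#' @param crs_label Free-text projection tag (metadata only).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(10, 10, cell_size = 1000)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1,
                      cell_area = cell_size^2,
                      origin = c(0, n_rows * cell_size),
                      crs_label = "local-equal-area") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows <= 0L || n_cols <= 0L) stop("grid dimensions must be positive")
  if (!is.numeric(cell_area) || cell_area <= 0) stop("cell_area must be > 0")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("origin must be numeric length 2")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         cell_size = as.numeric(cell_size), cell_area = as.numeric(cell_area),
         origin = as.numeric(origin), crs_label = as.character(crs_label)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, cell_size %g, cell_area %g m^2, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$cell_area,
              x$origin[1], x$origin[2], x$crs_label))
  invisible(x)
}

#' Test whether two grids are identical
#'
#' @param a,b `grid_spec` objects.
#' @param tol Numeric tolerance on origin/cell geometry.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) <= tol * max(1, a$cell_size) &&
    abs(a$cell_area - b$cell_area) <= tol * max(1, a$cell_area) &&
    all(abs(a$origin - b$origin) <= tol * max(1, a$cell_size))
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) {
    stop(sprintf("geometry error: %s are not on the same grid", what))
  }
  invisible(TRUE)
}

#' Construct a gridded field
#'
#' A `field` couples a [grid_spec()] with a numeric value matrix, a validity
#' mask and a units tag. Values must be finite wherever the mask is `TRUE`;
#' invalid cells are stored as `NA`.
#'
#' @param grid A `grid_spec`.
#' @param values Numeric matrix `n_rows x n_cols`.
#' @param valid_mask Logical matrix of the same shape; defaults to
#'   `is.finite(values)`.
#' @param units Units tag, e.g. `"kg C m-2 yr-1"` for fluxes,
#'   `"dimensionless"` for ratios.
#' @return An object of class `field`.
#' @examples
#' g <- grid_spec(2, 2, cell_size = 1000)
#' f <- field(g, matrix(1:4, 2, 2), units = "kg C m-2 yr-1")
#' @export
field <- function(grid, values, valid_mask = NULL, units = "unitless") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols))) {
    stop("values shape does not match grid")
  }
  storage.mode(values) <- "double"
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  valid_mask <- as.matrix(valid_mask)
  if (!is.logical(valid_mask) || !all(dim(valid_mask) == dim(values))) {
    stop("valid_mask must be a logical matrix matching values")
  }
  valid_mask[is.na(valid_mask)] <- FALSE
  if (any(!is.finite(values[valid_mask]))) {
    stop("values must be finite wherever valid_mask is TRUE")
  }
  values[!valid_mask] <- NA_real_
  structure(list(grid = grid, values = values, valid_mask = valid_mask,
                 units = as.character(units)),
            class = "field")
}

#' @export
print.field <- function(x, ...) {
  cat(sprintf("field: %d x %d [%s], %d valid cells, range [%g, %g]\n",
              x$grid$n_rows, x$grid$n_cols, x$units, sum(x$valid_mask),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Construct a constant-valued field
#'
#' Convenience constructor used widely in tests and worked examples.
#'
#' @inheritParams field
#' @param value Scalar value assigned to every cell.
#' @return A `field`.
#' @export
uniform_field <- function(grid, value, units = "kg C m-2 yr-1") {
  field(grid, matrix(value, grid$n_rows, grid$n_cols), units = units)
}

#' Construct a land-cover map
#'
#' @param grid A `grid_spec`.
#' @param classes Character (or factor) matrix of class codes drawn from
#'   [lc_classes()], one per cell.
#' @return An object of class `landcover_map`.
#' @export
landcover_map <- function(grid, classes) {
  stopifnot(inherits(grid, "grid_spec"))
  classes <- as.matrix(classes)
  if (is.factor(classes)) classes <- matrix(as.character(classes), nrow(classes))
  storage.mode(classes) <- "character"
  if (!all(dim(classes) == c(grid$n_rows, grid$n_cols))) {
    stop("classes shape does not match grid")
  }
  bad <- !(classes %in% lc_classes())
  if (any(bad)) {
    stop("unknown land-cover codes: ", paste(unique(classes[bad]), collapse = ", "))
  }
  structure(list(grid = grid, classes = classes), class = "landcover_map")
}

#' @export
print.landcover_map <- function(x, ...) {
  tab <- sort(table(x$classes), decreasing = TRUE)
  cat(sprintf("landcover_map: %d x %d cells\n", x$grid$n_rows, x$grid$n_cols))
  print(tab)
  invisible(x)
}

#' Nearest-neighbour (block-replication) resampling to a finer grid
#'
#' Each fine cell takes the value of the coarse cell containing its centre.
#' Because the fields handled here are per-area intensities (kg C m^-2 yr^-1,
#' dimensionless ratios), block replication conserves their per-area meaning:
#' area-weighted aggregation of the children reproduces the coarse value
#' exactly.
#'
#' @param coarse A `field` on the coarse grid.
#' @param fine A `grid_spec` nested in the coarse grid: same origin region,
#'   fine cell size dividing the coarse cell size.
#' @return A `field` on `fine`.
#' @export
resample_nearest <- function(coarse, fine) {
  stopifnot(inherits(coarse, "field"), inherits(fine, "grid_spec"))
  cg <- coarse$grid
  ratio <- cg$cell_size / fine$cell_size
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1 - 1e-9) {
    stop("geometry error: fine cell size must divide coarse cell size")
  }
  # fine cell centres
  xc <- fine$origin[1] + (seq_len(fine$n_cols) - 0.5) * fine$cell_size
  yc <- fine$origin[2] - (seq_len(fine$n_rows) - 0.5) * fine$cell_size
  col_idx <- floor((xc - cg$origin[1]) / cg$cell_size) + 1
  row_idx <- floor((cg$origin[2] - yc) / cg$cell_size) + 1
  if (any(col_idx < 1 | col_idx > cg$n_cols | row_idx < 1 | row_idx > cg$n_rows)) {
    stop("geometry error: fine grid extends beyond coarse grid extent")
  }
  vals <- coarse$values[row_idx, col_idx, drop = FALSE]
  mask <- coarse$valid_mask[row_idx, col_idx, drop = FALSE]
  field(fine, vals, mask, units = coarse$units)
}

#' Area-weighted aggregation of a fine field back to a coarse grid
#'
#' Mean of valid child cells weighted by cell area (uniform here, so an
#' ordinary mean). Used mainly to verify conservation under
#' [resample_nearest()].
#'
#' @param fine A `field`.
#' @param coarse A `grid_spec` such that `fine` nests inside it.
#' @param require_all_valid If `TRUE`, a coarse cell is valid only when all
#'   of its children are valid.
#' @return A `field` on `coarse`.
#' @export
aggregate_to_coarse <- function(fine, coarse, require_all_valid = TRUE) {
  stopifnot(inherits(fine, "field"), inherits(coarse, "grid_spec"))
  f <- coarse$cell_size / fine$grid$cell_size
  if (abs(f - round(f)) > 1e-9) stop("geometry error: grids do not nest")
  f <- as.integer(round(f))
  nrc <- coarse$n_rows; ncc <- coarse$n_cols
  if (fine$grid$n_rows != nrc * f || fine$grid$n_cols != ncc * f) {
    stop("geometry error: grids do not nest")
  }
  rid <- (seq_len(fine$grid$n_rows) - 1L) %/% f + 1L
  cid <- (seq_len(fine$grid$n_cols) - 1L) %/% f + 1L
  idx <- (rep(cid, each = fine$grid$n_rows) - 1L) * nrc + rid  # coarse linear index
  v <- as.vector(fine$values); ok <- as.vector(fine$valid_mask)
  v[!ok] <- 0
  sums <- rowsum(v, idx)
  cnts <- rowsum(as.numeric(ok), idx)
  mean_v <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  vals <- matrix(NA_real_, nrc, ncc)
  vals[as.integer(rownames(sums))] <- mean_v
  nvalid <- matrix(0, nrc, ncc)
  nvalid[as.integer(rownames(cnts))] <- cnts
  mask <- if (require_all_valid) nvalid == f * f else nvalid > 0
  vals[!mask] <- NA_real_
  field(coarse, vals, mask, units = fine$units)
}

#' Harmonize the validity masks of two co-gridded fields
#'
#' Both outputs are valid exactly on the intersection of the input masks,
#' minus cells whose land-cover class is excluded (`Barren`, `Water` and
#' `Urban` by default, for which the LUE product computes no GPP/NPP). The
#' operation is idempotent, and the two outputs always carry bitwise
#' identical masks -- paired products must cover the same cells before any
#' statistic is taken.
#'
#' @param a,b `field`s on one grid.
#' @param landcover A `landcover_map` on the same grid.
#' @param excluded_classes Character vector of class codes to drop.
#' @return List with elements `a` and `b` (masked fields).
#' @export
harmonize_masks <- function(a, b, landcover,
                            excluded_classes = default_excluded_classes()) {
  stopifnot(inherits(a, "field"), inherits(b, "field"),
            inherits(landcover, "landcover_map"))
  stop_if_grid_mismatch(a$grid, b$grid, "fields")
  stop_if_grid_mismatch(a$grid, landcover$grid, "field and landcover")
  keep <- a$valid_mask & b$valid_mask &
    !(landcover$classes %in% excluded_classes)
  list(a = field(a$grid, ifelse(keep, a$values, NA_real_), keep, units = a$units),
       b = field(b$grid, ifelse(keep, b$values, NA_real_), keep, units = b$units))
}

#' Per-class zonal statistics of a flux field
#'
#' For each land-cover class: count of valid cells, area (km^2), mean flux
#' over valid cells (kg C m^-2 yr^-1) and total (Pg C yr^-1, 1 Pg = 10^15 g
#' = 10^12 kg). Classes with no valid cells report `NA` mean and zero total,
#' so empty classes never bias cross-class summaries.
#'
#' @param field A `field` with units kg C m^-2 yr^-1.
#' @param landcover A `landcover_map` on the same grid.
#' @param classes Classes to report; defaults to all classes present.
#' @return A `data.frame` (class `class_statistics`) with columns `class`,
#'   `n_cells`, `area_km2`, `mean_kgC_m2_yr`, `total_PgC`, plus attribute
#'   `domain_total_PgC`.
#' @export
class_statistics <- function(field, landcover, classes = NULL) {
  stopifnot(inherits(field, "field"), inherits(landcover, "landcover_map"))
  stop_if_grid_mismatch(field$grid, landcover$grid, "field and landcover")
  if (is.null(classes)) {
    classes <- intersect(lc_classes(), unique(as.vector(landcover$classes)))
  }
  area <- field$grid$cell_area
  out <- do.call(rbind, lapply(classes, function(cl) {
    sel <- landcover$classes == cl & field$valid_mask
    n <- sum(sel)
    v <- field$values[sel]
    data.frame(class = cl, n_cells = n,
               area_km2 = n * area / 1e6,
               mean_kgC_m2_yr = if (n > 0) mean(v) else NA_real_,
               total_PgC = if (n > 0) sum(v) * area / 1e12 else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "domain_total_PgC") <- sum(out$total_PgC)
  class(out) <- c("class_statistics", class(out))
  out
}

#' Domain total of a class-statistics table (Pg C yr^-1)
#' @param stats A `class_statistics` table.
#' @return Numeric scalar.
#' @export
domain_total <- function(stats) {
  stopifnot(inherits(stats, "class_statistics"))
  attr(stats, "domain_total_PgC")
}

#' Per-class mean of an arbitrary field (e.g. QC percent)
#'
#' Plain per-class mean over valid cells without the Pg unit conversion of
#' [class_statistics()]; used for dimensionless or percent fields.
#'
#' @inheritParams class_statistics
#' @return Named numeric vector of class means (`NA` for empty classes).
#' @export
class_mean <- function(field, landcover, classes = NULL) {
  stopifnot(inherits(field, "field"), inherits(landcover, "landcover_map"))
  stop_if_grid_mismatch(field$grid, landcover$grid, "field and landcover")
  if (is.null(classes)) {
    classes <- intersect(lc_classes(), unique(as.vector(landcover$classes)))
  }
  vapply(stats::setNames(classes, classes), function(cl) {
    sel <- landcover$classes == cl & field$valid_mask
    if (any(sel)) mean(field$values[sel]) else NA_real_
  }, numeric(1))
}
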