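#' Read a single-band raster field
#'
#' The package's raster exchange format is the Esri ASCII grid (`.asc`): a
#' plain-text, single-band format with a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by row-major cell
#' values, north row first. Values are written with 17 significant digits so
#' doubles round-trip exactly. A JSON sidecar (`<path>.aux.json`) carries
#' the units tag, CRS label and cell area; when absent, `cell_area` defaults
#' to `cellsize^2` and the units to `"unitless"`.
#'
#' @param path File to read.
#' @param format_tag Raster format; only `"asc"` is supported.
#' @return A [field()]; nodata cells become invalid in `valid_mask`.
#' @export
read_field <- function(path, format_tag = "asc") {
  if (!identical(format_tag, "asc")) {
    stop("unsupported raster format: ", format_tag,
         " (single-band 'asc' ASCII grids only)")
  }
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  hdr <- readLines(path, n = 6L)
  parse_hdr <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), hdr, ignore.case = TRUE, value = TRUE)
    if (length(ln) != 1L) stop("I/O error: malformed ASCII grid header (", key, ")")
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- as.integer(parse_hdr("ncols")); nr <- as.integer(parse_hdr("nrows"))
  xll <- parse_hdr("xllcorner"); yll <- parse_hdr("yllcorner")
  cs <- parse_hdr("cellsize"); nodata <- parse_hdr("NODATA_value")
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("unsupported format: expected one band of ", nr * nc,
         " values, found ", length(vals))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- m != nodata
  m[!mask] <- NA_real_
  aux <- paste0(path, ".aux.json")
  units <- "unitless"; crs <- "unspecified"; cell_area <- cs^2
  if (file.exists(aux)) {
    meta <- jsonlite::read_json(aux, simplifyVector = TRUE)
    if (!is.null(meta$units)) units <- meta$units
    if (!is.null(meta$crs_label)) crs <- meta$crs_label
    if (!is.null(meta$cell_area)) cell_area <- as.numeric(meta$cell_area)
  }
  g <- grid_spec(nr, nc, cell_size = cs, cell_area = cell_area,
                 origin = c(xll, yll + nr * cs), crs_label = crs)
  field(g, m, mask, units = units)
}

#' Write a single-band raster field
#'
#' Inverse of [read_field()]; see that help page for the format. Writing is
#' lossless: a written field reads back with bit-identical values wherever
#' valid and an identical mask.
#'
#' @param field A [field()].
#' @param path Destination path.
#' @param format_tag Only `"asc"` is supported.
#' @param nodata Nodata sentinel written for invalid cells; must not collide
#'   with a valid value.
#' @return Invisibly, `path`.
#' @export
write_field <- function(field, path, format_tag = "asc", nodata = -9999) {
  if (!identical(format_tag, "asc")) {
    stop("unsupported raster format: ", format_tag)
  }
  stopifnot(inherits(field, "field"))
  if (any(field$values[field$valid_mask] == nodata)) {
    stop("nodata sentinel collides with a valid cell value")
  }
  g <- field$grid
  m <- field$values
  m[!field$valid_mask] <- nodata
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.17g", g$origin[1]),
           sprintf("yllcorner %.17g", g$origin[2] - g$n_rows * g$cell_size),
           sprintf("cellsize %.17g", g$cell_size),
           sprintf("NODATA_value %.17g", nodata))
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  jsonlite::write_json(
    list(units = field$units, crs_label = g$crs_label, cell_area = g$cell_area),
    paste0(path, ".aux.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a land-cover map (integer-coded grid + JSON legend)
#'
#' Classes are stored as 1-based integer codes into [lc_classes()] in an
#' ASCII grid; the legend (`<path>.legend.json`) maps codes back to class
#' names.
#'
#' @param landcover A [landcover_map()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_landcover <- function(landcover, path) {
  stopifnot(inherits(landcover, "landcover_map"))
  codes <- matrix(match(landcover$classes, lc_classes()),
                  landcover$grid$n_rows, landcover$grid$n_cols)
  f <- field(landcover$grid, codes, units = "class-code")
  write_field(f, path)
  jsonlite::write_json(
    as.list(stats::setNames(lc_classes(), seq_along(lc_classes()))),
    paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a land-cover map written by [write_landcover()]
#' @param path File to read.
#' @return A [landcover_map()].
#' @export
read_landcover <- function(path) {
  f <- read_field(path)
  if (!all(f$valid_mask)) stop("land-cover grid contains nodata cells")
  codes <- lc_classes()
  legend_path <- paste0(path, ".legend.json")
  if (file.exists(legend_path)) {
    leg <- jsonlite::read_json(legend_path, simplifyVector = TRUE)
    codes <- unname(unlist(leg)[order(as.integer(names(leg)))])
  }
  cls <- matrix(codes[as.integer(f$values)], f$grid$n_rows, f$grid$n_cols)
  landcover_map(f$grid, cls)
}

#' Write a class-statistics table to CSV
#' @param stats A [class_statistics()] table.
#' @param path Destination CSV.
#' @return Invisibly, `path`.
#' @export
write_class_statistics <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}
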