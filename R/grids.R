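## Minimal gridded-raster container and plain-text IO (ESRI ASCII grid,
## GeoJSON points/linestrings, panel CSV). Coordinates are abstract planar
## km; no CRS is attached.

#' Create a gridded raster
#'
#' A light container for a regular grid: a numeric matrix whose first row is
#' the northernmost row (the ASCII-grid convention), a cell size, the
#' lower-left corner, and a nodata value.
#'
#' @param data Numeric matrix (rows north to south).
#' @param cellsize Cell edge length, km.
#' @param xll,yll Coordinates of the lower-left corner, km.
#' @param nodata Value standing for missing cells.
#' @return An object of class `ascii_grid`.
#' @export
ascii_grid <- function(data, cellsize = 1, xll = 0, yll = 0,
                       nodata = -9999) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !nrow(data) || !ncol(data)) {
    stop("'data' must be a non-empty numeric matrix", call. = FALSE)
  }
  check_number(cellsize, "cellsize", lower = 0, open_lower = TRUE)
  structure(list(data = data, cellsize = cellsize, xll = xll, yll = yll,
                 nodata = nodata),
            class = "ascii_grid")
}

#' @export
print.ascii_grid <- function(x, ...) {
  vals <- x$data[x$data != x$nodata]
  cat(sprintf("ascii_grid: %d x %d cells of %g km; values in [%g, %g]\n",
              nrow(x$data), ncol(x$data), x$cellsize,
              min(vals), max(vals)))
  invisible(x)
}

#' @export
dim.ascii_grid <- function(x) dim(x$data)

#' @export
plot.ascii_grid <- function(x, main = "", ...) {
  z <- t(x$data[nrow(x$data):1, , drop = FALSE])
  z[z == x$nodata] <- NA
  xs <- x$xll + (seq_len(ncol(x$data)) - 0.5) * x$cellsize
  ys <- x$yll + (seq_len(nrow(x$data)) - 0.5) * x$cellsize
  image(xs, ys, z, xlab = "x (km)", ylab = "y (km)", main = main,
        useRaster = TRUE, ...)
  invisible(x)
}

## cell (row, col) centre -> (x, y); row 1 is the northern edge
grid_cell_xy <- function(grid, row, col) {
  nr <- nrow(grid$data)
  cbind(x = grid$xll + (col - 0.5) * grid$cellsize,
        y = grid$yll + (nr - row + 0.5) * grid$cellsize)
}

## (x, y) -> cell (row, col); NA outside the grid
grid_xy_cell <- function(grid, x, y) {
  nr <- nrow(grid$data)
  nc <- ncol(grid$data)
  col <- floor((x - grid$xll) / grid$cellsize) + 1
  row <- nr - floor((y - grid$yll) / grid$cellsize)
  bad <- col < 1 | col > nc | row < 1 | row > nr
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Write / read a grid as an ESRI ASCII raster
#'
#' Plain-text grid exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by the matrix
#' rows, north first.
#'
#' @param grid An [ascii_grid()].
#' @param path File path.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` an `ascii_grid`.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "ascii_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(grid$data)),
               sprintf("nrows %d", nrow(grid$data)),
               sprintf("xllcorner %.10g", grid$xll),
               sprintf("yllcorner %.10g", grid$yll),
               sprintf("cellsize %.10g", grid$cellsize),
               sprintf("NODATA_value %.10g", grid$nodata)), con)
  write.table(format(grid$data, digits = 10, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  m <- as.matrix(read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (nrow(m) != vals["nrows"] || ncol(m) != vals["ncols"]) {
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  }
  ascii_grid(m, cellsize = unname(vals["cellsize"]),
             xll = unname(vals["xllcorner"]),
             yll = unname(vals["yllcorner"]),
             nodata = unname(vals["nodata_value"]))
}

#' Write / read the sub-kebele panel as CSV
#'
#' The panel round-trips with its exact column names; files with missing
#' values are rejected on read.
#'
#' @param panel A panel data.frame (see [validate_panel()]).
#' @param path File path.
#' @return `write_panel_csv()` returns `path` invisibly;
#'   `read_panel_csv()` the validated panel.
#' @export
write_panel_csv <- function(panel, path) {
  validate_panel(panel)
  write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  panel <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_panel(panel)
  panel
}

#' Write / read point sets as GeoJSON
#'
#' Points carry their non-coordinate columns as properties. Coordinates are
#' the abstract planar km of the synthetic landscape.
#'
#' @param points data.frame with `x_km`, `y_km` and property columns.
#' @param path File path.
#' @return `write_points_geojson()` returns `path` invisibly;
#'   `read_points_geojson()` a data.frame.
#' @export
write_points_geojson <- function(points, path) {
  check_columns(points, c("x_km", "y_km"), "points")
  props <- setdiff(names(points), c("x_km", "y_km"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x_km[i], points$y_km[i])),
         properties = as.list(points[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_points_geojson
#' @export
read_points_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (!length(feats)) stop("GeoJSON has no features: ", path, call. = FALSE)
  coords <- t(vapply(feats, function(f)
    as.numeric(unlist(f$geometry$coordinates)), numeric(2)))
  props <- do.call(rbind, lapply(feats, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE)))
  out <- data.frame(x_km = coords[, 1], y_km = coords[, 2])
  if (!is.null(props)) out <- cbind(out, props)
  out
}

#' Write road polylines as GeoJSON linestrings
#'
#' @param roads List of two-column matrices (x_km, y_km), one per polyline;
#'   names become the `name` property.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_roads_geojson <- function(roads, path) {
  feats <- lapply(seq_along(roads), function(i) {
    m <- roads[[i]]
    list(type = "Feature",
         geometry = list(
           type = "LineString",
           coordinates = lapply(seq_len(nrow(m)), function(j)
             c(m[j, 1], m[j, 2]))),
         properties = list(name = names(roads)[i] %||% paste0("road", i)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
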