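## Spatially explicit delivered lime prices: friction surface, multi-source
## least-cost travel time, and the linear delivered-price model.

#' Friction-model parameters
#'
#' Travel speeds by surface class and the slope penalty. A cell's traversal
#' time is `cellsize / speed * (1 + slope_coef * slope%)`: time to cross one
#' cell edge, inflated linearly with terrain steepness.
#'
#' @param road_kmh Speeds (km/h) for road classes 1, 2, ... .
#' @param offroad_kmh Off-road speed (km/h), class 0.
#' @param slope_coef Penalty per percentage point of slope (default 0.02:
#'   a 50% slope doubles traversal time).
#' @return An object of class `friction_params`.
#' @export
friction_params <- function(road_kmh = c(60, 30), offroad_kmh = 10,
                            slope_coef = 0.02) {
  if (any(c(road_kmh, offroad_kmh) <= 0)) {
    stop("'road_kmh' and 'offroad_kmh' must be positive", call. = FALSE)
  }
  check_number(slope_coef, "slope_coef", lower = 0)
  structure(list(road_kmh = road_kmh, offroad_kmh = offroad_kmh,
                 slope_coef = slope_coef),
            class = "friction_params")
}

#' Build a friction surface from road classes and slope
#'
#' @param roads [ascii_grid()] of integer road-class codes (0 = off-road,
#'   1, 2, ... = road classes indexing `params$road_kmh`).
#' @param slope [ascii_grid()] of slope, in percent, congruent with `roads`.
#' @param params A [friction_params()].
#' @return An object of class `friction_surface`: list with `time` (an
#'   `ascii_grid` of hours per cell edge) and `slope`.
#' @export
build_friction <- function(roads, slope, params = friction_params()) {
  stopifnot(inherits(roads, "ascii_grid"), inherits(slope, "ascii_grid"))
  if (!identical(dim(roads$data), dim(slope$data))) {
    stop("'roads' and 'slope' grids are not congruent", call. = FALSE)
  }
  if (!inherits(params, "friction_params")) {
    stop("'params' must be friction_params()", call. = FALSE)
  }
  speeds <- c(params$offroad_kmh, params$road_kmh)
  cls <- roads$data
  mask <- cls == roads$nodata
  valid <- cls[!mask]
  if (any(valid < 0 | valid > length(params$road_kmh))) {
    stop("road class codes exceed the classes in 'params$road_kmh'",
         call. = FALSE)
  }
  cls_safe <- cls
  cls_safe[mask] <- 0
  speed <- matrix(speeds[cls_safe + 1], nrow(cls), ncol(cls))
  penalty <- 1 + params$slope_coef * slope$data
  tm <- roads$cellsize / speed * penalty
  tm[cls == roads$nodata | slope$data == slope$nodata] <- roads$nodata
  structure(list(time = ascii_grid(tm, roads$cellsize, roads$xll,
                                   roads$yll, roads$nodata),
                 slope = slope),
            class = "friction_surface")
}

#' Crusher locations and gate prices
#'
#' @param points data.frame with columns `name`, `x_km`, `y_km` and
#'   `price_etb_mt` (crusher-gate lime price; default 750 if absent).
#' @return An object of class `crusher_set`.
#' @export
crusher_set <- function(points) {
  points <- as.data.frame(points)
  check_columns(points, c("name", "x_km", "y_km"), "crushers")
  if (!nrow(points)) stop("need at least one crusher", call. = FALSE)
  if (is.null(points$price_etb_mt)) points$price_etb_mt <- 750
  if (any(points$price_etb_mt <= 0)) {
    stop("crusher prices must be positive", call. = FALSE)
  }
  structure(points, class = c("crusher_set", "data.frame"))
}

#' Least-cost travel time to the nearest crusher
#'
#' Multi-source shortest-path (exact Dijkstra) on the 8-connected cell
#' graph of the friction surface. The cost of moving between two adjacent
#' cells is the mean of their per-cell traversal times, scaled by sqrt(2)
#' on diagonal moves. Every cell is labelled with its time-minimising
#' crusher.
#'
#' @param friction A [build_friction()] surface, or an `ascii_grid` of
#'   per-cell times.
#' @param crushers A [crusher_set()]; every crusher must fall on a
#'   traversable cell.
#' @return An object of class `cost_surface`: list with `time` (hours,
#'   `ascii_grid`), `nearest` (`ascii_grid` of crusher indices), and
#'   `crushers`. Unreachable cells are set to nodata and counted in a
#'   message.
#' @export
travel_time <- function(friction, crushers) {
  tgrid <- if (inherits(friction, "friction_surface")) friction$time else
    friction
  stopifnot(inherits(tgrid, "ascii_grid"))
  crushers <- crusher_set(crushers)
  tm <- tgrid$data
  nr <- nrow(tm); nc <- ncol(tm)
  ok <- tm != tgrid$nodata & is.finite(tm)
  if (any(tm[ok] <= 0)) {
    stop("traversal times must be positive on traversable cells",
         call. = FALSE)
  }
  idx <- function(r, c) (c - 1L) * nr + r

  ## undirected 8-neighbour edge list over traversable cells
  edges <- list(); weights <- list(); e <- 0L
  offs <- rbind(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)),
                c(-1L, 1L, sqrt(2)))
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1]; dc <- offs[k, 2]; fac <- offs[k, 3]
    r1 <- seq_len(nr); c1 <- seq_len(nc)
    r1 <- r1[r1 + dr >= 1 & r1 + dr <= nr]
    c1 <- c1[c1 + dc >= 1 & c1 + dc <= nc]
    if (!length(r1) || !length(c1)) next
    g1 <- expand.grid(r = r1, c = c1)
    a <- idx(g1$r, g1$c); b <- idx(g1$r + dr, g1$c + dc)
    keep <- ok[a] & ok[b]
    a <- a[keep]; b <- b[keep]
    e <- e + 1L
    edges[[e]] <- rbind(a, b)
    weights[[e]] <- (tm[a] + tm[b]) / 2 * fac
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  igraph::E(g)$weight <- unlist(weights)

  cells <- grid_xy_cell(tgrid, crushers$x_km, crushers$y_km)
  if (anyNA(cells)) {
    stop("crusher(s) outside the grid: ",
         paste(crushers$name[is.na(cells[, 1])], collapse = ", "),
         call. = FALSE)
  }
  src <- idx(cells[, "row"], cells[, "col"])
  if (any(!ok[src])) {
    stop("crusher(s) on non-traversable cells: ",
         paste(crushers$name[!ok[src]], collapse = ", "), call. = FALSE)
  }
  d <- igraph::distances(g, v = src, algorithm = "dijkstra")
  nearest <- apply(d, 2, which.min)
  best <- d[cbind(nearest, seq_len(ncol(d)))]

  time_m <- matrix(best, nr, nc)
  near_m <- matrix(as.numeric(nearest), nr, nc)
  unreachable <- ok & !is.finite(time_m)
  if (any(unreachable)) {
    message(sprintf("%d traversable cell(s) unreachable from any crusher",
                    sum(unreachable)))
  }
  time_m[!ok | unreachable] <- tgrid$nodata
  near_m[!ok | unreachable] <- tgrid$nodata
  structure(list(time = ascii_grid(time_m, tgrid$cellsize, tgrid$xll,
                                   tgrid$yll, tgrid$nodata),
                 nearest = ascii_grid(near_m, tgrid$cellsize, tgrid$xll,
                                      tgrid$yll, tgrid$nodata),
                 crushers = crushers),
            class = "cost_surface")
}

#' Delivered lime price surface
#'
#' The delivered price at a cell is the gate price of its nearest crusher
#' plus a fixed loading charge plus a variable transport cost proportional
#' to travel time. Last-mile transport and field application are not
#' included.
#'
#' @param cost A [travel_time()] cost surface.
#' @param loading_etb_mt Fixed loading cost, ETB/mt (default 100).
#' @param variable_etb_mt_hr Variable transport cost, ETB/mt/hr
#'   (default 60).
#' @return `ascii_grid` of delivered prices, ETB/mt.
#' @export
delivered_price <- function(cost, loading_etb_mt = 100,
                            variable_etb_mt_hr = 60) {
  stopifnot(inherits(cost, "cost_surface"))
  check_number(loading_etb_mt, "loading_etb_mt", lower = 0)
  check_number(variable_etb_mt_hr, "variable_etb_mt_hr", lower = 0)
  tm <- cost$time$data
  nearest <- cost$nearest$data
  nodata <- cost$time$nodata
  ok <- tm != nodata
  price <- matrix(nodata, nrow(tm), ncol(tm))
  gate <- cost$crushers$price_etb_mt
  price[ok] <- gate[nearest[ok]] + loading_etb_mt +
    variable_etb_mt_hr * tm[ok]
  ascii_grid(price, cost$time$cellsize, cost$time$xll, cost$time$yll,
             nodata)
}

#' Sample a price (or any) grid at point locations
#'
#' @param points data.frame with `x_km`, `y_km`.
#' @param grid An [ascii_grid()].
#' @param method `"nearest"` (default) cell lookup or `"bilinear"`
#'   interpolation of the four surrounding cell centres.
#' @return Numeric vector of grid values at the points (NA where the
#'   underlying cells are nodata).
#' @export
price_at <- function(points, grid, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  check_columns(points, c("x_km", "y_km"), "points")
  stopifnot(inherits(grid, "ascii_grid"))
  cells <- grid_xy_cell(grid, points$x_km, points$y_km)
  if (anyNA(cells)) {
    bad <- which(is.na(cells[, 1]))
    stop(sprintf("point(s) outside grid bounds: rows %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (method == "nearest") {
    v <- grid$data[cells]
    v[v == grid$nodata] <- NA_real_
    return(v)
  }
  ## bilinear on cell centres, clamped to the grid interior
  nr <- nrow(grid$data); nc <- ncol(grid$data)
  gx <- (points$x_km - grid$xll) / grid$cellsize - 0.5
  gy <- (points$y_km - grid$yll) / grid$cellsize - 0.5
  cx <- clamp(gx, 0, nc - 1); cy <- clamp(gy, 0, nr - 1)
  c0 <- clamp(floor(cx), 0, nc - 2); r0 <- clamp(floor(cy), 0, nr - 2)
  fx <- cx - c0; fy <- cy - r0
  val <- function(r, c) {
    v <- grid$data[cbind(nr - r, c + 1)]  # row index from the south
    v[v == grid$nodata] <- NA_real_
    v
  }
  v00 <- val(r0, c0); v01 <- val(r0, c0 + 1)
  v10 <- val(r0 + 1, c0); v11 <- val(r0 + 1, c0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
}
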