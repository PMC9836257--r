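## Synthetic landscape: slope field, road network, crusher locations, and
## the derived friction surface.

#' Generate a synthetic landscape
#'
#' Builds an abstract rectangular landscape on planar km coordinates: a
#' smooth slope field (percent), a sparse grid of fast road corridors over
#' slow off-road terrain, crusher locations placed on roads, and the
#' resulting friction surface. Deterministic for a fixed config; the
#' landscape stream is derived from the master seed by a fixed offset.
#'
#' @param config A [synth_config()].
#' @param params A [friction_params()].
#' @return List of class `synth_landscape` with elements `friction`
#'   (a [build_friction()] surface), `roads` (road-class `ascii_grid`),
#'   `slope`, `crushers` (a [crusher_set()]) and `road_lines` (polylines
#'   for GeoJSON export).
#' @export
generate_landscape <- function(config = synth_config(),
                               params = friction_params()) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  if (nr < 2 || nc < 2) stop("'grid_shape' must be at least 2 x 2",
                             call. = FALSE)
  if (config$n_crushers < 1) stop("need at least one crusher",
                                  call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed + 1000L)

  cs <- config$cellsize_km

  ## smooth positive slope field: white noise passed twice through a 3x3
  ## moving average, then scaled to [0, 30] percent
  z <- matrix(rnorm(nr * nc), nr, nc)
  smooth3 <- function(m) {
    p <- rbind(m[1, ], m, m[nrow(m), ])
    p <- cbind(p[, 1], p, p[, ncol(p)])
    (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
       p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] +
       p[2:(nr + 1), 3:(nc + 2)] +
       p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] +
       p[3:(nr + 2), 3:(nc + 2)]) / 9
  }
  z <- smooth3(smooth3(z))
  slope_m <- (z - min(z)) / (max(z) - min(z)) * 30
  slope <- ascii_grid(slope_m, cs)

  ## road corridors: a few full-width rows and full-height columns,
  ## primary (class 1) horizontals and secondary (class 2) verticals
  n_h <- max(1L, nr %/% 15); n_v <- max(1L, nc %/% 15)
  rows <- sort(sample(seq(2L, nr - 1L), n_h))
  cols <- sort(sample(seq(2L, nc - 1L), n_v))
  road_m <- matrix(0, nr, nc)
  road_m[rows, ] <- 1
  road_m[, cols] <- pmax(road_m[, cols], 2)
  roads <- ascii_grid(road_m, cs)

  road_lines <- c(
    lapply(rows, function(r) {
      y <- (nr - r + 0.5) * cs
      cbind(x_km = c(0.5 * cs, (nc - 0.5) * cs), y_km = c(y, y))
    }),
    lapply(cols, function(cc) {
      x <- (cc - 0.5) * cs
      cbind(x_km = c(x, x), y_km = c(0.5 * cs, (nr - 0.5) * cs))
    })
  )
  names(road_lines) <- c(paste0("primary_", seq_along(rows)),
                         paste0("secondary_", seq_along(cols)))

  ## crushers sit on road cells, well separated
  road_cells <- which(road_m > 0, arr.ind = TRUE)
  picks <- road_cells[sample.int(nrow(road_cells),
                                 config$n_crushers * 25,
                                 replace = TRUE), , drop = FALSE]
  chosen <- picks[1, , drop = FALSE]
  for (i in seq_len(nrow(picks))[-1]) {
    if (nrow(chosen) >= config$n_crushers) break
    d <- sqrt((picks[i, 1] - chosen[, 1])^2 + (picks[i, 2] - chosen[, 2])^2)
    if (all(d > min(nr, nc) / (config$n_crushers + 1))) {
      chosen <- rbind(chosen, picks[i, , drop = FALSE])
    }
  }
  ## relax the separation rule if the landscape is too small to honour it
  i <- 1L
  while (nrow(chosen) < config$n_crushers) {
    cand <- road_cells[sample.int(nrow(road_cells), 1), , drop = FALSE]
    if (!any(cand[1] == chosen[, 1] & cand[2] == chosen[, 2])) {
      chosen <- rbind(chosen, cand)
    }
    i <- i + 1L
    if (i > 1000L) stop("could not place distinct crushers", call. = FALSE)
  }
  xy <- grid_cell_xy(roads, chosen[, 1], chosen[, 2])
  crushers <- crusher_set(data.frame(
    name = paste0("crusher_", seq_len(config$n_crushers)),
    x_km = xy[, "x"], y_km = xy[, "y"],
    price_etb_mt = config$crusher_price))

  structure(list(friction = build_friction(roads, slope, params),
                 roads = roads, slope = slope, crushers = crushers,
                 road_lines = road_lines),
            class = "synth_landscape")
}
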