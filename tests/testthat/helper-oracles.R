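## Independent oracles and small fixture builders shared across tests.

## Exhaustive shortest-path oracle on the 8-connected grid: iterative
## relaxation to a fixed point, written without any graph library. Edge
## cost is the mean of the endpoint cell times, times sqrt(2) on
## diagonals -- the same metric the implementation claims to minimise.
brute_travel_times <- function(tm, src_cells) {
  nr <- nrow(tm); nc <- ncol(tm)
  d <- matrix(Inf, nr, nc)
  for (s in seq_len(nrow(src_cells))) {
    d[src_cells[s, 1], src_cells[s, 2]] <- 0
  }
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        fac <- if (dr != 0 && dc != 0) sqrt(2) else 1
        w <- (tm[r, c] + tm[r2, c2]) / 2 * fac
        if (d[r, c] + w < d[r2, c2] - 1e-12) {
          d[r2, c2] <- d[r, c] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}

## crusher data.frame centred on the given cells of a grid
crushers_at_cells <- function(grid, cells, price = 750) {
  nr <- nrow(grid$data)
  cs <- grid$cellsize
  data.frame(
    name = paste0("c", seq_len(nrow(cells))),
    x_km = grid$xll + (cells[, 2] - 0.5) * cs,
    y_km = grid$yll + (nr - cells[, 1] + 0.5) * cs,
    price_etb_mt = price)
}

## a friction surface with every cell taking 'hours' to traverse
uniform_friction <- function(nr, nc, hours = 0.1, cellsize = 1) {
  ascii_grid(matrix(hours, nr, nc), cellsize = cellsize)
}

## planted truth with a single region, no zone/year structure unless asked
flat_truth <- function(intercept = 2, ph_gain = 0, ph_peak = 6.5,
                       fert_lin = 0, fert_quad = 0) {
  list(
    wheat = list(intercept = intercept, ph_peak = ph_peak,
                 ph_gain = ph_gain, fert_lin = fert_lin,
                 fert_quad = fert_quad),
    barley = list(intercept = intercept, ph_peak = ph_peak,
                  ph_gain = ph_gain, fert_lin = fert_lin,
                  fert_quad = fert_quad),
    effects = c(PDSI = 0, Elevation = 0, SOC = 0, SND = 0, CEC = 0,
                Ext.Area = 0, Imp.Seed = 0, Irg.Area = 0, Damage = 0,
                DistPP = 0, PSNP = 0, AGP = 0),
    year_trend = 0
  )
}

## small single-crop config for quick fits
quick_config <- function(n = 120, seed = 1, noise_sd = 0.2, ...) {
  synth_config(n_subkebeles = n, crops = "wheat", noise_sd = noise_sd,
               seed = seed, ...)
}
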