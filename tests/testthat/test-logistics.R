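test_that("friction formula: speed, cell size and slope penalty", {
  ## flat uniform 60 km/h roads on 1 km cells -> 1/60 hr per cell
  roads <- ascii_grid(matrix(1, 4, 4))
  flat <- ascii_grid(matrix(0, 4, 4))
  fr <- build_friction(roads, flat, friction_params(road_kmh = 60))
  expect_equal(fr$time$data, matrix(1 / 60, 4, 4))
  ## a 50% slope at c = 0.02 doubles traversal time
  steep <- ascii_grid(matrix(50, 4, 4))
  fr2 <- build_friction(roads, steep, friction_params(road_kmh = 60,
                                                      slope_coef = 0.02))
  expect_equal(fr2$time$data, 2 * fr$time$data)
  ## c = 0 removes the slope dependence entirely
  fr3 <- build_friction(roads, steep, friction_params(road_kmh = 60,
                                                      slope_coef = 0))
  expect_equal(fr3$time$data, fr$time$data)
  ## off-road cells use the off-road speed
  off <- build_friction(ascii_grid(matrix(0, 4, 4)), flat,
                        friction_params(offroad_kmh = 5))
  expect_equal(off$time$data, matrix(1 / 5, 4, 4))
  expect_error(friction_params(road_kmh = 0), "positive")
})

test_that("uniform friction gives travel time = octile distance", {
  fr <- uniform_friction(7, 9, hours = 0.1)
  cr <- crushers_at_cells(fr, cbind(3, 4))
  cost <- travel_time(fr, cr)
  for (r in seq_len(7)) for (c in seq_len(9)) {
    dr <- abs(r - 3); dc <- abs(c - 4)
    octile <- max(dr, dc) + (sqrt(2) - 1) * min(dr, dc)
    expect_equal(cost$time$data[r, c], 0.1 * octile, tolerance = 1e-12)
  }
  ## zero exactly at the crusher cell
  expect_identical(cost$time$data[3, 4], 0)
})

test_that("Dijkstra equals the brute-force relaxation oracle", {
  set.seed(3)
  for (i in 1:12) {
    nr <- sample(2:7, 1); nc <- sample(2:7, 1)
    tm <- matrix(runif(nr * nc, 0.05, 0.5), nr, nc)
    grid <- ascii_grid(tm)
    k <- sample(1:2, 1)
    cells <- cbind(sample(nr, k, replace = TRUE),
                   sample(nc, k, replace = TRUE))
    cells <- unique(cells)
    cost <- travel_time(grid, crushers_at_cells(grid, cells))
    expect_equal(cost$time$data, brute_travel_times(tm, cells),
                 tolerance = 1e-10)
  }
})

test_that("adding a crusher never increases any cell's travel time", {
  set.seed(9)
  tm <- matrix(runif(36, 0.05, 0.4), 6, 6)
  grid <- ascii_grid(tm)
  one <- travel_time(grid, crushers_at_cells(grid, cbind(1, 1)))
  two <- travel_time(grid, crushers_at_cells(grid,
                                             rbind(c(1, 1), c(6, 6))))
  expect_true(all(two$time$data <= one$time$data + 1e-12))
})

test_that("delivered price is affine in travel time: slope 60, intercept 850", {
  land <- generate_landscape(synth_config(seed = 11))
  cost <- travel_time(land$friction, land$crushers)
  price <- delivered_price(cost)
  tm <- as.vector(cost$time$data)
  pr <- as.vector(price$data)
  keep <- tm != cost$time$nodata
  fit <- lm(pr[keep] ~ tm[keep])
  expect_equal(unname(coef(fit)), c(850, 60), tolerance = 1e-9)
  expect_equal(suppressWarnings(summary(fit)$r.squared), 1,
               tolerance = 1e-12)
  ## crusher cells: gate price + loading only
  expect_equal(min(pr[keep]), 850)
  ## a zero variable rate flattens the surface
  flat <- delivered_price(cost, variable_etb_mt_hr = 0)
  expect_true(all(flat$data[keep] == 850))
  ## delivered price never undercuts gate price + loading
  expect_true(all(pr[keep] >= 850))
})

test_that("published town costs are reconstructed from printed travel times", {
  towns <- town_lime_costs()
  ## one pseudo-crusher; each town placed a cell whose travel time is the
  ## printed value, so the price model is exercised end to end
  tm <- matrix(c(0, towns$travel_hr), 1)
  cost <- structure(list(
    time = ascii_grid(tm),
    nearest = ascii_grid(matrix(1, 1, ncol(tm))),
    crushers = crusher_set(data.frame(name = "crusher", x_km = 0.5,
                                      y_km = 0.5, price_etb_mt = 750))),
    class = "cost_surface")
  price <- delivered_price(cost)
  recon <- price$data[1, -1]
  expect_true(all(abs(recon - towns$cost_etb_mt) <= 6))
})

test_that("point lookup matches direct indexing and flags outsiders", {
  land <- generate_landscape(synth_config(seed = 12))
  price <- delivered_price(travel_time(land$friction, land$crushers))
  pts <- data.frame(x_km = c(5.2, 20.7, 5.2), y_km = c(8.9, 30.1, 8.9))
  v <- price_at(pts, price)
  ## coincident points agree; value equals the underlying cell
  expect_equal(v[1], v[3])
  cell <- limeval:::grid_xy_cell(price, 5.2, 8.9)
  expect_equal(v[1], price$data[cell])
  ## crusher locations price at gate + loading
  expect_equal(price_at(as.data.frame(land$crushers), price),
               rep(850, 3))
  ## bilinear stays within the local cell values and matches nearest at
  ## cell centres
  ctr <- data.frame(x_km = 10.5, y_km = 10.5)
  expect_equal(price_at(ctr, price, "bilinear"),
               price_at(ctr, price, "nearest"))
  expect_error(price_at(data.frame(x_km = -5, y_km = 2), price),
               "outside grid")
})

test_that("ASCII grid and GeoJSON round-trips preserve the data", {
  g <- ascii_grid(matrix(runif(20), 4, 5), cellsize = 2.5, xll = 1,
                  yll = -3)
  path <- tempfile(fileext = ".asc")
  on.exit(unlink(path))
  write_ascii_grid(g, path)
  g2 <- read_ascii_grid(path)
  expect_equal(g2$data, g$data, tolerance = 1e-9)
  expect_equal(g2$cellsize, 2.5)
  expect_equal(g2$xll, 1)
  pts <- data.frame(x_km = c(1.5, 7.25), y_km = c(2, 4.5),
                    name = c("a", "b"), price_etb_mt = c(750, 800))
  pj <- tempfile(fileext = ".geojson")
  on.exit(unlink(pj), add = TRUE)
  write_points_geojson(pts, pj)
  back <- read_points_geojson(pj)
  expect_equal(back$x_km, pts$x_km)
  expect_equal(back$name, pts$name)
  expect_equal(back$price_etb_mt, pts$price_etb_mt)
})
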