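## End-to-end orchestration: simulate -> lime requirement -> fit ->
## lime price -> compare, with a deterministic manifest, plus the
## descriptive loess smoother.

#' Run configuration
#'
#' Bundles the stage configurations of a full run. Any element can be
#' omitted to use the package defaults.
#'
#' @param seed Master seed (overrides the synthetic config's seed).
#' @param out_dir Output directory; created if missing.
#' @param synth A [synth_config()].
#' @param spec A [model_spec()].
#' @param lime A [lime_spec()].
#' @param econ An [econ_params()].
#' @param friction A [friction_params()].
#' @param crops Crops to fit and compare.
#' @param orders Optional fixed polynomial orders passed to
#'   [yield_response()] (skips order selection).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("limeval_run_"),
                       synth = NULL, spec = model_spec(),
                       lime = lime_spec(), econ = econ_params(),
                       friction = friction_params(),
                       crops = NULL, orders = c(PH = 2, Fert = 2)) {
  check_number(seed, "seed")
  if (is.null(synth)) synth <- synth_config(seed = seed)
  else synth$seed <- as.integer(seed)
  crops <- crops %||% synth$crops
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 synth = synth, spec = spec, lime = lime, econ = econ,
                 friction = friction, crops = crops, orders = orders),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys: `seed`, `out_dir`, `crops`, and nested
#' `synth`, `econ`, `friction` blocks whose fields override the respective
#' constructor defaults. Referenced settings are validated by the
#' constructors.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file does not exist: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  synth <- do.call(synth_config, y$synth %||% list())
  econ <- do.call(econ_params, y$econ %||% list())
  friction <- do.call(friction_params, y$friction %||% list())
  run_config(seed = y$seed %||% synth$seed,
             out_dir = y$out_dir %||% tempfile("limeval_run_"),
             synth = synth, econ = econ, friction = friction,
             crops = y$crops)
}

#' Run the full lime-versus-fertilizer pipeline
#'
#' Executes every stage on synthetic inputs: simulate the panel and
#' landscape; compute per-sub-kebele lime requirements and acidity
#' classes; fit the yield response per crop; build travel-time and
#' delivered-price surfaces; compare present-value costs per sub-kebele
#' and aggregate by crop, region and acidity class. All hand-off is via
#' files in `config$out_dir`; a manifest records each artifact's MD5 hash
#' so that two runs with one seed are byte-identical.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the manifest and the paths of all
#'   artifacts.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  paths <- list()
  t_all <- proc.time()[3]

  ## stage 1: simulate
  t0 <- proc.time()[3]
  panel <- generate_panel(config$synth)
  land <- generate_landscape(config$synth, config$friction)
  paths$panel <- file.path(config$out_dir, "panel.csv")
  write_panel_csv(panel, paths$panel)
  paths$friction <- file.path(config$out_dir, "friction.asc")
  write_ascii_grid(land$friction$time, paths$friction)
  paths$slope <- file.path(config$out_dir, "slope.asc")
  write_ascii_grid(land$slope, paths$slope)
  paths$crushers <- file.path(config$out_dir, "crushers.geojson")
  write_points_geojson(as.data.frame(land$crushers), paths$crushers)
  paths$roads <- file.path(config$out_dir, "roads.geojson")
  write_roads_geojson(land$road_lines, paths$roads)
  say("simulate: %d panel rows, %dx%d grid [%.1fs]", nrow(panel),
      nrow(land$slope$data), ncol(land$slope$data), proc.time()[3] - t0)

  ## stage 2: lime requirement per sub-kebele
  t0 <- proc.time()[3]
  lime_df <- panel
  lime_df$lime_mt_ha <- lime_requirement(
    data.frame(ph = panel$PH, cec = panel$CEC), config$lime)
  lime_df$acidity_class <- classify_acidity(panel$PH)
  paths$lime <- file.path(config$out_dir, "lime.csv")
  write.csv(lime_df, paths$lime, row.names = FALSE)
  say("lime-req: median %.2f mt/ha on acidic soils [%.1fs]",
      median(lime_df$lime_mt_ha[lime_df$lime_mt_ha > 0]),
      proc.time()[3] - t0)

  ## stage 3: fit per crop
  t0 <- proc.time()[3]
  models <- list()
  for (crop in config$crops) {
    models[[crop]] <- yield_response(panel, crop = crop,
                                     spec = config$spec,
                                     orders = config$orders)
    paths[[paste0("model_", crop)]] <-
      file.path(config$out_dir, paste0("model_", crop, ".json"))
    write_model_json(models[[crop]], paths[[paste0("model_", crop)]])
  }
  say("fit: %s [%.1fs]",
      paste(sprintf("%s adjR2=%.3f", config$crops,
                    vapply(models, function(m) m$adj_r_squared,
                           numeric(1))), collapse = ", "),
      proc.time()[3] - t0)

  ## stage 4: delivered lime prices
  t0 <- proc.time()[3]
  cost <- travel_time(land$friction, land$crushers)
  price <- delivered_price(cost)
  paths$time_grid <- file.path(config$out_dir, "travel_time.asc")
  write_ascii_grid(cost$time, paths$time_grid)
  paths$price_grid <- file.path(config$out_dir, "lime_price.asc")
  write_ascii_grid(price, paths$price_grid)
  say("lime-price: mean %.0f ETB/mt [%.1fs]",
      mean(price$data[price$data != price$nodata]), proc.time()[3] - t0)

  ## stage 5: per-sub-kebele comparison and aggregation
  t0 <- proc.time()[3]
  sk <- unique(panel[c("subkebele_id", "region", "x_km", "y_km", "PH",
                       "CEC")])
  sk$lime_mt_ha <- lime_requirement(
    data.frame(ph = sk$PH, cec = sk$CEC), config$lime)
  sk$acidity_class <- classify_acidity(sk$PH)
  sk$price_etb_mt <- price_at(sk, price)
  target <- config$lime$target_ph
  rows <- list()
  for (crop in config$crops) {
    m <- models[[crop]]
    fert_base <- mean(panel$Fert[panel$crop == crop])
    for (i in seq_len(nrow(sk))) {
      gain <- yield_gain(m, sk$PH[i], target)
      ## a soil whose fitted curve peaks below the target can show a
      ## non-positive gain; it then needs no fertilizer to match
      fe <- equivalent_fertilizer(m, max(gain$gain, 0),
                                  at_ph = sk$PH[i],
                                  baseline_fert = fert_base)
      cmp <- compare_costs(gain$gain, fe, sk$lime_mt_ha[i],
                           sk$price_etb_mt[i], config$econ)
      rows[[length(rows) + 1]] <- data.frame(
        subkebele_id = sk$subkebele_id[i], crop = crop,
        region = sk$region[i], acidity_class = sk$acidity_class[i],
        x_km = sk$x_km[i], y_km = sk$y_km[i], ph = sk$PH[i],
        lime_mt_ha = sk$lime_mt_ha[i],
        price_etb_mt = sk$price_etb_mt[i],
        yield_gain = gain$gain, fert_equiv = cmp$fert_equiv,
        attainable = cmp$attainable, pv_lime = cmp$pv_lime,
        pv_fert = cmp$pv_fert, x_cost_of_lime = cmp$x_cost_of_lime,
        savings_etb = cmp$savings_etb,
        savings_pct_income = cmp$savings_pct_income,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  paths$results <- file.path(config$out_dir, "results.csv")
  write.csv(results, paths$results, row.names = FALSE)
  agg <- aggregate_results(results[results$acidity_class != "non-acidic", ])
  paths$aggregate <- file.path(config$out_dir, "aggregate.csv")
  write.csv(agg, paths$aggregate, row.names = FALSE)
  ## point map of the cost ratio; non-acidic cells are fertilizer-favoured
  map <- results[c("x_km", "y_km", "subkebele_id", "crop",
                   "acidity_class", "x_cost_of_lime")]
  map$fertilizer_favoured <- map$acidity_class == "non-acidic"
  paths$ratio_map <- file.path(config$out_dir, "x_cost_map.geojson")
  write_points_geojson(map, paths$ratio_map)
  say("compare: %d sub-kebele x crop results, %d aggregate cells [%.1fs]",
      nrow(results), nrow(agg), proc.time()[3] - t0)

  ## deterministic manifest: no timestamps or timings
  files <- unlist(paths)
  manifest <- list(
    seed = config$seed,
    package = "limeval",
    version = as.character(utils::packageVersion("limeval")),
    artifacts = data.frame(
      name = names(files),
      file = basename(files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE)
  )
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done: %d artifacts in %s [%.1fs total]", length(paths),
      config$out_dir, proc.time()[3] - t_all)
  invisible(list(manifest = manifest, paths = paths, models = models,
                 results = results, aggregate = agg))
}

#' Loess smoother of a bivariate relationship
#'
#' Descriptive local-regression smoother of `y` on `x`, optionally by
#' group, evaluated on a regular grid with a pointwise 95% band. Used for
#' exploratory yield-pH and fertilizer-pH plots before any model fitting.
#'
#' @param panel data.frame.
#' @param x,y Column names.
#' @param by Optional grouping column (e.g. `"region"`).
#' @param span Loess span (default 0.75).
#' @param n_grid Number of evaluation points.
#' @param degree Local polynomial degree (default 2).
#' @return data.frame of class `loess_curve` with columns `group`, `x`,
#'   `fit`, `lwr`, `upr`.
#' @export
smooth_bivariate <- function(panel, x, y, by = NULL, span = 0.75,
                             n_grid = 100, degree = 2) {
  check_columns(panel, c(x, y, by), "panel")
  groups <- if (is.null(by)) list(all = panel) else
    split(panel, panel[[by]])
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < 30) {
      stop(sprintf("group '%s' has %d points; need >= 30", g, nrow(d)),
           call. = FALSE)
    }
    if (var(d[[x]]) == 0) {
      stop(sprintf("'%s' is constant within group '%s'", x, g),
           call. = FALSE)
    }
    d2 <- data.frame(.x = d[[x]], .y = d[[y]])
    fit <- loess(.y ~ .x, data = d2, span = span, degree = degree)
    grid <- seq(min(d2$.x), max(d2$.x), length.out = n_grid)
    pr <- predict(fit, data.frame(.x = grid), se = TRUE)
    data.frame(group = g, x = grid, fit = pr$fit,
               lwr = pr$fit - 1.96 * pr$se.fit,
               upr = pr$fit + 1.96 * pr$se.fit,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), xvar = x, yvar = y,
            class = c("loess_curve", "data.frame"))
}

#' @export
plot.loess_curve <- function(x, ...) {
  groups <- unique(x$group)
  plot(range(x$x), range(x$lwr, x$upr, na.rm = TRUE), type = "n",
       xlab = attr(x, "xvar"), ylab = attr(x, "yvar"), ...)
  for (i in seq_along(groups)) {
    d <- x[x$group == groups[i], ]
    polygon(c(d$x, rev(d$x)), c(d$lwr, rev(d$upr)),
            col = adjustcolor(i, 0.2), border = NA)
    lines(d$x, d$fit, col = i, lwd = 2)
  }
  if (length(groups) > 1) {
    legend("topleft", legend = groups, col = seq_along(groups), lwd = 2,
           bty = "n")
  }
  invisible(x)
}
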