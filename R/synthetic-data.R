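## Synthetic sub-kebele panel generator.
##
## Emulates the statistical structure of a national agricultural sample
## survey aggregated to sub-kebele level (one row per sub-kebele x year x
## crop) joined to gridded soil properties: a concave pH-yield response
## peaking near pH 6.5, a diminishing-returns fertilizer response,
## region-specific pH distributions, and a configurable within-region
## correlation between fertilizer use and soil pH.

PANEL_COLUMNS <- c("subkebele_id", "year", "region", "agro_eco_zone",
                   "x_km", "y_km", "PH", "CEC", "SOC", "SND", "Elevation",
                   "PDSI", "Fert", "Ext.Area", "Imp.Seed", "Irg.Area",
                   "Damage", "DistPP", "PSNP", "AGP", "crop", "Yield")

#' Default regional pH mixture
#'
#' Four growing regions with per-region pH mean/sd, sampling weight and a
#' planted within-region slope of fertilizer use on pH (kg/ha per pH unit).
#' The defaults plant (a) a region, Amhara, where farmers apply 45.8 kg/ha
#' more fertilizer for each unit drop in pH, and (b) a region, Tigray, whose
#' pH distribution contains essentially no moderately acidic (5.5, 6] soil,
#' so that class-by-region aggregation exercises empty-cell handling.
#'
#' @return data.frame with columns `region`, `ph_mean`, `ph_sd`, `weight`,
#'   `fert_ph_slope`.
#' @export
default_regions <- function() {
  data.frame(
    region = c("Amhara", "Oromia", "SNNP", "Tigray"),
    ph_mean = c(5.6, 6.0, 5.4, 6.9),
    ph_sd = c(0.5, 0.6, 0.5, 0.25),
    weight = c(0.30, 0.30, 0.25, 0.15),
    fert_ph_slope = c(-45.8, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Default planted ("true") yield response
#'
#' The known-truth response used by the generator and by parameter-recovery
#' tests. Per crop: an intercept (mt/ha), a concave quadratic in pH with
#' peak at `ph_peak` and amplitude `ph_gain` (the yield difference between
#' pH `ph_peak - 1` and the peak, so the planted gain of the 5.5 to 6.5
#' correction is `ph_gain` exactly), and a linear + quadratic fertilizer
#' term with diminishing returns. Shared across crops: linear effects of
#' the remaining covariates, a yearly trend and zone offsets.
#'
#' The default amplitudes (0.30 mt/ha wheat, 0.20 barley) and fertilizer
#' responses (0.16 and 0.24 mt/ha per additional 100 kg/ha at the mean
#' application rate) match published response magnitudes for Ethiopian
#' wheat and barley; intercepts are set so the gains correspond to about
#' 21.5% and 18.5% of the predicted yield at pH 5.5.
#'
#' @return Nested list with elements `wheat`, `barley`, `effects`,
#'   `year_trend`.
#' @export
default_true_response <- function() {
  list(
    wheat = list(intercept = 1.006, ph_peak = 6.5, ph_gain = 0.30,
                 fert_lin = 0.0024, fert_quad = -2e-6),
    barley = list(intercept = 0.472, ph_peak = 6.5, ph_gain = 0.20,
                  fert_lin = 0.0032, fert_quad = -2e-6),
    effects = c(PDSI = 0.05, Elevation = 5e-5, SOC = 0.05, SND = -0.002,
                CEC = 0.005, Ext.Area = 0.002, Imp.Seed = 0.003,
                Irg.Area = 0, Damage = -0.004, DistPP = -0.002,
                PSNP = -0.05, AGP = 0.05),
    year_trend = 0.02
  )
}

default_covariate_params <- function() {
  list(
    cec_meanlog = log(15), cec_sdlog = 0.3,
    soc_meanlog = log(2), soc_sdlog = 0.4,
    snd_mean = 35, snd_sd = 10,
    elev_mean = 2000, elev_sd = 400,
    pdsi_sd = 1.5,
    fert_mean = 150, fert_sd = 40,
    ext_mean = 50, ext_sd = 20,
    imp_mean = 20, imp_sd = 10,
    irg_mean = 5, irg_sd = 5,
    dmg_mean = 10, dmg_sd = 8,
    distpp_meanlog = log(10), distpp_sdlog = 0.5,
    psnp_p = 0.3, agp_p = 0.3
  )
}

#' Synthetic study configuration
#'
#' All knobs of the synthetic panel and landscape generator. The defaults
#' are the package's reference study conditions; tests and examples vary
#' only what they need.
#'
#' @param n_subkebeles Number of sub-kebeles (each observed every year for
#'   every crop).
#' @param years Harvest years (default 2010:2016).
#' @param regions Regional pH mixture, see [default_regions()].
#' @param n_zones Number of agro-ecological zones (fixed-effect levels).
#' @param crops Crops generated (default wheat and barley).
#' @param true_response Planted yield response, see
#'   [default_true_response()].
#' @param covariates Distributional parameters of the covariates.
#' @param noise_sd Yield noise standard deviation, mt/ha (> 0 unless
#'   exactly 0 for noiseless oracles).
#' @param ph_range Soil pH values are clipped to this range.
#' @param grid_shape Landscape grid as c(rows, cols).
#' @param cellsize_km Landscape cell size in km.
#' @param n_crushers Number of lime crusher locations (>= 1).
#' @param crusher_price Crusher-gate lime price, ETB/mt.
#' @param seed Master seed; all internal streams are derived from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subkebeles = 250, years = 2010:2016,
                         regions = default_regions(), n_zones = 5,
                         crops = c("wheat", "barley"),
                         true_response = default_true_response(),
                         covariates = default_covariate_params(),
                         noise_sd = 0.35, ph_range = c(4.2, 8.5),
                         grid_shape = c(40, 40), cellsize_km = 1,
                         n_crushers = 3, crusher_price = 750, seed = 1) {
  check_number(n_subkebeles, "n_subkebeles", lower = 1)
  if (!is.numeric(years) || length(years) < 1) {
    stop("'years' must be a non-empty numeric vector", call. = FALSE)
  }
  check_columns(regions, c("region", "ph_mean", "ph_sd", "weight",
                           "fert_ph_slope"), "regions")
  if (any(regions$weight <= 0)) {
    stop("'regions$weight' must be positive", call. = FALSE)
  }
  check_number(n_zones, "n_zones", lower = 1)
  if (!length(crops)) stop("'crops' must be non-empty", call. = FALSE)
  for (crop in crops) {
    tr <- true_response[[crop]]
    if (is.null(tr)) {
      stop(sprintf("'true_response' has no entry for crop '%s'", crop),
           call. = FALSE)
    }
    check_number(tr$ph_peak, sprintf("true_response$%s$ph_peak", crop),
                 lower = 6, upper = 7)
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_crushers, "n_crushers", lower = 1)
  check_number(crusher_price, "crusher_price", lower = 0, open_lower = TRUE)
  check_number(seed, "seed")
  ## enough rows to identify every fixed-effect cell plus covariates
  n_cells <- length(years) * n_zones
  min_n <- ceiling((n_cells + 14 + 10) / length(years))
  if (n_subkebeles * length(years) < n_cells + 14 + 10) {
    stop(sprintf(
      "'n_subkebeles' too small: need >= %d sub-kebeles for %d fixed-effect cells",
      min_n, n_cells), call. = FALSE)
  }
  structure(list(n_subkebeles = as.integer(n_subkebeles), years = years,
                 regions = regions, n_zones = as.integer(n_zones),
                 crops = crops, true_response = true_response,
                 covariates = covariates, noise_sd = noise_sd,
                 ph_range = ph_range, grid_shape = grid_shape,
                 cellsize_km = cellsize_km,
                 n_crushers = as.integer(n_crushers),
                 crusher_price = crusher_price, seed = as.integer(seed)),
            class = "synth_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Planted ("true") yield of a covariate row
#'
#' Closed-form evaluation of the generator's planted response, exposed so
#' tests can compute the true yield change of any pH or fertilizer move
#' analytically.
#'
#' @param covariates data.frame of covariate rows; must contain `PH`,
#'   `Fert`, every covariate named in the planted effects, and (unless
#'   `crop` is given) a `crop` column. `year` and `agro_eco_zone` are
#'   optional; missing fixed effects contribute 0.
#' @param config A [synth_config()].
#' @param crop Crop name; defaults to the `crop` column of `covariates`.
#' @return Numeric vector of noiseless yields, mt/ha.
#' @export
true_yield <- function(covariates, config = synth_config(), crop = NULL) {
  covariates <- as.data.frame(covariates)
  crop <- crop %||% covariates$crop
  if (is.null(crop)) {
    stop("'crop' not given and no 'crop' column present", call. = FALSE)
  }
  crop <- rep_len(crop, nrow(covariates))
  tr <- config$true_response
  check_columns(covariates, c("PH", "Fert", names(tr$effects)),
                "covariates")
  bad <- setdiff(unique(crop), names(tr))
  if (length(bad)) {
    stop(sprintf("no planted response for crop(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  pars <- lapply(tr[crop], function(p)
    c(p$intercept, p$ph_peak, p$ph_gain, p$fert_lin, p$fert_quad))
  pm <- do.call(rbind, pars)
  y <- pm[, 1] - pm[, 3] * (covariates$PH - pm[, 2])^2 +
    pm[, 4] * covariates$Fert + pm[, 5] * covariates$Fert^2
  for (v in names(tr$effects)) {
    y <- y + tr$effects[[v]] * covariates[[v]]
  }
  if (!is.null(covariates$year)) {
    y <- y + tr$year_trend * (covariates$year - min(config$years))
  }
  if (!is.null(covariates$agro_eco_zone)) {
    zone_eff <- zone_effects(config)
    y <- y + zone_eff[covariates$agro_eco_zone]
  }
  unname(y)
}

zone_effects <- function(config) {
  if (config$n_zones == 1) return(c(zone1 = 0))
  setNames(seq(-0.1, 0.1, length.out = config$n_zones),
           paste0("zone", seq_len(config$n_zones)))
}

#' Generate a synthetic sub-kebele panel
#'
#' Draws sub-kebele locations, soil properties and policy membership once
#' per sub-kebele, management and weather per year, and computes yields as
#' the planted response plus Gaussian noise (truncated below at zero).
#' Deterministic for a fixed config (the panel stream is derived from the
#' master seed).
#'
#' @param config A [synth_config()].
#' @return data.frame with one row per sub-kebele x year x crop and the
#'   standard panel columns (see [validate_panel()]); no missing values.
#' @export
generate_panel <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cv <- config$covariates
  n <- config$n_subkebeles

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  reg <- config$regions
  region_idx <- sample.int(nrow(reg), n, replace = TRUE,
                           prob = reg$weight / sum(reg$weight))
  ## round-robin zone assignment guarantees every (year, zone) cell non-empty
  zone <- paste0("zone", sample(rep_len(seq_len(config$n_zones), n)))
  extent_x <- config$grid_shape[2] * config$cellsize_km
  extent_y <- config$grid_shape[1] * config$cellsize_km
  sk <- data.frame(
    subkebele_id = sprintf("sk%05d", seq_len(n)),
    region = reg$region[region_idx],
    agro_eco_zone = zone,
    x_km = runif(n, 0, extent_x),
    y_km = runif(n, 0, extent_y),
    PH = clamp(rnorm(n, reg$ph_mean[region_idx], reg$ph_sd[region_idx]),
               config$ph_range[1], config$ph_range[2]),
    CEC = rlnorm(n, cv$cec_meanlog, cv$cec_sdlog),
    SOC = rlnorm(n, cv$soc_meanlog, cv$soc_sdlog),
    SND = clamp(rnorm(n, cv$snd_mean, cv$snd_sd), 5, 90),
    Elevation = clamp(rnorm(n, cv$elev_mean, cv$elev_sd), 500, 3500),
    DistPP = rlnorm(n, cv$distpp_meanlog, cv$distpp_sdlog),
    PSNP = rbinom(n, 1, cv$psnp_p),
    AGP = rbinom(n, 1, cv$agp_p),
    stringsAsFactors = FALSE
  )

  grid <- expand.grid(i = seq_len(n), year = config$years,
                      crop = config$crops, stringsAsFactors = FALSE)
  panel <- sk[grid$i, ]
  panel$year <- grid$year
  panel$crop <- grid$crop
  m <- nrow(panel)

  ## weather varies by sub-kebele x year (shared across crops)
  ny <- length(config$years)
  pdsi_sy <- matrix(clamp(rnorm(n * ny, 0, cv$pdsi_sd), -5, 5), n, ny)
  panel$PDSI <- pdsi_sy[cbind(grid$i, match(grid$year, config$years))]

  ## management varies by row; fertilizer tracks pH within regions with the
  ## planted slope
  slope <- reg$fert_ph_slope[region_idx][grid$i]
  ph_ctr <- panel$PH - reg$ph_mean[region_idx][grid$i]
  panel$Fert <- pmax(rnorm(m, cv$fert_mean, cv$fert_sd) + slope * ph_ctr, 0)
  panel$Ext.Area <- clamp(rnorm(m, cv$ext_mean, cv$ext_sd), 0, 100)
  panel$Imp.Seed <- clamp(rnorm(m, cv$imp_mean, cv$imp_sd), 0, 100)
  panel$Irg.Area <- clamp(rnorm(m, cv$irg_mean, cv$irg_sd), 0, 100)
  panel$Damage <- clamp(rnorm(m, cv$dmg_mean, cv$dmg_sd), 0, 100)

  panel$Yield <- pmax(true_yield(panel, config) +
                        rnorm(m, 0, config$noise_sd), 0)
  panel <- panel[PANEL_COLUMNS]
  rownames(panel) <- NULL
  validate_panel(panel)
  panel
}

#' Validate a sub-kebele panel
#'
#' Checks the structural invariants the analysis relies on: all standard
#' columns present, no missing values, percentage fields in [0, 100], pH in
#' (3, 10), non-negative yields, and every (year, zone) fixed-effect cell
#' non-empty.
#'
#' @param panel data.frame to validate.
#' @return The panel, invisibly; errors describe the first violated field.
#' @export
validate_panel <- function(panel) {
  check_columns(panel, PANEL_COLUMNS, "panel")
  if (anyNA(panel[PANEL_COLUMNS])) {
    bad <- PANEL_COLUMNS[colSums(is.na(panel[PANEL_COLUMNS])) > 0]
    stop(sprintf("panel contains missing values in: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (v in c("Ext.Area", "Imp.Seed", "Irg.Area", "Damage")) {
    if (any(panel[[v]] < 0 | panel[[v]] > 100)) {
      stop(sprintf("'%s' outside [0, 100]", v), call. = FALSE)
    }
  }
  if (any(panel$PH <= 3 | panel$PH >= 10)) {
    stop("'PH' outside (3, 10)", call. = FALSE)
  }
  if (any(panel$Yield < 0)) stop("'Yield' negative", call. = FALSE)
  cells <- table(panel$year, panel$agro_eco_zone)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop(sprintf("empty (year, zone) cell(s): %s",
                 paste(rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]],
                       sep = "/", collapse = ", ")), call. = FALSE)
  }
  invisible(panel)
}
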