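## Marginal-effect curves, pH-change yield gains, and the fertilizer
## quantity equivalent to a lime-induced gain.

#' Marginal response curve of one covariate
#'
#' Predicted yield over a grid of one covariate with all other covariates
#' held at their training means (binary covariates at their sample shares)
#' and the fixed effects at the model's reference year and zone. Any
#' covariate can instead be pinned through `overrides` (e.g. fertilizer
#' response at pH 5.5). Pointwise confidence intervals come from the
#' coefficient covariance.
#'
#' @param model A [yield_response()] fit.
#' @param vary Name of the covariate to vary.
#' @param grid Numeric grid for `vary`; default 100 equally spaced points
#'   over the training range. Points outside the training range trigger an
#'   extrapolation warning, not a failure.
#' @param overrides Named list pinning other covariates (or the fixed
#'   effects `year` / `agro_eco_zone`).
#' @param level Confidence level (default 0.95).
#' @return An object of class `response_curve`: data.frame with columns
#'   `value`, `fit`, `lwr`, `upr` and attributes `vary`, `overrides`,
#'   `crop`.
#' @export
marginal_curve <- function(model, vary, grid = NULL, overrides = list(),
                           level = 0.95) {
  stopifnot(inherits(model, "yield_response"))
  if (!vary %in% c(model$spec$continuous, model$spec$binary)) {
    stop(sprintf("'%s' is not a model covariate", vary), call. = FALSE)
  }
  rng <- model$ranges[, vary]
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 100)
  if (any(diff(grid) <= 0)) {
    stop("'grid' must be strictly increasing", call. = FALSE)
  }
  outside <- grid < rng[1] | grid > rng[2]
  if (any(outside)) {
    warning(sprintf("%d grid point(s) outside the training support of %s",
                    sum(outside), vary), call. = FALSE)
  }
  nd <- newdata_rows(model, n = length(grid), overrides = overrides)
  nd[[vary]] <- grid
  pr <- predict(model, nd, interval = "confidence", level = level)
  structure(data.frame(value = grid, fit = pr[, "fit"],
                       lwr = pr[, "lwr"], upr = pr[, "upr"]),
            vary = vary, overrides = overrides, crop = model$crop,
            level = level,
            class = c("response_curve", "data.frame"))
}

#' @export
plot.response_curve <- function(x, main = NULL, ...) {
  vary <- attr(x, "vary")
  main <- main %||% sprintf("Yield response to %s%s", vary,
                           if (!is.null(attr(x, "crop")))
                             paste0(" (", attr(x, "crop"), ")") else "")
  plot(x$value, x$fit, type = "n", xlab = vary, ylab = "Yield (mt/ha)",
       ylim = range(x$lwr, x$upr), main = main, ...)
  polygon(c(x$value, rev(x$value)), c(x$lwr, rev(x$upr)),
          col = gray(0.85), border = NA)
  lines(x$value, x$fit, lwd = 2)
  invisible(x)
}

#' Yield gain from a pH change
#'
#' Difference in predicted yield between two pH levels with all other
#' covariates at their training means, as an absolute gain (mt/ha) and as a
#' percentage of the predicted yield at the starting pH. Under the default
#' "raise to a minimum" convention a soil already at or above the target pH
#' gains nothing.
#'
#' @param model A [yield_response()] fit.
#' @param ph_from,ph_to Starting and target pH (within training support).
#' @param overrides Named list pinning other covariates.
#' @param minimum_target If `TRUE` (default) return a zero gain whenever
#'   `ph_from >= ph_to`; set `FALSE` for pure prediction differences
#'   (which are additive along a pH path).
#' @param fe_baseline How the fixed effects enter the baseline prediction
#'   that the percentage gain is measured against: `"means"` (default)
#'   averages the year/zone dummies at their sample shares -- the average
#'   sub-kebele hectare -- while `"reference"` uses the model's reference
#'   cell. The absolute gain is unaffected: fixed effects cancel in the
#'   difference.
#' @param level Confidence level for the gain interval.
#' @return An object of class `yield_gain_est`: list with `gain` (mt/ha),
#'   `pct` (% of the baseline prediction), `se`, `lwr`, `upr`, and the
#'   baseline prediction `baseline`.
#' @export
yield_gain <- function(model, ph_from, ph_to, overrides = list(),
                       minimum_target = TRUE,
                       fe_baseline = c("means", "reference"),
                       level = 0.95) {
  fe_baseline <- match.arg(fe_baseline)
  stopifnot(inherits(model, "yield_response"))
  check_number(ph_from, "ph_from", lower = 3, upper = 10,
               open_lower = TRUE, open_upper = TRUE)
  check_number(ph_to, "ph_to", lower = 3, upper = 10,
               open_lower = TRUE, open_upper = TRUE)
  nd_from <- newdata_rows(model, overrides = overrides)
  nd_from$PH <- ph_from
  Xb <- design_matrix(model, nd_from)
  if (fe_baseline == "means") {
    for (l in names(model$fe$year_shares)[-1]) {
      cn <- paste0("year_f", l)
      if (cn %in% colnames(Xb)) Xb[, cn] <- model$fe$year_shares[[l]]
    }
    for (l in names(model$fe$zone_shares)[-1]) {
      cn <- paste0("zone_f", l)
      if (cn %in% colnames(Xb)) Xb[, cn] <- model$fe$zone_shares[[l]]
    }
  }
  baseline <- drop(Xb %*% model$coefficients)
  if (minimum_target && ph_from >= ph_to) {
    return(structure(list(gain = 0, pct = 0, se = 0, lwr = 0, upr = 0,
                          baseline = baseline, ph_from = ph_from,
                          ph_to = ph_to),
                     class = "yield_gain_est"))
  }
  nd_to <- nd_from
  nd_to$PH <- ph_to
  X1 <- design_matrix(model, complete_nd(model, nd_from))
  X2 <- design_matrix(model, complete_nd(model, nd_to))
  d <- X2 - X1
  gain <- drop(d %*% model$coefficients)
  se <- sqrt(max(drop(d %*% model$vcov %*% t(d)), 0))
  tq <- qt(1 - (1 - level) / 2, model$df_residual)
  structure(list(gain = gain, pct = 100 * gain / baseline, se = se,
                 lwr = gain - tq * se, upr = gain + tq * se,
                 baseline = baseline, ph_from = ph_from, ph_to = ph_to),
            class = "yield_gain_est")
}

## newdata_rows output already has all columns; this re-fills anything the
## caller dropped
complete_nd <- function(model, nd) {
  base <- newdata_rows(model, n = nrow(nd))
  for (v in names(nd)) base[[v]] <- nd[[v]]
  base
}

#' @export
print.yield_gain_est <- function(x, ...) {
  cat(sprintf(
    "Yield gain pH %.2f -> %.2f: %.3f mt/ha (%.1f%%), 95%% CI [%.3f, %.3f]\n",
    x$ph_from, x$ph_to, x$gain, x$pct, x$lwr, x$upr))
  invisible(x)
}

#' Fertilizer quantity equivalent to a target yield gain
#'
#' The smallest additional annual fertilizer application (kg/ha) whose
#' predicted yield response, at a given pH and with everything else at the
#' training means, at least matches `target_gain`. Found by a grid bracket
#' plus bisection to `tol`. Because the fitted fertilizer response has
#' diminishing returns, some gains are unattainable within the search cap;
#' these are flagged and returned with the maximum achievable gain.
#'
#' @param model A [yield_response()] fit.
#' @param target_gain Target yield gain, mt/ha (>= 0).
#' @param at_ph Soil pH at which the response is evaluated.
#' @param baseline_fert Baseline application, kg/ha (default: training
#'   mean).
#' @param cap Largest additional application searched (default: the
#'   training 99th percentile of fertilizer use).
#' @param tol Bisection tolerance, kg/ha.
#' @return An object of class `fert_equiv`: list with `kg_ha` (NA when
#'   unattainable), `attainable`, `max_gain`, `cap`, `target_gain`,
#'   `at_ph`, `baseline_fert`.
#' @export
equivalent_fertilizer <- function(model, target_gain, at_ph,
                                  baseline_fert = NULL, cap = NULL,
                                  tol = 1e-3) {
  stopifnot(inherits(model, "yield_response"))
  if (!is.numeric(target_gain) || length(target_gain) != 1 ||
      is.na(target_gain) || target_gain < 0) {
    stop("'target_gain' must be a single non-negative number",
         call. = FALSE)
  }
  baseline_fert <- baseline_fert %||% unname(model$means["Fert"])
  cap <- cap %||% model$fert_cap
  gain_at <- function(df) {
    nd <- newdata_rows(model, n = length(df),
                       overrides = list(PH = at_ph))
    nd$Fert <- baseline_fert + df
    nd0 <- newdata_rows(model, n = length(df),
                        overrides = list(PH = at_ph))
    nd0$Fert <- baseline_fert
    drop(design_matrix(model, nd) %*% model$coefficients) -
      drop(design_matrix(model, nd0) %*% model$coefficients)
  }
  mk <- function(kg, attainable, max_gain) {
    structure(list(kg_ha = kg, attainable = attainable,
                   max_gain = max_gain, cap = cap,
                   target_gain = target_gain, at_ph = at_ph,
                   baseline_fert = baseline_fert),
              class = "fert_equiv")
  }
  if (target_gain == 0) return(mk(0, TRUE, NA_real_))
  grid <- seq(0, cap, length.out = 512)
  g <- gain_at(grid)
  hit <- which(g >= target_gain)
  if (!length(hit)) {
    return(mk(NA_real_, FALSE, max(g)))
  }
  i <- hit[1]
  if (i == 1) return(mk(0, TRUE, NA_real_))
  lo <- grid[i - 1]; hi <- grid[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gain_at(mid) >= target_gain) hi <- mid else lo <- mid
  }
  mk(hi, TRUE, NA_real_)
}

#' @export
print.fert_equiv <- function(x, ...) {
  if (x$attainable) {
    cat(sprintf(
      "Fertilizer equivalent: +%.1f kg/ha/yr for a %.2f mt/ha gain at pH %.2f\n",
      x$kg_ha, x$target_gain, x$at_ph))
  } else {
    cat(sprintf(
      "Gain of %.2f mt/ha unattainable within +%.0f kg/ha (max %.3f mt/ha)\n",
      x$target_gain, x$cap, x$max_gain))
  }
  invisible(x)
}

#' Within-region slope of fertilizer use on soil pH
#'
#' Descriptive OLS of fertilizer application on pH within one region,
#' summarising how strongly farmers in that region target fertilizer
#' toward (or away from) acidic soils.
#'
#' @param panel Sub-kebele panel.
#' @param region Region name (needs >= 30 rows).
#' @return List with `slope` (kg/ha per pH unit), `se`, `p_value`, `n`.
#' @export
region_fert_ph_slope <- function(panel, region) {
  check_columns(panel, c("region", "Fert", "PH"))
  sub <- panel[panel$region == region, , drop = FALSE]
  if (nrow(sub) < 30) {
    stop(sprintf("region '%s' has %d rows; need >= 30", region,
                 nrow(sub)), call. = FALSE)
  }
  fit <- lm(Fert ~ PH, data = sub)
  cf <- summary(fit)$coefficients
  list(slope = cf["PH", "Estimate"], se = cf["PH", "Std. Error"],
       p_value = cf["PH", "Pr(>|t|)"], n = nrow(sub), region = region)
}

#' Serialize / restore a fitted yield response model as JSON
#'
#' The JSON stores everything needed to reproduce predictions: selected
#' orders, the frozen orthogonal-polynomial bases, coefficients and their
#' covariance, covariate means and ranges, fixed-effect levels and fit
#' statistics. Training fitted values and residuals are not stored, so
#' `residuals()` and `simulate()` are unavailable on a restored model;
#' `predict()` and everything built on it round-trip exactly.
#'
#' @param model A [yield_response()] fit.
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` a `yield_response` object.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "yield_response"))
  payload <- list(
    crop = model$crop,
    orders = as.list(model$orders),
    basis = lapply(model$basis, function(b)
      list(degree = b$degree, alpha = b$coefs$alpha,
           norm2 = b$coefs$norm2)),
    coefficients = as.list(model$coefficients),
    vcov = model$vcov,
    sigma = model$sigma,
    df_residual = model$df_residual,
    r_squared = model$r_squared,
    adj_r_squared = model$adj_r_squared,
    means = as.list(model$means),
    ranges = model$ranges,
    fert_cap = model$fert_cap,
    fe = model$fe,
    n = model$n,
    spec = list(continuous = model$spec$continuous,
                binary = model$spec$binary, fixed = model$spec$fixed,
                max_order = model$spec$max_order,
                alpha = model$spec$alpha)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(p$coefficients)
  vc <- as.matrix(p$vcov)
  dimnames(vc) <- list(names(coefs), names(coefs))
  spec <- model_spec(continuous = p$spec$continuous,
                     binary = p$spec$binary, fixed = p$spec$fixed,
                     max_order = p$spec$max_order, alpha = p$spec$alpha)
  basis <- lapply(p$basis, function(b)
    list(degree = as.integer(b$degree),
         coefs = list(alpha = as.numeric(b$alpha),
                      norm2 = as.numeric(b$norm2))))
  ranges <- as.matrix(p$ranges)
  colnames(ranges) <- spec$continuous
  structure(list(
    coefficients = coefs, vcov = vc, sigma = p$sigma,
    df_residual = p$df_residual, r_squared = p$r_squared,
    adj_r_squared = p$adj_r_squared,
    orders = unlist(p$orders), basis = basis, spec = spec,
    crop = p$crop, means = unlist(p$means), ranges = ranges,
    fert_cap = p$fert_cap,
    fe = list(year_levels = as.character(p$fe$year_levels),
              zone_levels = as.character(p$fe$zone_levels),
              ref_year = as.character(p$fe$ref_year),
              ref_zone = as.character(p$fe$ref_zone),
              year_shares = unlist(p$fe$year_shares),
              zone_shares = unlist(p$fe$zone_shares)),
    n = p$n, fitted_values = NULL, residuals_values = NULL,
    call = NULL
  ), class = "yield_response")
}
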