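## Soil chemistry: acidity classes, the pH -> base-saturation buffer model,
## and the lime requirement.

## mt/acre -> mt/hectare
MT_AC_TO_MT_HA <- 2.4710

#' Classify soil acidity from pH
#'
#' Standard agronomic classes: soils with pH at or below 5.5 are "highly"
#' acidic, those with pH in (5.5, 6] "moderately" acidic, and anything above
#' 6 "non-acidic". Both boundaries are closed on the acidic side.
#'
#' @param ph Numeric vector of soil pH values; each must lie in (3, 10).
#' @return Character vector with values `"highly"`, `"moderately"` or
#'   `"non-acidic"`.
#' @examples
#' classify_acidity(c(5.2, 5.5, 5.8, 6.0, 6.7))
#' @export
classify_acidity <- function(ph) {
  if (!is.numeric(ph) || anyNA(ph)) {
    stop("'ph' must be numeric with no missing values", call. = FALSE)
  }
  if (any(ph <= 3 | ph >= 10)) {
    stop(sprintf("'ph' must lie in (3, 10); offending value(s): %s",
                 paste(signif(ph[ph <= 3 | ph >= 10], 4), collapse = ", ")),
         call. = FALSE)
  }
  ifelse(ph <= 5.5, "highly", ifelse(ph <= 6, "moderately", "non-acidic"))
}

#' Piecewise-linear pH to base-saturation model
#'
#' Base saturation -- the fraction of the cation exchange complex occupied by
#' basic cations -- rises with pH. The mapping is represented by ordered
#' anchor points joined by linear interpolation, together with a calibration
#' scalar `k` applied to the lime requirement so that the model can be
#' adapted to local (here Ethiopian) soil conditions.
#'
#' The default anchors are (4.5, 0.25), (5.5, 0.40), (6.5, 0.70),
#' (7.0, 0.85), and the default `k` is chosen by [calibrate_lime_k()] so
#' that raising a reference soil (CEC `ref_cec` cmol(+)/kg) from pH 5.5 to
#' 6.5 requires 3.12 mt/ha of lime, the published per-hectare rate for that
#' one-unit correction.
#'
#' @param anchors Two-column matrix or data.frame of (pH, base-saturation
#'   fraction) pairs, strictly increasing in both coordinates, fractions in
#'   (0, 1).
#' @param k Calibration scalar multiplying the lime requirement. If `NULL`,
#'   computed by [calibrate_lime_k()] with the remaining defaults.
#' @param ref_cec Reference cation exchange capacity (cmol(+)/kg) used only
#'   when calibrating `k`.
#' @return An object of class `bs_model`.
#' @seealso [base_saturation()], [lime_requirement()]
#' @export
base_saturation_model <- function(anchors = default_bs_anchors(),
                                  k = NULL, ref_cec = 10) {
  anchors <- as.matrix(anchors)
  if (!is.numeric(anchors) || ncol(anchors) != 2 || nrow(anchors) < 2 ||
      anyNA(anchors)) {
    stop("'anchors' must be a numeric matrix of >= 2 rows (pH, fraction)",
         call. = FALSE)
  }
  if (any(diff(anchors[, 1]) <= 0) || any(diff(anchors[, 2]) <= 0)) {
    stop("'anchors' must be strictly increasing in both pH and base saturation",
         call. = FALSE)
  }
  if (any(anchors[, 2] <= 0 | anchors[, 2] >= 1)) {
    stop("anchor base saturation must lie in (0, 1)", call. = FALSE)
  }
  colnames(anchors) <- c("ph", "bs")
  m <- structure(list(anchors = anchors, k = 1), class = "bs_model")
  m$k <- if (is.null(k)) calibrate_lime_k(model = m, ref_cec = ref_cec) else
    check_number(k, "k", lower = 0, open_lower = TRUE)
  m
}

default_bs_anchors <- function() {
  cbind(ph = c(4.5, 5.5, 6.5, 7.0), bs = c(0.25, 0.40, 0.70, 0.85))
}

#' @export
print.bs_model <- function(x, ...) {
  cat("pH -> base saturation model (piecewise linear)\n")
  cat(sprintf("  anchors: %s\n",
              paste(sprintf("(%.2f, %.2f)", x$anchors[, 1], x$anchors[, 2]),
                    collapse = " ")))
  cat(sprintf("  calibration scalar k = %.6f\n", x$k))
  invisible(x)
}

#' Calibration scalar for the lime requirement
#'
#' Solves for the scalar `k` such that [lime_requirement()] returns
#' `target_mt_ha` for the reference correction `ph_from -> ph_to` on a soil
#' with CEC `ref_cec`, under the given anchor model and default tillage
#' depth, CCE and fineness.
#'
#' @param target_mt_ha Lime rate (mt/ha) the reference correction must
#'   reproduce; default 3.12.
#' @param ref_cec Reference CEC, cmol(+)/kg.
#' @param ph_from,ph_to Reference pH correction (default 5.5 to 6.5).
#' @param model A `bs_model` (its `k` is ignored).
#' @return The calibration scalar.
#' @export
calibrate_lime_k <- function(target_mt_ha = 3.12, ref_cec = 10,
                             ph_from = 5.5, ph_to = 6.5,
                             model = base_saturation_model(k = 1)) {
  check_number(target_mt_ha, "target_mt_ha", lower = 0, open_lower = TRUE)
  check_number(ref_cec, "ref_cec", lower = 0, open_lower = TRUE)
  bs_o <- base_saturation(ph_from, model)
  bs_t <- base_saturation(ph_to, model)
  raw <- ref_cec * (bs_t - bs_o) / (2 * (1 - bs_o)) * MT_AC_TO_MT_HA
  target_mt_ha / raw
}

#' Base saturation at a given pH
#'
#' Linear interpolation between the model's anchors; pH outside the anchor
#' span is clamped to the nearest anchor with a warning.
#'
#' @param ph Numeric vector of pH values.
#' @param model A [base_saturation_model()].
#' @return Base saturation fractions in (0, 1); monotone non-decreasing
#'   in `ph`.
#' @export
base_saturation <- function(ph, model = base_saturation_model()) {
  if (!inherits(model, "bs_model")) {
    stop("'model' must be a base_saturation_model()", call. = FALSE)
  }
  if (!is.numeric(ph) || anyNA(ph)) {
    stop("'ph' must be numeric with no missing values", call. = FALSE)
  }
  a <- model$anchors
  out_of_span <- ph < a[1, "ph"] | ph > a[nrow(a), "ph"]
  if (any(out_of_span)) {
    warning(sprintf("%d pH value(s) outside anchor span [%g, %g]; clamped",
                    sum(out_of_span), a[1, "ph"], a[nrow(a), "ph"]),
            call. = FALSE)
  }
  approx(a[, "ph"], a[, "bs"], xout = ph, rule = 2)$y
}

#' Lime application specification
#'
#' Parameters of the liming operation entering the lime-requirement formula:
#' tillage depth (TD, inches; the formula is normalised to a 6-inch
#' incorporation depth), calcium carbonate equivalent (CCE, neutralising
#' power relative to pure calcite) and relative fineness (F) of the liming
#' material, the target pH, and the base-saturation model supplying the
#' buffering term.
#'
#' @param tillage_depth_in Tillage depth in inches (> 0; default 6).
#' @param cce Calcium carbonate equivalent as a fraction in (0, 1.5].
#' @param fineness Relative fineness factor in (0, 1.5].
#' @param target_ph Target pH in (5, 8]; default 6.5.
#' @param bs_model A [base_saturation_model()].
#' @return An object of class `lime_spec`.
#' @export
lime_spec <- function(tillage_depth_in = 6, cce = 1.0, fineness = 1.0,
                      target_ph = 6.5, bs_model = base_saturation_model()) {
  check_number(tillage_depth_in, "tillage_depth_in", lower = 0,
               open_lower = TRUE)
  check_number(cce, "cce", lower = 0, upper = 1.5, open_lower = TRUE)
  check_number(fineness, "fineness", lower = 0, upper = 1.5,
               open_lower = TRUE)
  check_number(target_ph, "target_ph", lower = 5, upper = 8,
               open_lower = TRUE)
  if (!inherits(bs_model, "bs_model")) {
    stop("'bs_model' must be a base_saturation_model()", call. = FALSE)
  }
  structure(list(tillage_depth_in = tillage_depth_in, cce = cce,
                 fineness = fineness, target_ph = target_ph,
                 bs_model = bs_model),
            class = "lime_spec")
}

#' Lime requirement to reach a target pH
#'
#' Implements the base-saturation lime requirement
#' \deqn{L = CEC \cdot \frac{BS_t - BS_o}{2\,(1 - BS_o)} \cdot \frac{TD}{6}
#'   \cdot CCE \cdot F}
#' where \eqn{L} is in metric tons per acre, \eqn{BS_o} and \eqn{BS_t} are
#' the base saturations at the current and target pH, TD the tillage depth in
#' inches. The result is converted to mt/ha (factor 2.4710) and multiplied by
#' the model's calibration scalar `k`. Soils already at or above the target
#' pH require no lime.
#'
#' @param soil A data.frame (or list) with numeric columns/elements `ph` (in
#'   (3, 10)) and `cec` (> 0, cmol(+)/kg); one row per location.
#' @param spec A [lime_spec()].
#' @return Numeric vector of lime requirements in mt/ha, one per soil row.
#' @examples
#' lime_requirement(data.frame(ph = 5.5, cec = 10))  # the 3.12 mt/ha anchor
#' @export
lime_requirement <- function(soil, spec = lime_spec()) {
  if (!inherits(spec, "lime_spec")) {
    stop("'spec' must be a lime_spec()", call. = FALSE)
  }
  soil <- as.data.frame(soil)
  check_columns(soil, c("ph", "cec"), "soil")
  check_number(soil$ph, "soil$ph", lower = 3, upper = 10,
               open_lower = TRUE, open_upper = TRUE, len = nrow(soil))
  check_number(soil$cec, "soil$cec", lower = 0, open_lower = TRUE,
               len = nrow(soil))
  bs_t <- base_saturation(spec$target_ph, spec$bs_model)
  ## soils at or above target need no lime; cap at the target so their
  ## (discarded) deficit never probes the model outside its span
  bs_o <- base_saturation(pmin(soil$ph, spec$target_ph), spec$bs_model)
  if (any(bs_o >= 1)) {
    stop("base saturation at current pH >= 1: formula singular", call. = FALSE)
  }
  l_ac <- soil$cec * (bs_t - bs_o) / (2 * (1 - bs_o)) *
    (spec$tillage_depth_in / 6) * spec$cce * spec$fineness
  out <- l_ac * MT_AC_TO_MT_HA * spec$bs_model$k
  ## no deficit once at/above target
  out[soil$ph >= spec$target_ph] <- 0
  pmax(out, 0)
}
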