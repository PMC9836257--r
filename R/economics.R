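## Present-value accounting for lime versus fertilizer and the
## "x cost of lime" ratio.

#' Economic parameters
#'
#' Prices and rates driving all present-value arithmetic. Defaults reflect
#' Ethiopian conditions in December 2016: blended Urea/NPS fertilizer at
#' 11.5 ETB/kg, an 8% annual discount rate against 13.4% inflation, a
#' five-year horizon matching the assumed lime re-application interval, an
#' exchange rate of 22.07 ETB per USD, and an average one-year agricultural
#' household income of 8,176 ETB.
#'
#' @param horizon_years Planning horizon in years (>= 1).
#' @param discount_rate Annual discount rate (fraction).
#' @param inflation_rate Annual inflation rate (fraction).
#' @param fert_price Fertilizer price, ETB/kg.
#' @param exchange_rate ETB per USD.
#' @param household_income Annual agricultural household income, ETB.
#' @param lime_interval_years Years between lime applications.
#' @return An object of class `econ_params`.
#' @export
econ_params <- function(horizon_years = 5, discount_rate = 0.08,
                        inflation_rate = 0.134, fert_price = 11.5,
                        exchange_rate = 22.07, household_income = 8176,
                        lime_interval_years = 5) {
  check_number(horizon_years, "horizon_years", lower = 1)
  check_number(discount_rate, "discount_rate", lower = 0)
  check_number(inflation_rate, "inflation_rate", lower = 0)
  check_number(fert_price, "fert_price", lower = 0, open_lower = TRUE)
  check_number(exchange_rate, "exchange_rate", lower = 0, open_lower = TRUE)
  check_number(household_income, "household_income", lower = 0,
               open_lower = TRUE)
  check_number(lime_interval_years, "lime_interval_years", lower = 1)
  structure(list(horizon_years = as.integer(horizon_years),
                 discount_rate = discount_rate,
                 inflation_rate = inflation_rate,
                 fert_price = fert_price,
                 exchange_rate = exchange_rate,
                 household_income = household_income,
                 lime_interval_years = as.integer(lime_interval_years)),
            class = "econ_params")
}

#' Annuity factor for a recurring real cost
#'
#' Sum of the inflation-grown, discounted payment weights over the horizon:
#' \eqn{\sum_t ((1+i)/(1+r))^t} with `t = 0, ..., H-1` under the
#' `"start"`-of-year convention (first payment immediate) or
#' `t = 1, ..., H` under `"end"`. With the default rates (i = 13.4%,
#' r = 8%, H = 5) the start-of-year factor is 5.5256.
#'
#' @param p An [econ_params()].
#' @param timing `"start"` (default) or `"end"` of year payments.
#' @return The dimensionless annuity factor.
#' @export
annuity_factor <- function(p = econ_params(), timing = c("start", "end")) {
  timing <- match.arg(timing)
  g <- (1 + p$inflation_rate) / (1 + p$discount_rate)
  t0 <- if (timing == "start") 0 else 1
  sum(g^(seq_len(p$horizon_years) - 1 + t0))
}

#' Present value of a recurring annual cost
#'
#' Fertilizer must be re-purchased every season, so its cost is an annual
#' stream: each year's outlay grows with inflation and is discounted back to
#' the present. Returned as a negative number (a cost).
#'
#' @param annual_cost Annual cost in ETB (>= 0), today's prices.
#' @param p An [econ_params()].
#' @param timing Payment timing convention, see [annuity_factor()].
#' @return Present value in ETB (<= 0).
#' @examples
#' pv_recurring(1000)  # about -5525.6 ETB over five years
#' @export
pv_recurring <- function(annual_cost, p = econ_params(),
                         timing = c("start", "end")) {
  check_number(annual_cost, "annual_cost", lower = 0,
               len = length(annual_cost))
  -annual_cost * annuity_factor(p, timing)
}

#' Present value of a lime application
#'
#' Lime is applied once per horizon, paid up front at t = 0, so its present
#' value is simply minus the delivered cost of the required tonnage.
#'
#' @param lime_mt_ha Lime requirement, mt/ha (>= 0).
#' @param delivered_price Delivered lime price, ETB/mt (>= 0).
#' @param p An [econ_params()] (unused by the default t = 0 convention;
#'   kept so alternative timings can be slotted in).
#' @return Present value in ETB (<= 0).
#' @export
pv_lime <- function(lime_mt_ha, delivered_price, p = econ_params()) {
  check_number(lime_mt_ha, "lime_mt_ha", lower = 0, len = length(lime_mt_ha))
  check_number(delivered_price, "delivered_price", lower = 0,
               len = length(delivered_price))
  -lime_mt_ha * delivered_price
}

#' Convert ETB to USD
#'
#' @param etb Amount in Ethiopian Birr.
#' @param p An [econ_params()] supplying the exchange rate.
#' @return Amount in USD.
#' @export
to_usd <- function(etb, p = econ_params()) {
  etb / p$exchange_rate
}

#' Compare the cost of lime and fertilizer for an equal yield gain
#'
#' The two interventions are normalised on yield: the fertilizer quantity is
#' the annual application achieving the same yield gain as the lime
#' treatment. Fertilizer is a recurring annual cost; lime a one-off. The "x
#' cost of lime" is the magnitude of the fertilizer present value divided by
#' the magnitude of the lime present value: values above 1 mean lime is
#' cheaper.
#'
#' @param yield_gain Yield gain of the lime treatment, mt/ha.
#' @param fert_equiv Equivalent fertilizer quantity, kg/ha/yr; either a
#'   number or the result of [equivalent_fertilizer()] (which may be flagged
#'   unattainable, in which case the quantity at the search cap is used and
#'   the ratio reported as a lower bound).
#' @param lime_mt_ha Lime requirement, mt/ha.
#' @param delivered_price Delivered lime price, ETB/mt.
#' @param p An [econ_params()].
#' @param timing Fertilizer payment timing, see [annuity_factor()].
#' @return An object of class `pv_comparison`: a list with `pv_lime`,
#'   `pv_fert` (both ETB, negative), `x_cost_of_lime`, `savings_etb`
#'   (|pv_fert| - |pv_lime|), `savings_pct_income`, `yield_gain`,
#'   `fert_equiv`, and logical `attainable`.
#' @export
compare_costs <- function(yield_gain, fert_equiv, lime_mt_ha,
                          delivered_price, p = econ_params(),
                          timing = c("start", "end")) {
  attainable <- TRUE
  fe_kg <- fert_equiv
  if (inherits(fert_equiv, "fert_equiv")) {
    attainable <- fert_equiv$attainable
    fe_kg <- if (attainable) fert_equiv$kg_ha else fert_equiv$cap
  }
  check_number(fe_kg, "fert_equiv", lower = 0)
  pvf <- pv_recurring(fe_kg * p$fert_price, p, timing)
  pvl <- pv_lime(lime_mt_ha, delivered_price, p)
  if (pvl == 0 && pvf != 0) {
    stop("lime present value is zero with nonzero fertilizer cost: ",
         "x cost of lime undefined", call. = FALSE)
  }
  ratio <- if (pvl == 0) 1 else abs(pvf) / abs(pvl)
  savings <- abs(pvf) - abs(pvl)
  structure(list(pv_lime = pvl, pv_fert = pvf,
                 x_cost_of_lime = ratio,
                 ratio_is_lower_bound = !attainable,
                 savings_etb = savings,
                 savings_pct_income = 100 * savings / p$household_income,
                 yield_gain = yield_gain, fert_equiv = fe_kg,
                 attainable = attainable),
            class = "pv_comparison")
}

#' @export
print.pv_comparison <- function(x, ...) {
  cat("Lime vs fertilizer cost comparison (equal yield gain)\n")
  cat(sprintf("  yield gain:        %.2f mt/ha\n", x$yield_gain))
  cat(sprintf("  fertilizer equiv.: %.1f kg/ha/yr%s\n", x$fert_equiv,
              if (x$attainable) "" else " (cap; gain unattainable)"))
  cat(sprintf("  PV lime:           %s ETB\n", format(round(x$pv_lime, 1),
                                                      big.mark = ",")))
  cat(sprintf("  PV fertilizer:     %s ETB\n", format(round(x$pv_fert, 1),
                                                      big.mark = ",")))
  cat(sprintf("  x cost of lime:    %s%.1f\n",
              if (x$ratio_is_lower_bound) "> " else "", x$x_cost_of_lime))
  cat(sprintf("  savings:           %s ETB (%.0f%% of household income)\n",
              format(round(x$savings_etb, 1), big.mark = ","),
              x$savings_pct_income))
  invisible(x)
}

#' Aggregate per-location comparison results
#'
#' Medians (or another statistic) of the numeric comparison columns within
#' cells of grouping variables, dropping (with a message) cells that contain
#' no observations -- e.g. a region whose sample holds no moderately acidic
#' sub-kebeles.
#'
#' @param results data.frame of per-location results.
#' @param by Character vector of grouping column names (default crop,
#'   region, acidity class).
#' @param stat Summary function applied within each cell (default
#'   [median()]).
#' @return data.frame keyed by the grouping columns, one row per non-empty
#'   cell.
#' @export
aggregate_results <- function(results,
                              by = c("crop", "region", "acidity_class"),
                              stat = median) {
  check_columns(results, by, "results")
  if (!nrow(results)) stop("'results' is empty", call. = FALSE)
  num_cols <- names(results)[vapply(results, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, by)
  key <- interaction(results[by], drop = FALSE, sep = " / ")
  present <- levels(droplevels(key))
  absent <- setdiff(levels(key), present)
  if (length(absent)) {
    message(sprintf("dropping %d empty cell(s): %s", length(absent),
                    paste(absent, collapse = "; ")))
  }
  agg <- aggregate(results[num_cols], by = results[by],
                   FUN = function(v) stat(v, na.rm = TRUE))
  agg[do.call(order, agg[by]), , drop = FALSE]
}
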