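#' Published delivered lime cost predictions for Ethiopian towns
#'
#' Reference table of seven Ethiopian towns with their nearest lime
#' crusher, the estimated travel time from it (hours, printed to 0.1 hr)
#' and the predicted distributor cost of delivered lime (ETB/mt). Used to
#' validate the delivered-price model: with the default cost assumptions
#' (750 ETB/mt at the crusher gate, 100 ETB/mt loading, 60 ETB/mt/hr
#' transport), `750 + 100 + 60 * travel_hr` reproduces every printed cost
#' to within the rounding of the printed travel times (about 6 ETB).
#'
#' @return data.frame with columns `city`, `nearest_crusher`, `travel_hr`,
#'   `cost_etb_mt`.
#' @export
town_lime_costs <- function() {
  data.frame(
    city = c("Adigrat", "Axum", "Gonder", "Bahir Dar", "Dessie",
             "Debre Markos", "Debre Birhan"),
    nearest_crusher = c("Dejen", "Dejen", "Dejen", "Dejen", "Butajira",
                        "Dejen", "Butajira"),
    travel_hr = c(16.2, 14.0, 8.9, 6.0, 8.6, 1.7, 4.5),
    cost_etb_mt = c(1821, 1689, 1381, 1213, 1367, 954, 1121),
    stringsAsFactors = FALSE
  )
}
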