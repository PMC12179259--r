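# Criterion energy expenditure from breath-by-breath gas exchange.

#' Energy expenditure from gas exchange (Weir equation)
#'
#' `EE (kcal/min) = 3.941 * VO2 (L/min) + 1.106 * VCO2 (L/min)`, the
#' abbreviated Weir formula for indirect calorimetry. Vectorised and
#' linear in both inputs.
#'
#' @param vo2 Oxygen uptake, L/min, non-negative.
#' @param vco2 Carbon-dioxide production, L/min, non-negative.
#' @return Energy expenditure in kcal/min.
#' @export
#' @examples
#' weir_ee(0.3, 0.25)
weir_ee <- function(vo2, vco2) {
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE))
    wm_contract_error("vo2 and vco2 must be non-negative")
  3.941 * vo2 + 1.106 * vco2
}

#' Convert oxygen uptake to METs
#'
#' One MET is an oxygen uptake of 3.5 ml per kg body mass per minute
#' (quiet sitting), so `MET = (vo2 * 1000 / weight) / 3.5` with `vo2` in
#' L/min and weight in kg. An alternative kcal-referenced convention
#' divides Weir-equation energy expenditure by `0.0175 kcal/kg/min`
#' (the caloric equivalent of 1 MET); select it with
#' `convention = "kcal"` and supply `vco2`.
#'
#' @param vo2 Oxygen uptake, L/min.
#' @param weight Body mass, kg (> 0).
#' @param convention `"vo2"` (default) or `"kcal"`.
#' @param vco2 Carbon-dioxide production, L/min; required for the kcal
#'   convention.
#' @return MET values.
#' @export
ee_to_met <- function(vo2, weight, convention = c("vo2", "kcal"), vco2 = NULL) {
  convention <- match.arg(convention)
  if (any(weight <= 0)) wm_contract_error("weight must be > 0")
  if (convention == "vo2") {
    (vo2 * 1000 / weight) / 3.5
  } else {
    if (is.null(vco2))
      wm_contract_error("vco2 is required for the kcal convention")
    weir_ee(vo2, vco2) / (weight * 0.0175)
  }
}

#' Per-sample MET series from a calorimetry trace
#'
#' Breath-by-breath data are event-sampled, so values are resampled onto
#' the IMU clock with a previous-value hold (times before the first
#' breath take the first breath's value). Energy expenditure (kcal/min,
#' Weir equation) is carried alongside the MET value.
#'
#' @param trace A [calorimetry_trace()].
#' @param demo One-row [demographics()] table (the participant's weight
#'   sets the MET denominator).
#' @param clock_t Optional target timestamps (the IMU clock); when `NULL`
#'   the per-breath series is returned.
#' @param convention MET convention, see [ee_to_met()].
#' @return Data frame of class `met_series` with columns `t, met, ee`.
#' @export
calorimetry_to_met_series <- function(trace, demo, clock_t = NULL,
                                      convention = c("vo2", "kcal")) {
  convention <- match.arg(convention)
  weight <- demo$weight_kg[[1L]]
  if (nrow(trace) == 0L) {
    return(structure(data.frame(t = numeric(0), met = numeric(0),
                                ee = numeric(0)),
                     class = c("met_series", "data.frame")))
  }
  met <- ee_to_met(trace$vo2, weight, convention = convention,
                   vco2 = trace$vco2)
  ee <- weir_ee(trace$vo2, trace$vco2)
  if (!is.null(clock_t)) {
    if (nrow(trace) == 1L) {
      met <- rep(met, length(clock_t))
      ee <- rep(ee, length(clock_t))
    } else {
      met <- approx(trace$t, met, xout = clock_t, method = "constant",
                    f = 0, rule = 2)$y
      ee <- approx(trace$t, ee, xout = clock_t, method = "constant",
                   f = 0, rule = 2)$y
    }
    t_out <- clock_t
  } else {
    t_out <- trace$t
  }
  structure(data.frame(t = t_out, met = met, ee = ee),
            class = c("met_series", "data.frame"))
}
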