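#' Energy-based aggregation of A-weighted sound levels
#'
#' Combines sound levels measured in dB(A) on the energy (linear power)
#' scale, the convention implied by a 3 dB exchange rate: each level is
#' converted to relative power `10^(L/10)`, power is averaged with the
#' supplied duration weights, and the result is converted back to decibels,
#'
#' \deqn{L_{eq} = 10 \log_{10}\left(\frac{\sum_i w_i 10^{L_i/10}}{\sum_i w_i}\right).}
#'
#' @param levels Numeric vector of sound levels in dB(A).
#' @param weights Positive durations (any common unit); defaults to equal
#'   weighting.
#' @return A single equivalent continuous level in dB(A).
#' @examples
#' laeq_aggregate(c(60, 70))        # 67.4, not 65
#' laeq_aggregate(c(60, 70), c(2, 1))
#' @export
laeq_aggregate <- function(levels, weights = NULL) {
  if (length(levels) == 0L) {
    abort("`levels` must be non-empty.")
  }
  if (is.null(weights)) weights <- rep(1, length(levels))
  if (length(weights) != length(levels) || any(weights <= 0)) {
    abort("`weights` must be positive and match `levels` in length.")
  }
  10 * log10(sum(weights * 10^(levels / 10)) / sum(weights))
}

#' Mean and standard deviation of decibel values on the energy scale
#'
#' Arithmetic moments of decibel values understate acoustic energy; both
#' moments are therefore computed on the linear power scale and re-expressed
#' in dB(A).  The mean equals [laeq_aggregate()] with equal weights; the SD
#' is the dB equivalent of the power-scale dispersion,
#' `10*log10(1 + sd(p)/mean(p))` with `p = 10^(L/10)`, which is zero for a
#' constant series and grows with relative energy spread.
#'
#' @param levels Numeric vector of sound levels in dB(A).
#' @return A named numeric vector with elements `mean` and `sd`, both dB(A).
#' @examples
#' db_mean_sd(c(70, 80))
#' @export
db_mean_sd <- function(levels) {
  if (length(levels) == 0L) {
    abort("`levels` must be non-empty.")
  }
  p <- 10^(levels / 10)
  m <- mean(p)
  s <- if (length(p) > 1L) sd(p) else 0
  c(mean = 10 * log10(m), sd = 10 * log10(1 + s / m))
}

#' Inhaled pollutant dose over one minute
#'
#' Mass of pollutant inhaled in one minute: the minute ventilation VE
#' (L/min) converted to m^3 (factor 0.001) times the ambient concentration,
#' `I = (VE * 0.001) * C`.
#'
#' @param ve_lmin Minute ventilation in L/min (>= 0).
#' @param no2_ugm3 Ambient concentration in µg/m³ (>= 0).
#' @return Inhaled dose in µg per minute.
#' @examples
#' inhaled_dose(35, 200)  # 7 µg/min for a cyclist at the WHO 1-h guideline
#' inhaled_dose(15, 200)  # 3 µg/min at a pedestrian's ventilation rate
#' @export
inhaled_dose <- function(ve_lmin, no2_ugm3) {
  if (any(ve_lmin < 0) || any(no2_ugm3 < 0)) {
    abort("`ve_lmin` and `no2_ugm3` must be non-negative.")
  }
  (ve_lmin * 0.001) * no2_ugm3
}

#' Convert NO2 mixing ratio to mass concentration
#'
#' Electrochemical NO2 sensors report ppm; exposure guidelines use µg/m³.
#' At 25 °C and 1013 hPa, 1 ppm NO2 corresponds to 1880 µg/m³.
#'
#' @param ppm Mixing ratio in parts per million.
#' @return Concentration in µg/m³.
#' @export
no2_ppm_to_ugm3 <- function(ppm) {
  ppm * 1880
}
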