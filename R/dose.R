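#' Criteria for noise dose and pollutant intake assessment
#'
#' Bundles the guideline constants: criterion sound level `l_c` (dB(A))
#' sustained for `t_c` hours defines the 100% noise dose, with exchange
#' rate parameter `q` (10 for a 3 dB exchange rate, so +3.01 dB doubles
#' dose accumulation); the NO2 short-term guideline concentration and
#' duration define the intake thresholds via the pedestrian and cyclist
#' ventilation rates (200 µg/m³ × 0.015 m³/min × 60 min = 180 µg;
#' 200 × 0.035 × 60 = 420 µg).
#'
#' @param l_c Criterion sound level in dB(A); default 59.3, the daily mean
#'   level associated with a 5% increase in ischaemic heart disease
#'   incidence.
#' @param t_c Criterion duration in hours (default 24).
#' @param q Exchange-rate parameter in dB (default 10, i.e. 3 dB doubling).
#' @param no2_guideline Short-term NO2 guideline in µg/m³ (default 200).
#' @param guideline_duration Guideline averaging time in minutes (60).
#' @param ve_pedestrian,ve_cyclist Ventilation rates in L/min (15 and 35).
#' @return A `dose_criteria` object.
#' @export
dose_criteria <- function(l_c = 59.3, t_c = 24, q = 10,
                          no2_guideline = 200, guideline_duration = 60,
                          ve_pedestrian = 15, ve_cyclist = 35) {
  vals <- c(l_c = l_c, t_c = t_c, q = q, no2_guideline = no2_guideline,
            guideline_duration = guideline_duration,
            ve_pedestrian = ve_pedestrian, ve_cyclist = ve_cyclist)
  if (any(vals <= 0)) abort("All dose criteria must be positive.")
  structure(as.list(vals), class = "dose_criteria")
}

#' Total noise dose as a percentage of the criterion exposure
#'
#' `D = (100 / T_c) * sum_i T_i * 10^((L_i - L_c) / q)`: each exposure
#' interval contributes its duration weighted by the energy ratio to the
#' criterion level.  The criterion level sustained for the criterion
#' duration gives exactly 100%.
#'
#' @param level_db Sound levels `L_i` in dB(A), one per interval.
#' @param hours Interval durations `T_i` in hours.
#' @param criteria A [dose_criteria()].
#' @return Total dose in percent.
#' @examples
#' noise_dose(56.3, 24)       # ~50%
#' noise_dose(75, 40 / 60)    # ~103%
#' @export
noise_dose <- function(level_db, hours, criteria = dose_criteria()) {
  if (length(level_db) == 0L) abort("Empty exposure list.")
  if (length(hours) == 1L) hours <- rep(hours, length(level_db))
  if (length(hours) != length(level_db) || any(hours <= 0)) {
    abort("`hours` must be positive and match `level_db` in length.")
  }
  (100 / criteria$t_c) *
    sum(hours * 10^((level_db - criteria$l_c) / criteria$q))
}

#' Intake threshold implied by a concentration guideline
#'
#' Mass inhaled while breathing at `ve` L/min for `duration` minutes at
#' the guideline concentration: `guideline * (ve * 0.001) * duration`.
#'
#' @param guideline Concentration in µg/m³ (>= 0).
#' @param ve Ventilation rate in L/min (> 0).
#' @param duration Duration in minutes (> 0).
#' @return Threshold in µg.
#' @examples
#' intake_threshold(200, 15, 60)  # 180 µg, pedestrian
#' intake_threshold(200, 35, 60)  # 420 µg, cyclist
#' @export
intake_threshold <- function(guideline, ve, duration) {
  if (guideline < 0 || ve <= 0 || duration <= 0) {
    abort("`guideline` must be >= 0; `ve` and `duration` must be positive.")
  }
  guideline * (ve * 0.001) * duration
}

#' Cumulative inhaled dose along a concentration series
#'
#' Running sum of per-minute inhaled dose `(ve * 0.001) * conc`.
#'
#' @param conc_ugm3 Per-minute concentrations in µg/m³ (>= 0).
#' @param ve Ventilation rate in L/min.
#' @return Cumulative dose in µg at each minute index.
#' @export
cumulative_intake <- function(conc_ugm3, ve) {
  if (any(conc_ugm3 < 0)) abort("Concentrations must be non-negative.")
  cumsum((ve * 0.001) * conc_ugm3)
}

#' Minutes of constant exposure needed to reach a noise-dose target
#'
#' Closed-form inversion of [noise_dose()]:
#' `minutes = (target / 100) * T_c * 60 * 10^((L_c - level) / q)`.
#'
#' @param level_db Constant sound level in dB(A).
#' @param criteria A [dose_criteria()].
#' @param target_pct Dose target in percent (default 100).
#' @return Minutes to reach the target.
#' @examples
#' minutes_to_noise_dose(75)    # under 40 min
#' minutes_to_noise_dose(59.3)  # 1440 min: criterion level, criterion day
#' @export
minutes_to_noise_dose <- function(level_db, criteria = dose_criteria(),
                                  target_pct = 100) {
  (target_pct / 100) * criteria$t_c * 60 *
    10^((criteria$l_c - level_db) / criteria$q)
}

#' Minutes of constant exposure needed to reach an intake threshold
#'
#' @param conc_ugm3 Constant concentration in µg/m³.
#' @param ve Ventilation rate in L/min.
#' @param threshold Intake threshold in µg.
#' @return Minutes to reach the threshold; infinite (with a warning) at
#'   zero concentration.
#' @examples
#' minutes_to_intake(200, 35, 420)  # 60 min by construction
#' @export
minutes_to_intake <- function(conc_ugm3, ve, threshold) {
  if (conc_ugm3 < 0) abort("`conc_ugm3` must be non-negative.")
  if (conc_ugm3 == 0) {
    warn("Zero concentration: threshold never reached.")
    return(Inf)
  }
  threshold / ((ve * 0.001) * conc_ugm3)
}

#' Dose and intake accumulation curves by location and road type
#'
#' The scenario-prediction analysis: for each location and road class,
#' predict the constant per-minute noise level and NO2 concentration from
#' the two fitted exposure models (random effects excluded, other
#' covariates at their fitted means, clock time fixed, default 11:00),
#' then accumulate the noise dose and the cyclist's NO2 intake minute by
#' minute and record when the 100% noise dose and the pedestrian/cyclist
#' intake thresholds are crossed (closed form, to 0.1 min).
#'
#' @param model_noise,model_no2 Converged `gammar_fit` objects for the
#'   noise and NO2 responses.
#' @param locations Tibble with `x`, `y`, `label`.
#' @param road_types Road classes to profile (default all six).
#' @param duration_min Curve length in minutes.
#' @param criteria A [dose_criteria()].
#' @param clock_min Prediction clock time in minutes since 08:00
#'   (default 180 = 11:00).
#' @return A `dose_curves` tibble: one row per location × road type ×
#'   response × minute, with `value`, `threshold` and `crossing_min`
#'   columns.  The per-curve crossing summary is available via
#'   [dose_crossings()].
#' @export
hazard_curves <- function(model_noise, model_no2, locations,
                          road_types = NULL,
                          duration_min = 90,
                          criteria = dose_criteria(),
                          clock_min = 180) {
  if (!model_noise$converged || !model_no2$converged) {
    abort("Both models must have converged.")
  }
  all_types <- c("trunk_motorway", "primary", "secondary", "tertiary",
                 "residential", "unclassified_service")
  road_types <- road_types %||% all_types
  if (duration_min < 1) {
    return(structure(tibble(), class = c("dose_curves", "tbl_df", "tbl",
                                         "data.frame")))
  }
  grid <- tidyr::expand_grid(
    location_label = locations$label,
    road_type = road_types
  ) %>%
    left_join(locations %>% rename(location_label = "label"),
              by = "location_label")

  newdata_for <- function(fit, g) {
    nd <- tibble::as_tibble(as.list(fit$covariate_means))
    nd <- nd[rep(1, nrow(g)), ]
    for (rt in setdiff(all_types, "residential")) {
      cn <- paste0("share_", rt)
      if (cn %in% names(nd)) nd[[cn]] <- as.numeric(g$road_type == rt)
    }
    nd$x <- g$x; nd$y <- g$y; nd$clock_min <- clock_min
    nd
  }

  pn <- predict_exposure(model_noise, newdata_for(model_noise, grid))
  pc <- predict_exposure(model_no2, newdata_for(model_no2, grid))
  grid$level_db <- pn$.pred
  grid$no2 <- pmax(pc$.pred, 0)

  minutes <- seq_len(duration_min)
  thr_ped <- intake_threshold(criteria$no2_guideline, criteria$ve_pedestrian,
                              criteria$guideline_duration)
  thr_cyc <- intake_threshold(criteria$no2_guideline, criteria$ve_cyclist,
                              criteria$guideline_duration)

  curves <- purrr::pmap_dfr(grid, function(location_label, road_type, x, y,
                                           level_db, no2, ...) {
    dose_t <- sapply(minutes, function(m)
      noise_dose(level_db, m / 60, criteria))
    intake_t <- cumulative_intake(rep(no2, duration_min),
                                  criteria$ve_cyclist)
    cross_noise <- minutes_to_noise_dose(level_db, criteria)
    cross_cyc <- if (no2 > 0) thr_cyc / ((criteria$ve_cyclist * 0.001) * no2)
                 else Inf
    cross_ped <- if (no2 > 0) thr_ped / ((criteria$ve_cyclist * 0.001) * no2)
                 else Inf
    bind_rows(
      tibble(location_label, road_type, response = "noise_dose_pct",
             minute = minutes, value = dose_t, threshold = 100,
             crossing_min = round(cross_noise, 1)),
      tibble(location_label, road_type, response = "no2_intake_ug",
             minute = minutes, value = intake_t, threshold = thr_cyc,
             crossing_min = round(cross_cyc, 1)),
      tibble(location_label, road_type, response = "no2_intake_ug_pedestrian_threshold",
             minute = minutes, value = intake_t, threshold = thr_ped,
             crossing_min = round(cross_ped, 1))
    )
  })
  class(curves) <- c("dose_curves", class(curves))
  attr(curves, "criteria") <- criteria
  curves
}

#' Threshold-crossing summary of hazard curves
#'
#' @param curves A `dose_curves` tibble from [hazard_curves()].
#' @return One row per location × road type × response with the threshold
#'   and the crossing time in minutes.
#' @export
dose_crossings <- function(curves) {
  curves %>%
    group_by(.data$location_label, .data$road_type, .data$response) %>%
    summarise(threshold = first(.data$threshold),
              crossing_min = first(.data$crossing_min),
              .groups = "drop")
}

#' Pick hazard-assessment locations from a scenario's spatial field
#'
#' Defines "low", "moderate" and "high" exposure locations as the grid
#' points whose generating NO2 spatial-field values sit at the 25th, 50th
#' and 75th percentiles, mirroring the choice of three contrasting city
#' areas.
#'
#' @param scenario A `scenario_params` object.
#' @param response Field to rank on (default `"no2"`).
#' @return Tibble with `label`, `x`, `y`, `field_value`.
#' @export
pick_hazard_locations <- function(scenario, response = "no2") {
  gx <- seq(scenario$bbox[1], scenario$bbox[2], length.out = 41)
  gy <- seq(scenario$bbox[3], scenario$bbox[4], length.out = 41)
  grid <- tidyr::expand_grid(x = gx, y = gy) %>%
    mutate(field_value = scenario_spatial(scenario, response, .data$x, .data$y))
  targets <- quantile(grid$field_value, c(0.25, 0.50, 0.75))
  labs <- c("low", "moderate", "high")
  purrr::map_dfr(seq_along(targets), function(i) {
    j <- which.min(abs(grid$field_value - targets[i]))
    tibble(label = labs[i], x = grid$x[j], y = grid$y[j],
           field_value = grid$field_value[j])
  })
}

#' @export
print.dose_criteria <- function(x, ...) {
  cat(sprintf(
    "<dose_criteria> L_c=%.1f dB(A) over %g h (q=%g); NO2 %g ug/m3 x %g min; VE %g/%g L/min\n",
    x$l_c, x$t_c, x$q, x$no2_guideline, x$guideline_duration,
    x$ve_pedestrian, x$ve_cyclist))
  invisible(x)
}
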