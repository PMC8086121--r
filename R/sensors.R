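#' Per-minute covariates of a GPS trace
#'
#' Aggregates a 1 Hz trace to the one-minute analysis grid: mean speed and
#' grade, time shares on each of the six road classes (fix counts, so a
#' time basis), number of intersection crossings (distinct traversals of
#' nodes with degree >= 3), segment midpoint, and clock time at the minute
#' centre.  Both the simulator and the segmentation stage use this one
#' function, so the generating mean structure and the fitted design agree
#' by construction.
#'
#' @param trace A `gps_trace` (or merged track) tibble.
#' @return A tibble with one row per minute present in the trace.
#' @export
minute_covariates <- function(trace) {
  net <- attr(trace, "network")
  deg <- if (!is.null(net)) net$nodes$degree else integer(0)
  n_crossings <- function(crossed) {
    if (length(deg) == 0L) return(0L)
    sum(!is.na(crossed) & deg[pmax(crossed, 1L)] >= 3, na.rm = TRUE)
  }
  trace %>%
    mutate(timestamp_minute = (.data$timestamp - 1) %/% 60) %>%
    group_by(.data$timestamp_minute) %>%
    summarise(
      n_fix = dplyr::n(),
      speed_kmh = mean(.data$speed_kmh),
      slope_pct = mean(.data$slope_pct),
      intersections = n_crossings(.data$crossed_node),
      x = mean(.data$x),
      y = mean(.data$y),
      share_trunk_motorway = mean(.data$road_type == "trunk_motorway"),
      share_primary = mean(.data$road_type == "primary"),
      share_secondary = mean(.data$road_type == "secondary"),
      share_tertiary = mean(.data$road_type == "tertiary"),
      share_residential = mean(.data$road_type == "residential"),
      share_unclassified_service = mean(.data$road_type == "unclassified_service"),
      .groups = "drop"
    ) %>%
    mutate(clock_min = .data$timestamp_minute + 0.5)
}

#' Simulate per-minute sensor records along a trip
#'
#' Generates one record per elapsed minute with the exact statistical
#' structure the exposure models assume.  For noise and NO2 the per-minute
#' mean is intercept + fixed-effect linear predictor (road-class time
#' shares, speed, grade, intersections, humidity, wind) + spatial field at
#' the minute midpoint + diurnal profile + day and participant random
#' intercepts; the error added to the mean is an MA(3) process driven by
#' Student-t innovations, restarted at the trip boundary.  Minute
#' ventilation follows the scenario's linear speed/grade model with AR(1)
#' noise.  The inhaled NO2 dose is not simulated separately: it is derived
#' downstream from the recorded VE and NO2 by the dose equation, exactly as
#' in a real campaign.
#'
#' @param trace A `gps_trace` from [simulate_trip()].
#' @param scenario A `scenario_params` object.
#' @param participant,day Level labels; must exist in the scenario's
#'   random-intercept tables.
#' @param seed Integer seed.
#' @return A tibble with one row per minute: `timestamp_minute`,
#'   `laeq_1min` (dB(A)), `no2_ugm3`, `humidity_pct`, `wind_kmh`,
#'   `ve_lmin`.  The generating mean structure is attached as the `truth`
#'   attribute (columns `mu_noise`, `mu_no2`) for simulation diagnostics.
#' @examples
#' net <- make_road_network(n_nodes = 25, seed = 1)
#' tr <- simulate_trip(net, duration_min = 5, seed = 1)
#' rec <- simulate_sensor_records(tr, default_scenario(), "I", "Monday", seed = 2)
#' @export
simulate_sensor_records <- function(trace, scenario, participant = "I",
                                    day = "Monday", seed = 1) {
  if (nrow(trace) == 0L) abort("`trace` must be non-empty.")
  if (!participant %in% scenario$random_participant$participant) {
    abort(paste0("Unknown participant '", participant, "'."))
  }
  if (!day %in% scenario$random_day$day) {
    abort(paste0("Unknown day '", day, "'."))
  }
  withr_seed(seed)

  cov <- minute_covariates(trace)
  n <- nrow(cov)
  w <- scenario$weather

  # humidity: day-level baseline plus a slow within-trip AR(1)
  base <- w$humidity_mean + rnorm(1, 0, w$humidity_day_sd)
  hum <- numeric(n)
  h <- 0
  innov <- rnorm(n, 0, w$humidity_minute_sd)
  for (t in seq_len(n)) {
    h <- w$humidity_ar1 * h + innov[t]
    hum[t] <- base + h
  }
  hum <- pmin(pmax(hum, w$humidity_range[1]), w$humidity_range[2])

  # wind: piecewise constant per half-hour block, point mass at zero
  block <- cov$clock_min %/% w$wind_block_min
  ub <- unique(block)
  shape <- (w$wind_mean / w$wind_sd)^2
  bw <- ifelse(runif(length(ub)) < w$wind_p_zero, 0,
               rgamma(length(ub), shape = shape,
                      scale = w$wind_mean / shape))
  wind <- bw[match(block, ub)]

  # ventilation: deterministic speed/grade model plus AR(1) noise
  ve_det <- scenario_ve(scenario, cov$speed_kmh, cov$slope_pct)
  vn <- numeric(n)
  vz <- 0
  innov_v <- rnorm(n, 0, scenario$ve_model$sd)
  for (t in seq_len(n)) {
    vz <- scenario$ve_model$ar1 * vz + innov_v[t]
    vn[t] <- vz
  }
  ve <- pmin(pmax(ve_det + vn, scenario$ve_model$lo), scenario$ve_model$hi)

  covariates <- cov %>%
    mutate(humidity_pct = hum, wind_kmh = wind)

  mu <- list()
  err <- list()
  for (r in c("noise", "no2")) {
    b <- setNames(scenario$beta_fixed[[r]], scenario$beta_fixed$term)
    eta <- scenario$intercepts[[r]]
    for (trm in names(b)) eta <- eta + b[[trm]] * covariates[[trm]]
    eta <- eta +
      scenario_spatial(scenario, r, cov$x, cov$y) +
      scenario_temporal(scenario, r, cov$clock_min) +
      scenario$random_day[[r]][scenario$random_day$day == day] +
      scenario$random_participant[[r]][
        scenario$random_participant$participant == participant]
    mu[[r]] <- eta
    err[[r]] <- ma_process(n, scenario$ma_coefs[[r]],
                           scenario$resid_scale[[r]], scenario$student_df)
  }

  rec <- tibble(
    timestamp_minute = cov$timestamp_minute,
    laeq_1min = mu$noise + err$noise,
    no2_ugm3 = pmax(mu$no2 + err$no2, 0),
    humidity_pct = hum,
    wind_kmh = wind,
    ve_lmin = ve
  )
  attr(rec, "truth") <- tibble(
    timestamp_minute = cov$timestamp_minute,
    mu_noise = mu$noise, mu_no2 = mu$no2
  )
  rec
}

# MA(q) error series with Student-t innovations; pre-sample innovations are
# zero, so the process is exact from lag q+1 onward.
ma_process <- function(n, theta, scale, df) {
  e <- rt(n, df) * scale
  u <- e
  for (k in seq_along(theta)) {
    if (k < n) {
      u[(k + 1):n] <- u[(k + 1):n] + theta[k] * e[1:(n - k)]
    }
  }
  u
}

#' Simulate a complete multi-trip exposure study
#'
#' Convenience wrapper that generates a road network (unless supplied),
#' simulates `n_trips` rides with participants and days assigned in
#' rotation, generates sensor records for each, merges and segments them,
#' and returns the pooled one-minute segments ready for modelling.
#'
#' @param scenario A `scenario_params` object.
#' @param n_trips Number of trips.
#' @param minutes_per_trip Trip duration in minutes.
#' @param seed Integer seed driving every random choice.
#' @param network Optional [make_road_network()] object.
#' @param mean_speed_kmh Mean riding speed (default 17 km/h).
#' @return A tibble of one-minute segments (see [segment_one_minute()])
#'   with `trip_id`, `participant` and `day` columns.
#' @examples
#' \donttest{
#' segs <- simulate_study(default_scenario(), n_trips = 4,
#'                        minutes_per_trip = 20, seed = 1)
#' }
#' @export
simulate_study <- function(scenario, n_trips = 50, minutes_per_trip = 60,
                           seed = 1, network = NULL,
                           mean_speed_kmh = 17) {
  if (n_trips < 1) abort("`n_trips` must be at least 1.")
  withr_seed(seed)
  trip_seeds <- sample.int(2^30, n_trips * 2)
  if (is.null(network)) {
    network <- make_road_network(seed = sample.int(2^30, 1))
  }
  participants <- scenario$random_participant$participant
  days <- scenario$random_day$day
  window <- scenario$clock_window
  starts <- runif(n_trips, window[1], max(window[1],
                                          window[2] - minutes_per_trip))
  purrr::map_dfr(seq_len(n_trips), function(i) {
    p <- participants[(i - 1) %% length(participants) + 1]
    d <- days[((i - 1) %/% length(participants)) %% length(days) + 1]
    tr <- simulate_trip(network, minutes_per_trip,
                        mean_speed_kmh = mean_speed_kmh,
                        start_clock = floor(starts[i]),
                        seed = trip_seeds[2 * i - 1])
    rec <- simulate_sensor_records(tr, scenario, participant = p, day = d,
                                   seed = trip_seeds[2 * i])
    track <- merge_streams(tr, rec, quiet = TRUE)
    attr(track, "participant") <- p
    attr(track, "day") <- d
    attr(track, "trip_id") <- paste0("trip_", sprintf("%03d", i))
    segment_one_minute(track)
  })
}
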