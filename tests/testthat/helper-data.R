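# Shared, lazily-built fixtures.  Everything is generated in code with
# fixed seeds and cached for the session so expensive objects are built at
# most once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_network <- function() {
  cached("tiny_network", function() make_road_network(n_nodes = 49, seed = 7))
}

# 8 trips x 30 min = 240 one-minute segments under the default scenario
small_study <- function() {
  cached("small_study", function() {
    simulate_study(default_scenario(), n_trips = 8, minutes_per_trip = 30,
                   seed = 101, network = tiny_network())
  })
}

# moderate study used by fit-based tests (not the acceptance replicates)
medium_study <- function() {
  cached("medium_study", function() {
    simulate_study(default_scenario(), n_trips = 15, minutes_per_trip = 60,
                   seed = 202)
  })
}

small_fit <- function(response) {
  cached(paste0("small_fit_", response), function() {
    fit_gammar(medium_study(),
               gammar_spec(response, spline_time = 8, spline_space = 20))
  })
}

# hand-built straight-line trace: `secs` seconds on the given road types
# (one element per second), constant speed, no network attribute
manual_track <- function(road_type_per_sec, speed_kmh = 15,
                         laeq = 70, no2 = 200, ve = 35) {
  n <- length(road_type_per_sec)
  trace <- tibble::tibble(
    timestamp = seq_len(n),
    x = cumsum(rep(speed_kmh / 3.6, n)),
    y = 0,
    speed_kmh = speed_kmh,
    edge_id = cumsum(c(1, diff(match(road_type_per_sec,
                                     unique(road_type_per_sec))) != 0)),
    road_type = road_type_per_sec,
    slope_pct = 0,
    crossed_node = NA_integer_
  )
  minutes <- unique((trace$timestamp - 1) %/% 60)
  records <- tibble::tibble(
    timestamp_minute = minutes,
    laeq_1min = laeq, no2_ugm3 = no2,
    humidity_pct = 46, wind_kmh = 0, ve_lmin = ve
  )
  merge_streams(trace, records, quiet = TRUE)
}
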