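#' Configuration for the end-to-end exposure pipeline
#'
#' Bundles every knob of the simulate → segment → describe → fit → hazard
#' chain, with defaults small enough for interactive use.  The seed drives
#' every random stage, so a configuration identifies a run completely.
#'
#' @param seed Integer seed.
#' @param n_trips Number of simulated trips (>= 1 to run).
#' @param minutes_per_trip Trip duration in minutes.
#' @param scenario A `scenario_params` object.
#' @param criteria A [dose_criteria()].
#' @param spline_time,spline_space Basis sizes passed to the model specs.
#' @param fit_models Fit the noise and NO2 models (the slow stage).
#' @param hazard_duration_min Length of the dose curves in minutes.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 1, n_trips = 12, minutes_per_trip = 40,
                            scenario = default_scenario(),
                            criteria = dose_criteria(),
                            spline_time = 8, spline_space = 20,
                            fit_models = TRUE,
                            hazard_duration_min = 90) {
  structure(
    list(seed = seed, n_trips = n_trips,
         minutes_per_trip = minutes_per_trip,
         scenario = scenario, criteria = criteria,
         spline_time = spline_time, spline_space = spline_space,
         fit_models = fit_models,
         hazard_duration_min = hazard_duration_min),
    class = "pipeline_config"
  )
}

#' Run the full exposure pipeline
#'
#' Executes simulate → segment → describe → (fit → hazard) with the given
#' configuration, writes each stage's artifact as CSV/GeoJSON under
#' `out_dir`, and writes a `manifest.json` recording the seed, a hash of
#' the configuration, the package version and a content checksum per
#' artifact.  A rerun with the same configuration is bit-identical.  If a
#' stage fails, the manifest records the failure point before the error
#' propagates.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly a list; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir = tempfile("exposure_run_")) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config.")
  }
  if (config$n_trips < 1) {
    abort("Pipeline requires at least one trip (n_trips >= 1).")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config)
  manifest <- list(
    package = "cycleexposure",
    version = as.character(utils::packageVersion("cycleexposure")),
    seed = config$seed,
    config_hash = cfg_hash,
    stages = list()
  )
  record <- function(stage, file) {
    chk <- rlang::hash(readLines(file, warn = FALSE))
    manifest$stages[[stage]] <<- list(stage = stage, file = basename(file),
                                      checksum = chk)
  }
  fail <- function(stage, err) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(err)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    abort(paste0("Pipeline failed at stage '", stage, "': ",
                 conditionMessage(err)))
  }

  stage <- "simulate"
  segs <- tryCatch({
    net <- make_road_network(seed = config$seed)
    f_net <- file.path(out_dir, "network.geojson")
    write_network_geojson(net, f_net)
    record("network", f_net)
    s <- simulate_study(config$scenario, n_trips = config$n_trips,
                        minutes_per_trip = config$minutes_per_trip,
                        seed = config$seed, network = net)
    f_seg <- file.path(out_dir, "segments.csv")
    write_segments_csv(s, f_seg)
    record("segments", f_seg)
    s
  }, error = function(e) fail(stage, e))

  stage <- "describe"
  tryCatch({
    summ <- summarize_exposure(segs, include_moran = nrow(segs) <= 3000)
    f_sum <- file.path(out_dir, "summary.csv")
    write_segments_csv(summ, f_sum)
    record("summary", f_sum)
  }, error = function(e) fail(stage, e))

  if (config$fit_models) {
    stage <- "fit"
    fits <- tryCatch({
      fn <- fit_gammar(segs, gammar_spec(
        "noise", spline_time = config$spline_time,
        spline_space = config$spline_space))
      fc <- fit_gammar(segs, gammar_spec(
        "no2", spline_time = config$spline_time,
        spline_space = config$spline_space))
      tab <- bind_rows(
        tidy(fn) %>% mutate(response = "noise"),
        tidy(fc) %>% mutate(response = "no2")
      )
      f_fit <- file.path(out_dir, "coefficients.csv")
      write_segments_csv(tab, f_fit)
      record("coefficients", f_fit)
      list(noise = fn, no2 = fc)
    }, error = function(e) fail(stage, e))

    stage <- "hazard"
    tryCatch({
      locs <- pick_hazard_locations(config$scenario)
      curves <- hazard_curves(fits$noise, fits$no2, locs,
                              duration_min = config$hazard_duration_min,
                              criteria = config$criteria)
      f_cur <- file.path(out_dir, "dose_curves.csv")
      write_segments_csv(as_tibble_plain(curves), f_cur)
      record("dose_curves", f_cur)
      f_cross <- file.path(out_dir, "dose_crossings.csv")
      write_segments_csv(dose_crossings(curves), f_cross)
      record("dose_crossings", f_cross)
    }, error = function(e) fail(stage, e))
  }

  # the guideline worked examples, always part of the run report
  crit <- config$criteria
  worked <- tibble(
    quantity = c("dose_56_3_dba_24h_pct", "dose_75_dba_40min_pct",
                 "intake_threshold_pedestrian_ug",
                 "intake_threshold_cyclist_ug"),
    value = c(noise_dose(56.3, 24, crit),
              noise_dose(75, 40 / 60, crit),
              intake_threshold(crit$no2_guideline, crit$ve_pedestrian,
                               crit$guideline_duration),
              intake_threshold(crit$no2_guideline, crit$ve_cyclist,
                               crit$guideline_duration))
  )
  f_worked <- file.path(out_dir, "worked_examples.csv")
  write_segments_csv(worked, f_worked)
  record("worked_examples", f_worked)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate the small bundled fixture dataset
#'
#' Writes a compact, fully deterministic dataset (a 49-node network and
#' 240 one-minute segments from 8 trips) used by the fast tests; the same
#' seed always reproduces the same files byte for byte.
#'
#' @param seed Integer seed (the bundled copy uses 42).
#' @param dir Output directory.
#' @return Tibble of the written paths.
#' @export
make_fixtures <- function(seed = 42, dir = tempfile("fixtures_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr_seed(seed)
  net <- make_road_network(n_nodes = 49, spacing = 200, seed = seed)
  segs <- simulate_study(default_scenario(), n_trips = 8,
                         minutes_per_trip = 30, seed = seed, network = net)
  f_net <- file.path(dir, "fixture_network_synthetic.geojson")
  f_seg <- file.path(dir, "fixture_segments_synthetic.csv")
  write_network_geojson(net, f_net)
  write_segments_csv(segs, f_seg)
  tibble(what = c("network", "segments"), path = c(f_net, f_seg))
}
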