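#' Merge a GPS trace with per-minute sensor records
#'
#' Joins each 1 Hz fix to the sensor record of its containing minute
#' (Step 2 of the processing chain).  Fixes outside the sensor coverage are
#' dropped and their count reported; input order does not matter.
#'
#' @param trace A `gps_trace` tibble (1 Hz fixes with `timestamp` in
#'   seconds).
#' @param records A tibble of per-minute sensor records with
#'   `timestamp_minute`.
#' @param quiet Suppress the dropped-fix message.
#' @return A `merged_track` tibble: one row per retained fix with the
#'   covering sensor values joined on.
#' @export
merge_streams <- function(trace, records, quiet = FALSE) {
  if (nrow(trace) == 0L || nrow(records) == 0L) {
    abort("`trace` and `records` must both be non-empty.")
  }
  keep_attrs <- c("network", "start_clock", "participant", "day", "trip_id")
  atts <- attributes(trace)[intersect(keep_attrs, names(attributes(trace)))]
  trace <- arrange(as_tibble_plain(trace), .data$timestamp)
  records <- arrange(as_tibble_plain(records), .data$timestamp_minute)
  joined <- trace %>%
    mutate(timestamp_minute = (.data$timestamp - 1) %/% 60) %>%
    left_join(records, by = "timestamp_minute")
  dropped <- sum(is.na(joined$laeq_1min))
  joined <- filter(joined, !is.na(.data$laeq_1min))
  if (nrow(joined) == 0L) {
    abort("No overlap between trace and sensor records.")
  }
  if (dropped > 0 && !quiet) {
    inform(paste0("merge_streams: dropped ", dropped,
                  " fixes outside sensor coverage."))
  }
  for (a in names(atts)) attr(joined, a) <- atts[[a]]
  class(joined) <- c("merged_track", class(joined))
  joined
}

as_tibble_plain <- function(x) {
  x <- tibble::as_tibble(x)
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Divide a merged track into one-minute analysis segments
#'
#' The observation unit of the exposure models is the one-minute segment.
#' Each complete minute yields one segment carrying the minute's sound
#' level, NO2 concentration, ventilation, derived inhaled dose
#' (`(VE*0.001)*NO2`), road-class time shares (which sum to 1), mean speed
#' and grade, intersection crossings, weather, midpoint coordinates and
#' clock time.  A trailing partial minute is kept and flagged when it
#' covers at least 30 s, and discarded otherwise.
#'
#' @param track A `merged_track` from [merge_streams()].
#' @return A tibble of segments, one row per minute; `partial` flags
#'   kept incomplete minutes.  Returns an empty tibble with a warning when
#'   the track is shorter than 30 s.
#' @export
segment_one_minute <- function(track) {
  if (nrow(track) == 0L) abort("`track` must be non-empty.")
  if (nrow(track) < 30L) {
    warn("Track shorter than 30 s; no segments produced.")
    return(tibble())
  }
  cov <- minute_covariates(track)
  rec <- track %>%
    group_by(.data$timestamp_minute) %>%
    summarise(
      laeq_1min = first(.data$laeq_1min),
      no2_ugm3 = first(.data$no2_ugm3),
      humidity_pct = first(.data$humidity_pct),
      wind_kmh = first(.data$wind_kmh),
      ve_lmin = first(.data$ve_lmin),
      .groups = "drop"
    )
  seg <- cov %>%
    left_join(rec, by = "timestamp_minute") %>%
    filter(.data$n_fix >= 30L) %>%
    mutate(
      partial = .data$n_fix < 60L,
      inhaled_ug = inhaled_dose(.data$ve_lmin, .data$no2_ugm3),
      trip_id = attr(track, "trip_id") %||% "trip_001",
      participant = attr(track, "participant") %||% NA_character_,
      day = attr(track, "day") %||% NA_character_
    ) %>%
    arrange(.data$timestamp_minute) %>%
    mutate(segment_index = dplyr::row_number()) %>%
    select("trip_id", "segment_index", "timestamp_minute", "clock_min",
           "laeq_1min", "no2_ugm3", "ve_lmin", "inhaled_ug",
           "humidity_pct", "wind_kmh", "speed_kmh", "slope_pct",
           "intersections", dplyr::starts_with("share_"),
           "x", "y", "partial", "participant", "day", "n_fix")
  if (nrow(seg) == 0L) {
    warn("No minute covered at least 30 s; no segments produced.")
  }
  seg
}
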