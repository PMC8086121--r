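# Readers and writers for the exchange formats: GPX traces, GeoJSON road
# networks, CSV segment tables.  The synthetic coordinate system is planar
# metres; GPX needs geographic coordinates, so traces are mapped through a
# fixed synthetic anchor (a plate carree projection about 28.6 N, 77.2 E)
# and mapped back exactly on read.

GPX_ANCHOR <- list(lat = 28.6, lon = 77.2, epoch = "2019-02-04T08:00:00Z")
M_PER_DEG_LAT <- 111320
M_PER_DEG_LON <- 111320 * cos(28.6 * pi / 180)

#' Write a GPS trace as GPX
#'
#' One `trkpt` per fix with latitude/longitude derived from the planar
#' coordinates through a fixed synthetic anchor, a `time` element, and
#' speed and edge id as extensions.
#'
#' @param trace A `gps_trace` tibble.
#' @param path Output path.
#' @export
write_trace_gpx <- function(trace, path) {
  doc <- xml2::xml_new_root("gpx", version = "1.1",
                            creator = "cycleexposure")
  trk <- xml2::xml_add_child(doc, "trk")
  seg <- xml2::xml_add_child(trk, "trkseg")
  base <- as.POSIXct(GPX_ANCHOR$epoch, tz = "UTC",
                     format = "%Y-%m-%dT%H:%M:%SZ")
  for (i in seq_len(nrow(trace))) {
    pt <- xml2::xml_add_child(
      seg, "trkpt",
      lat = sprintf("%.8f", GPX_ANCHOR$lat + trace$y[i] / M_PER_DEG_LAT),
      lon = sprintf("%.8f", GPX_ANCHOR$lon + trace$x[i] / M_PER_DEG_LON))
    xml2::xml_add_child(pt, "time", format(
      base + trace$timestamp[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
    ext <- xml2::xml_add_child(pt, "extensions")
    xml2::xml_add_child(ext, "speed_kmh", sprintf("%.4f", trace$speed_kmh[i]))
    xml2::xml_add_child(ext, "edge_id", as.character(trace$edge_id[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GPX trace written by [write_trace_gpx()]
#'
#' @param path GPX file path.
#' @return A tibble with `timestamp`, `x`, `y`, `speed_kmh`, `edge_id`.
#' @export
read_trace_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  base <- as.POSIXct(GPX_ANCHOR$epoch, tz = "UTC",
                     format = "%Y-%m-%dT%H:%M:%SZ")
  times <- as.POSIXct(xml2::xml_text(xml2::xml_find_all(pts, "time")),
                      tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  tibble(
    timestamp = as.numeric(difftime(times, base, units = "secs")),
    x = (as.numeric(xml2::xml_attr(pts, "lon")) - GPX_ANCHOR$lon) *
      M_PER_DEG_LON,
    y = (as.numeric(xml2::xml_attr(pts, "lat")) - GPX_ANCHOR$lat) *
      M_PER_DEG_LAT,
    speed_kmh = as.numeric(
      xml2::xml_text(xml2::xml_find_all(pts, "extensions/speed_kmh"))),
    edge_id = as.integer(
      xml2::xml_text(xml2::xml_find_all(pts, "extensions/edge_id")))
  )
}

#' Write a road network as GeoJSON
#'
#' A `FeatureCollection` of `LineString` features with `edge_id`,
#' `road_type` and `slope_pct` properties; coordinates are planar metres.
#'
#' @param network A `road_network`.
#' @param path Output path.
#' @export
write_network_geojson <- function(network, path) {
  feats <- purrr::pmap(network$edges, function(edge_id, road_type, from, to,
                                               x0, y0, x1, y1, slope_pct,
                                               length_m, ...) {
    list(
      type = "Feature",
      properties = list(edge_id = edge_id, road_type = road_type,
                        slope_pct = round(slope_pct, 6),
                        from = from, to = to),
      geometry = list(
        type = "LineString",
        coordinates = list(c(round(x0, 3), round(y0, 3)),
                           c(round(x1, 3), round(y1, 3)))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection",
         crs_note = network$crs_note,
         features = feats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a road network from GeoJSON written by [write_network_geojson()]
#'
#' @param path GeoJSON file path.
#' @return A `road_network` object.
#' @export
read_network_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  edges <- purrr::map_dfr(js$features, function(f) {
    cc <- f$geometry$coordinates
    tibble(
      edge_id = f$properties$edge_id,
      road_type = f$properties$road_type,
      from = f$properties$from, to = f$properties$to,
      x0 = cc[[1]][[1]], y0 = cc[[1]][[2]],
      x1 = cc[[2]][[1]], y1 = cc[[2]][[2]],
      slope_pct = f$properties$slope_pct
    )
  }) %>%
    mutate(length_m = sqrt((.data$x1 - .data$x0)^2 + (.data$y1 - .data$y0)^2))
  n_nodes <- max(c(edges$from, edges$to))
  nodes <- tibble(node_id = seq_len(n_nodes),
                  x = NA_real_, y = NA_real_)
  nodes$x[edges$from] <- edges$x0; nodes$y[edges$from] <- edges$y0
  nodes$x[edges$to] <- edges$x1; nodes$y[edges$to] <- edges$y1
  nodes$degree <- tabulate(c(edges$from, edges$to), nbins = n_nodes)
  structure(list(nodes = nodes, edges = edges,
                 crs_note = js$crs_note %||% "planar, metres"),
            class = "road_network")
}

#' Write one-minute segments as CSV
#'
#' Deterministic formatting (fixed 4-decimal reals), so identical segment
#' tables always produce byte-identical files.
#'
#' @param segments Segment tibble.
#' @param path Output path.
#' @export
write_segments_csv <- function(segments, path) {
  fmt <- function(v) {
    if (is.double(v)) sprintf("%.4f", v)
    else if (is.logical(v)) ifelse(v, "TRUE", "FALSE")
    else as.character(v)
  }
  m <- vapply(segments, fmt, character(nrow(segments)))
  if (nrow(segments) == 1L) m <- matrix(m, nrow = 1,
                                        dimnames = list(NULL, names(segments)))
  lines <- c(paste(names(segments), collapse = ","),
             apply(m, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a segment CSV written by [write_segments_csv()]
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_segments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Write a trace as CSV
#'
#' @param trace A `gps_trace` tibble.
#' @param path Output path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as_tibble_plain(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write segments as GeoJSON points
#'
#' One `Point` feature per one-minute segment at its midpoint, carrying all
#' segment attributes as properties.
#'
#' @param segments Segment tibble.
#' @param path Output path.
#' @export
write_segments_geojson <- function(segments, path) {
  feats <- purrr::map(seq_len(nrow(segments)), function(i) {
    row <- segments[i, ]
    props <- as.list(row[setdiff(names(row), c("x", "y"))])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Point",
                         coordinates = c(row$x, row$y)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
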