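#' Simulate a cycling trip as a 1 Hz GPS trace on a road network
#'
#' Performs a random walk over network edges (avoiding immediate U-turns
#' where possible), assigns a per-minute riding speed fluctuating around
#' `mean_speed_kmh`, and emits one fix per second.  Each fix carries its
#' planar position, instantaneous speed, the edge it lies on and that
#' edge's road class and grade; crossings of intersection nodes (degree
#' >= 3) are tagged so segmentation can count them.
#'
#' @param network A [make_road_network()] object.
#' @param duration_min Trip duration in whole minutes (>= 1).
#' @param mean_speed_kmh Mean riding speed; the campaign average was
#'   17 km/h.
#' @param start_clock Start time in minutes since 08:00.
#' @param seed Integer seed.
#' @param speed_sd Between-minute SD of speed (km/h); 0 gives a perfectly
#'   constant speed.
#' @param start_node Optional starting node id; random by default.
#' @return A `gps_trace` tibble with one row per second: `timestamp`
#'   (seconds since 08:00), `x`, `y` (metres), `speed_kmh`, `edge_id`,
#'   `road_type`, `slope_pct`, `crossed_node` (node id passed since the
#'   previous fix, or `NA`).  The network and start clock are attached as
#'   attributes.
#' @examples
#' net <- make_road_network(n_nodes = 25, seed = 1)
#' tr <- simulate_trip(net, duration_min = 2, seed = 1)
#' nrow(tr)  # 120 fixes
#' @export
simulate_trip <- function(network, duration_min, mean_speed_kmh = 17,
                          start_clock = 0, seed = 1, speed_sd = 2,
                          start_node = NULL) {
  if (!inherits(network, "road_network")) abort("`network` must be a road_network.")
  if (duration_min < 1) abort("`duration_min` must be at least 1 (empty trace).")
  withr_seed(seed)

  n_sec <- as.integer(round(duration_min * 60))
  # per-minute speed, constant within each minute
  n_min <- ceiling(n_sec / 60)
  v_min <- pmax(rnorm(n_min, mean_speed_kmh, speed_sd), 3)
  if (speed_sd == 0) v_min <- rep(mean_speed_kmh, n_min)
  v_sec <- rep(v_min, each = 60L)[seq_len(n_sec)]
  dist_sec <- cumsum(v_sec / 3.6)  # metres travelled at each fix (1 s steps)
  total_dist <- dist_sec[n_sec]

  route <- walk_route(network, total_dist, start_node)
  # cumulative length breaks along the route
  len <- route$length_m
  brk <- cumsum(len)
  # edge index for each fix: first edge whose cumulative end >= distance
  ei <- findInterval(dist_sec, brk, left.open = TRUE) + 1L
  ei <- pmin(ei, nrow(route))
  d0 <- c(0, brk)[ei]           # distance at the start of the current edge
  frac <- (dist_sec - d0) / len[ei]
  frac <- pmin(pmax(frac, 0), 1)

  x <- route$x0[ei] + frac * (route$x1[ei] - route$x0[ei])
  y <- route$y0[ei] + frac * (route$y1[ei] - route$y0[ei])

  # node passed between consecutive fixes = entry node of the new edge
  crossed <- rep(NA_integer_, n_sec)
  step_new <- c(FALSE, diff(ei) > 0)
  crossed[step_new] <- route$enter_node[ei[step_new]]

  trace <- tibble(
    timestamp = start_clock * 60 + seq_len(n_sec),
    x = x, y = y,
    speed_kmh = v_sec,
    edge_id = route$edge_id[ei],
    road_type = route$road_type[ei],
    slope_pct = route$slope_signed[ei],
    crossed_node = crossed
  )
  attr(trace, "network") <- network
  attr(trace, "start_clock") <- start_clock
  class(trace) <- c("gps_trace", class(trace))
  trace
}

# Random walk over edges until at least `total_dist` metres of route exist.
# Returns one row per traversed edge with travel-direction endpoints and
# the node through which the edge was entered.
walk_route <- function(network, total_dist, start_node = NULL) {
  ed <- network$edges
  n_nodes <- nrow(network$nodes)
  # incident edge list per node
  inc <- vector("list", n_nodes)
  for (i in seq_len(nrow(ed))) {
    inc[[ed$from[i]]] <- c(inc[[ed$from[i]]], i)
    inc[[ed$to[i]]] <- c(inc[[ed$to[i]]], i)
  }
  node <- start_node %||% sample.int(n_nodes, 1)
  prev_edge <- NA_integer_
  rows <- list()
  acc <- 0
  while (acc < total_dist) {
    cand <- inc[[node]]
    if (length(cand) > 1L && !is.na(prev_edge)) {
      cand2 <- setdiff(cand, prev_edge)
      if (length(cand2) > 0L) cand <- cand2
    }
    e <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1)]
    forward <- ed$from[e] == node
    nxt <- if (forward) ed$to[e] else ed$from[e]
    rows[[length(rows) + 1L]] <- tibble(
      edge_id = ed$edge_id[e],
      x0 = if (forward) ed$x0[e] else ed$x1[e],
      y0 = if (forward) ed$y0[e] else ed$y1[e],
      x1 = if (forward) ed$x1[e] else ed$x0[e],
      y1 = if (forward) ed$y1[e] else ed$y0[e],
      length_m = ed$length_m[e],
      road_type = ed$road_type[e],
      # grade is signed along the direction of travel
      slope_signed = if (forward) ed$slope_pct[e] else -ed$slope_pct[e],
      enter_node = node
    )
    acc <- acc + ed$length_m[e]
    prev_edge <- e
    node <- nxt
  }
  bind_rows(rows)
}

#' @export
print.gps_trace <- function(x, ...) {
  cat("<gps_trace> ", nrow(x), " fixes (1 Hz), start ",
      attr(x, "start_clock"), " min past 08:00\n", sep = "")
  NextMethod()
}
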