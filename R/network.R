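#' The six modelled road classes
#'
#' Community road-network tags collapsed to the six classes used throughout
#' the package: trunk and motorway merged, unclassified and service merged,
#' residential streets the reference class in the exposure models.
#'
#' @export
road_types <- function() {
  c("trunk_motorway", "primary", "secondary", "tertiary",
    "residential", "unclassified_service")
}

#' Generate a synthetic typed road network
#'
#' Builds a connected planar road network on a jittered rectangular lattice
#' in planar metric coordinates.  Lattice edges are thinned at random while
#' preserving connectivity, each surviving edge receives a road class drawn
#' independently from `type_mix` and a signed percent grade, and node
#' degrees are recorded so that intersections (degree >= 3) can be counted
#' during segmentation.
#'
#' @param n_nodes Number of nodes (>= 4); laid out row-major on a lattice.
#' @param type_mix Named or ordered numeric vector of six proportions over
#'   [road_types()], summing to 1.
#' @param spacing Lattice spacing in metres (default 180).
#' @param edge_keep Probability of retaining each lattice edge, in (0, 1];
#'   candidate removals that would disconnect the network are skipped.
#' @param slope_sd SD of the signed edge grade in percent (default 1).
#' @param seed Integer seed; the same seed always yields the same network.
#' @return A `road_network` object: a list with tibbles `nodes`
#'   (`node_id, x, y, degree`) and `edges` (`edge_id, road_type, from, to,
#'   x0, y0, x1, y1, length_m, slope_pct`) plus `crs_note`.
#' @examples
#' net <- make_road_network(n_nodes = 25, seed = 1)
#' table(net$edges$road_type)
#' @export
make_road_network <- function(n_nodes = 225,
                              type_mix = default_type_mix(),
                              spacing = 180,
                              edge_keep = 0.85,
                              slope_sd = 1,
                              seed = 1) {
  if (n_nodes < 4) abort("`n_nodes` must be at least 4.")
  type_mix <- check_type_mix(type_mix)
  if (edge_keep <= 0 || edge_keep > 1) {
    abort("`edge_keep` must be in (0, 1]; values <= 0 would disconnect the network.")
  }
  withr_seed(seed)

  ncol <- ceiling(sqrt(n_nodes))
  nrow <- ceiling(n_nodes / ncol)
  idx <- seq_len(n_nodes) - 1L
  row <- idx %/% ncol
  col <- idx %% ncol
  nodes <- tibble(
    node_id = seq_len(n_nodes),
    x = col * spacing + runif(n_nodes, -0.2, 0.2) * spacing,
    y = row * spacing + runif(n_nodes, -0.2, 0.2) * spacing
  )

  # lattice adjacency: right and up neighbours
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n_nodes)) {
    r <- row[i]; cl <- col[i]
    right <- if (cl + 1L < ncol && i + 1L <= n_nodes) i + 1L else NA_integer_
    up <- if (i + ncol <= n_nodes) i + ncol else NA_integer_
    if (!is.na(right)) { from <- c(from, i); to <- c(to, right) }
    if (!is.na(up)) { from <- c(from, i); to <- c(to, up) }
  }

  as_graph <- function(f, t) {
    igraph::graph_from_data_frame(
      data.frame(from = f, to = t),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n_nodes))
    )
  }
  if (igraph::components(as_graph(from, to))$no != 1L) {
    abort("Internal lattice construction produced a disconnected network.")
  }

  # thin edges, never disconnecting
  n_edge <- length(from)
  drop_candidates <- which(runif(n_edge) > edge_keep)
  keep <- rep(TRUE, n_edge)
  for (e in drop_candidates[sample.int(length(drop_candidates))]) {
    keep_try <- keep
    keep_try[e] <- FALSE
    if (igraph::components(as_graph(from[keep_try], to[keep_try]))$no == 1L) {
      keep <- keep_try
    }
  }
  from <- from[keep]; to <- to[keep]
  n_edge <- length(from)

  edges <- tibble(
    edge_id = seq_len(n_edge),
    road_type = sample(road_types(), n_edge, replace = TRUE, prob = type_mix),
    from = from,
    to = to,
    x0 = nodes$x[from], y0 = nodes$y[from],
    x1 = nodes$x[to], y1 = nodes$y[to],
    slope_pct = rnorm(n_edge, 0, slope_sd)
  ) %>%
    mutate(length_m = sqrt((.data$x1 - .data$x0)^2 + (.data$y1 - .data$y0)^2))

  deg <- tabulate(c(from, to), nbins = n_nodes)
  nodes$degree <- deg

  structure(
    list(nodes = nodes, edges = edges, crs_note = "planar, metres"),
    class = "road_network"
  )
}

#' Default road-class mix
#'
#' Proportions of the six road classes used by the synthetic network, chosen
#' so that a ride sampling roads uniformly by time reproduces realistic
#' city-wide mean exposures under the default scenario coefficients.
#'
#' @return Named numeric vector over [road_types()], summing to 1.
#' @export
default_type_mix <- function() {
  c(trunk_motorway = 0.06, primary = 0.18, secondary = 0.22,
    tertiary = 0.20, residential = 0.26, unclassified_service = 0.08)
}

check_type_mix <- function(type_mix) {
  if (length(type_mix) != 6L) {
    abort("`type_mix` must have six entries, one per road class.")
  }
  if (!is.null(names(type_mix))) {
    missing <- setdiff(road_types(), names(type_mix))
    if (length(missing)) {
      abort(paste0("`type_mix` is missing classes: ",
                   paste(missing, collapse = ", ")))
    }
    type_mix <- type_mix[road_types()]
  }
  if (any(type_mix < 0) || abs(sum(type_mix) - 1) > 1e-8) {
    abort("`type_mix` must be non-negative and sum to 1.")
  }
  unname(type_mix)
}

#' @export
print.road_network <- function(x, ...) {
  cat("<road_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", x$crs_note, ")\n", sep = "")
  print(count(x$edges, .data$road_type))
  invisible(x)
}

# seed handling: isolate RNG state so generators do not disturb the caller
withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}
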