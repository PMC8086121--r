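#' Descriptive exposure statistics for one-minute segments
#'
#' Reproduces the standard descriptive table for mobile exposure
#' campaigns: per response the number of segments, percentiles
#' (1/5/10/25/50/75/90/95/99, linear interpolation between order
#' statistics), mean and SD — energy-based for the sound level via
#' [db_mean_sd()], arithmetic for NO2 and inhaled dose — the within-trip
#' autocorrelation index at lags 1 and 2, and optionally the maximum
#' distance-band Moran's I over a 50–500 m grid.
#'
#' @param segments Segment tibble from [segment_one_minute()] or
#'   [simulate_study()].
#' @param include_moran Compute the Moran's I scan (O(n^2) in segments).
#' @return A tibble with one row per response.
#' @export
summarize_exposure <- function(segments, include_moran = TRUE) {
  if (nrow(segments) < 2L) abort("Need at least 2 segments.")
  probs <- c(0.01, 0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95, 0.99)
  responses <- c(noise = "laeq_1min", no2 = "no2_ugm3",
                 inhalation = "inhaled_ug")
  purrr::map_dfr(names(responses), function(r) {
    col <- responses[[r]]
    v <- segments[[col]]
    pct <- quantile(v, probs, type = 7, names = FALSE)
    if (r == "noise") {
      ms <- db_mean_sd(v)
    } else {
      ms <- c(mean = mean(v), sd = sd(v))
    }
    a1 <- tryCatch(acf_index(segments, !!rlang::sym(col), k = 1),
                   error = function(e) NA_real_)
    a2 <- tryCatch(acf_index(segments, !!rlang::sym(col), k = 2),
                   error = function(e) NA_real_)
    row <- tibble(
      response = r, n = length(v),
      p01 = pct[1], p05 = pct[2], p10 = pct[3], p25 = pct[4],
      p50 = pct[5], p75 = pct[6], p90 = pct[7], p95 = pct[8],
      p99 = pct[9],
      mean = ms[["mean"]], sd = ms[["sd"]],
      acf_k1 = a1, acf_k2 = a2
    )
    if (include_moran) {
      sc <- tryCatch(morans_i_scan(segments, !!rlang::sym(col)),
                     error = function(e) list(best_i = NA_real_,
                                              best_d = NA_real_))
      row$morans_i <- sc$best_i
      row$morans_d <- sc$best_d
    }
    row
  })
}

#' Within-trip autocorrelation index
#'
#' Lag-`k` autocorrelation of an ordered one-minute exposure series,
#' computed within each trip (never across trip boundaries) and pooled as
#' the average weighted by the number of lag-`k` pairs each trip
#' contributes.
#'
#' @param data Segment tibble; must contain a trip identifier and be
#'   ordered in time within trips (it is re-sorted defensively).
#' @param value Unquoted column holding the series.
#' @param k Lag, in minutes.
#' @param trip Unquoted trip-identifier column (default `trip_id`).
#' @return The pooled lag-`k` autocorrelation.
#' @export
acf_index <- function(data, value, k = 1, trip = trip_id) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  tr <- tryCatch(rlang::eval_tidy(rlang::enquo(trip), data),
                 error = function(e) NULL)
  if (is.null(tr)) tr <- rep("all", length(v))
  ord <- order(tr, seq_along(v))
  v <- v[ord]; tr <- tr[ord]
  if (sd(v) == 0) abort("ACF undefined for a constant series.")
  per <- split(v, tr)
  num <- 0; den <- 0
  for (s in per) {
    n <- length(s)
    if (n <= k) next
    m <- mean(s)
    r <- sum((s[1:(n - k)] - m) * (s[(k + 1):n] - m)) / sum((s - m)^2)
    if (!is.finite(r)) next
    w <- n - k
    num <- num + w * r
    den <- den + w
  }
  if (den == 0) abort("No trip longer than the requested lag.")
  num / den
}

#' Distance-band Moran's I
#'
#' Spatial autocorrelation of segment values with binary neighbour weights:
#' `w_ij = 1` iff the distance between segment midpoints is in `(0, d]`.
#' Uses the standard statistic
#' `I = n/S0 * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values and `S0` the total weight.
#'
#' @param data Segment tibble with midpoint coordinate columns.
#' @param value Unquoted column holding the response.
#' @param d Neighbourhood distance in metres (> 0).
#' @param coords Names of the coordinate columns.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(data, value, d, coords = c("x", "y")) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  if (d <= 0) abort("`d` must be positive.")
  if (length(v) < 3L) abort("Need at least 3 segments.")
  z <- v - mean(v)
  if (sum(z^2) == 0) abort("Moran's I undefined for zero-variance values.")
  xy <- as.matrix(data[, coords])
  dm <- as.matrix(stats::dist(xy))
  w <- (dm > 0 & dm <= d) * 1
  s0 <- sum(w)
  if (s0 == 0) abort(paste0("No neighbour pairs within d = ", d, " m."))
  n <- length(v)
  (n / s0) * sum(w * tcrossprod(z)) / sum(z^2)
}

#' Scan Moran's I over a grid of neighbourhood distances
#'
#' Evaluates [morans_i()] on a distance grid (default 50 m to 500 m in
#' 50 m steps) and returns the maximum, the convention used when a single
#' spatial-autocorrelation figure is reported per response.  Distances with
#' no neighbour pairs are skipped.
#'
#' @inheritParams morans_i
#' @param d_grid Numeric vector of candidate distances in metres.
#' @return A list with `best_i`, `best_d`, and `grid` (a tibble of all
#'   evaluated distances).
#' @export
morans_i_scan <- function(data, value, d_grid = seq(50, 500, by = 50),
                          coords = c("x", "y")) {
  qv <- rlang::enquo(value)
  res <- purrr::map_dfr(d_grid, function(d) {
    i <- tryCatch(morans_i(data, !!qv, d = d, coords = coords),
                  error = function(e) NA_real_)
    tibble(d = d, morans_i = i)
  })
  ok <- filter(res, is.finite(.data$morans_i))
  if (nrow(ok) == 0L) abort("Moran's I could not be computed on any distance.")
  best <- ok %>% filter(.data$morans_i == max(.data$morans_i)) %>% slice(1)
  list(best_i = best$morans_i, best_d = best$d, grid = res)
}
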