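# Descriptive machinery: percentiles, ACF index, Moran's I.

# direct O(n^2) double-loop oracle for Moran's I with binary weights
morans_oracle <- function(x, y, v, d) {
  n <- length(v)
  z <- v - mean(v)
  num <- 0; s0 <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    dist_ij <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (dist_ij > 0 && dist_ij <= d) {
      num <- num + z[i] * z[j]
      s0 <- s0 + 1
    }
  }
  (n / s0) * num / sum(z^2)
}

test_that("summary percentiles are order statistics with interpolation", {
  segs <- tibble::tibble(
    trip_id = "t1", timestamp_minute = 1:101,
    laeq_1min = 60 + (1:101) / 10,
    no2_ugm3 = as.numeric(1:101),
    inhaled_ug = (1:101) / 20,
    x = runif(101, 0, 400), y = runif(101, 0, 400)
  )
  s <- summarize_exposure(segs, include_moran = FALSE)
  expect_equal(s$p50[s$response == "no2"], 51)  # median of 1..101
  expect_equal(s$n, rep(101L, 3))
  # monotone percentiles
  pct <- as.matrix(s[, paste0("p", c("01", "05", "10", "25", "50",
                                     "75", "90", "95", "99"))])
  expect_true(all(apply(pct, 1, function(r) all(diff(r) >= 0))))
})

test_that("constant segments yield equal percentiles and zero SD", {
  segs <- tibble::tibble(
    trip_id = "t1", timestamp_minute = 1:40,
    laeq_1min = 70, no2_ugm3 = 150, inhaled_ug = 5,
    x = runif(40, 0, 100), y = runif(40, 0, 100)
  )
  s <- summarize_exposure(segs, include_moran = FALSE)
  expect_equal(s$p01, s$p99)
  expect_equal(s$sd, rep(0, 3))
  expect_true(all(is.na(s$acf_k1)))  # undefined on a constant series
})

test_that("acf_index is near zero for white noise", {
  set.seed(33)
  d <- tibble::tibble(v = rnorm(5000), trip_id = "t1")
  expect_lt(abs(acf_index(d, v, k = 1)), 3 / sqrt(5000))
})

test_that("acf_index recovers an AR(1) coefficient", {
  set.seed(34)
  v <- as.numeric(arima.sim(list(ar = 0.6), n = 5000))
  d <- tibble::tibble(v = v, trip_id = "t1")
  expect_equal(acf_index(d, v, k = 1), 0.6, tolerance = 0.05 / 0.6)
})

test_that("acf_index never crosses trip boundaries", {
  set.seed(35)
  a <- rnorm(400); b <- rnorm(300)
  pooled <- tibble::tibble(v = c(a, b), trip_id = rep(c("a", "b"), c(400, 300)))
  ra <- acf_index(tibble::tibble(v = a, trip_id = "a"), v, k = 1)
  rb <- acf_index(tibble::tibble(v = b, trip_id = "b"), v, k = 1)
  manual <- (399 * ra + 299 * rb) / (399 + 299)
  expect_equal(acf_index(pooled, v, k = 1), manual, tolerance = 1e-12)
  expect_error(acf_index(tibble::tibble(v = rep(1, 10), trip_id = "a"), v),
               "constant")
})

test_that("morans_i equals the brute-force oracle exactly", {
  set.seed(36)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    df <- tibble::tibble(x = runif(n, 0, 300), y = runif(n, 0, 300),
                         v = rnorm(n))
    d <- runif(1, 40, 200)
    expect_equal(morans_i(df, v, d = d),
                 morans_oracle(df$x, df$y, df$v, d),
                 tolerance = 1e-12)
  }
})

test_that("a 2x2 checkerboard has Moran's I of -1", {
  df <- tibble::tibble(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                       v = c(1, -1, -1, 1))
  expect_equal(morans_i(df, v, d = 1), -1, tolerance = 1e-12)
})

test_that("permuted values give the null expectation -1/(n-1)", {
  set.seed(37)
  n <- 400
  df <- tibble::tibble(x = runif(n, 0, 500), y = runif(n, 0, 500),
                       v = sample(rnorm(n)))
  i_obs <- morans_i(df, v, d = 150)
  perm <- replicate(199, morans_i(dplyr::mutate(df, v = sample(v)), v,
                                  d = 150))
  expect_lt(abs(i_obs - (-1 / (n - 1))), 3 * sd(perm))
})

test_that("the distance scan returns the grid maximum", {
  set.seed(38)
  n <- 150
  df <- tibble::tibble(x = runif(n, 0, 1000), y = runif(n, 0, 1000))
  df$v <- sin(df$x / 150) + cos(df$y / 150) + rnorm(n, 0, 0.2)
  sc <- morans_i_scan(df, v)
  grid_vals <- sc$grid$morans_i
  expect_equal(sc$best_i, max(grid_vals, na.rm = TRUE))
  expect_equal(morans_i(df, v, d = sc$best_d), sc$best_i)
  # degenerate single-distance grid equals a direct call
  one <- morans_i_scan(df, v, d_grid = 250)
  expect_equal(one$best_i, morans_i(df, v, d = 250))
})

test_that("a smooth field with ~250 m range puts the scan optimum low", {
  set.seed(39)
  n <- 250
  df <- tibble::tibble(x = runif(n, 0, 1500), y = runif(n, 0, 1500))
  centers <- tibble::tibble(cx = runif(12, 0, 1500), cy = runif(12, 0, 1500),
                            h = rnorm(12))
  df$v <- purrr::pmap_dbl(df, function(x, y) {
    sum(centers$h * exp(-((x - centers$cx)^2 + (y - centers$cy)^2) /
                          (2 * 125^2)))
  })
  sc <- morans_i_scan(df, v)
  # the correlation range of the generating field is ~2*125 = 250 m;
  # bands beyond it mix decorrelated pairs, so the maximum sits at or
  # below ~250 m
  expect_lte(sc$best_d, 300)
  expect_gt(sc$best_i, 0.3)
})

test_that("spatially independent values stay inside the permutation band", {
  set.seed(40)
  n <- 120
  df <- tibble::tibble(x = runif(n, 0, 800), y = runif(n, 0, 800),
                       v = rnorm(n))
  sc <- morans_i_scan(df, v)
  best_null <- replicate(199, {
    morans_i_scan(dplyr::mutate(df, v = sample(v)), v)$best_i
  })
  expect_lte(sc$best_i, quantile(best_null, 0.95))
})

test_that("Moran's I error conditions are signalled", {
  df <- tibble::tibble(x = c(0, 100, 200), y = c(0, 0, 0), v = c(1, 2, 3))
  expect_error(morans_i(df, v, d = 10), "neighbour")
  expect_error(morans_i(dplyr::mutate(df, v = 1), v, d = 150), "variance")
  expect_error(morans_i(df[1:2, ], v, d = 150), "3 segments")
})
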