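# GAMMAR design construction, fitting, prediction, and diagnostics.

make_linear_segments <- function(n = 300, seed = 50, sd = 0) {
  set.seed(seed)
  tibble::tibble(
    trip_id = rep(paste0("t", 1:3), each = n / 3),
    timestamp_minute = rep(1:(n / 3), 3),
    clock_min = runif(n, 0, 600),
    x = runif(n, 0, 2000), y = runif(n, 0, 2000),
    intersections = rpois(n, 1.5),
    speed_kmh = runif(n, 10, 25),
    slope_pct = rnorm(n),
    humidity_pct = runif(n, 35, 60),
    wind_kmh = runif(n, 0, 15),
    share_trunk_motorway = 0.1 * runif(n),
    share_primary = 0.3 * runif(n),
    share_secondary = 0.2 * runif(n),
    share_tertiary = 0.2 * runif(n),
    share_unclassified_service = 0.05 * runif(n),
    day = sample(c("Monday", "Tuesday"), n, TRUE),
    participant = sample(c("I", "II"), n, TRUE)
  ) %>%
    dplyr::mutate(
      share_residential = 1 - share_trunk_motorway - share_primary -
        share_secondary - share_tertiary - share_unclassified_service,
      no2_ugm3 = 100 + 2 * humidity_pct - 1.5 * wind_kmh - 2 * intersections -
        1.6 * speed_kmh + 50 * share_primary + 30 * share_secondary +
        rnorm(n, 0, sd),
      laeq_1min = 76 + 3 * share_primary - 0.02 * speed_kmh + rnorm(n, 0, sd),
      inhaled_ug = 0.001 * 33 * no2_ugm3
    )
}

test_that("build_design enforces reference coding and response rules", {
  segs <- small_study()
  d_noise <- build_design(segs, gammar_spec("noise"))
  expect_false(any(c("humidity_pct", "wind_kmh") %in% colnames(d_noise$X)))
  expect_false("share_residential" %in% colnames(d_noise$X))
  d_no2 <- build_design(segs, gammar_spec("no2"))
  expect_true(all(c("humidity_pct", "wind_kmh") %in% colnames(d_no2$X)))
  expect_error(gammar_spec("noise", fixed = c("humidity_pct", "speed_kmh")),
               "excludes")
  # all-residential data: the five class columns are identically zero
  track <- manual_track(rep("residential", 180))
  seg3 <- segment_one_minute(track)
  seg3$day <- "Monday"; seg3$participant <- "I"
  d3 <- build_design(seg3, gammar_spec("noise", spline_time = 0,
                                       spline_space = 0))
  expect_true(all(d3$X[, grep("share_", colnames(d3$X))] == 0))
  expect_error(build_design(segs[, 1:4], gammar_spec("no2")),
               "Missing covariates")
})

test_that("penalized spline bases are centred", {
  segs <- small_study()
  d <- build_design(segs, gammar_spec("no2"))
  expect_lt(max(abs(colMeans(d$basis_time))), 1e-8)
  expect_lt(max(abs(colMeans(d$basis_space))), 1e-8)
})

test_that("with everything disabled the fit is exactly least squares", {
  segs <- make_linear_segments(sd = 0)
  spec <- gammar_spec("no2", spline_time = 0, spline_space = 0,
                      random = FALSE, ma_order = 0, likelihood = "gaussian")
  fit <- fit_gammar(segs, spec)
  ols <- lm(no2_ugm3 ~ humidity_pct + wind_kmh + intersections + speed_kmh +
              slope_pct + share_trunk_motorway + share_primary +
              share_secondary + share_tertiary + share_unclassified_service,
            data = segs)
  expect_equal(unname(fit$coefficients$estimate),
               unname(coef(ols)[c("(Intercept)", "humidity_pct", "wind_kmh",
                                  "intersections", "speed_kmh", "slope_pct",
                                  "share_trunk_motorway", "share_primary",
                                  "share_secondary", "share_tertiary",
                                  "share_unclassified_service")]),
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("an intercept-only fit on a constant response returns it", {
  segs <- make_linear_segments(n = 30) %>%
    dplyr::mutate(no2_ugm3 = 42)
  spec <- gammar_spec("no2", fixed = character(0), spline_time = 0,
                      spline_space = 0, random = FALSE, ma_order = 0,
                      likelihood = "gaussian")
  fit <- fit_gammar(segs, spec)
  expect_equal(fit$coefficients$estimate, 42, tolerance = 1e-9)
})

test_that("two-stage fit agrees with a one-stage mixed fit on MA-free data", {
  sc <- default_scenario()
  sc$ma_coefs <- lapply(sc$ma_coefs, function(x) x * 0)
  segs <- simulate_study(sc, n_trips = 12, minutes_per_trip = 50, seed = 61)
  ours <- fit_gammar(segs, gammar_spec("no2", spline_time = 8,
                                       spline_space = 20, ma_order = 0,
                                       likelihood = "gaussian"))
  segs$day_f <- factor(segs$day)
  segs$participant_f <- factor(segs$participant)
  g <- mgcv::gam(
    no2_ugm3 ~ humidity_pct + wind_kmh + intersections + speed_kmh +
      slope_pct + share_trunk_motorway + share_primary + share_secondary +
      share_tertiary + share_unclassified_service +
      s(clock_min, k = 8, bs = "tp") + s(x, y, k = 20, bs = "tp") +
      s(day_f, bs = "re") + s(participant_f, bs = "re"),
    data = segs, method = "REML")
  for (trm in c("share_primary", "speed_kmh", "humidity_pct")) {
    ci_ours <- ours$coefficients %>% dplyr::filter(term == trm)
    est_gam <- coef(g)[trm]
    se_gam <- sqrt(diag(vcov(g))[trm])
    # intervals overlap
    expect_lt(max(ci_ours$conf.low, est_gam - 1.96 * se_gam),
              min(ci_ours$conf.high, est_gam + 1.96 * se_gam))
  }
})

test_that("prediction obeys the linear-predictor algebra", {
  segs <- make_linear_segments(sd = 1, seed = 51)
  spec <- gammar_spec("no2", spline_time = 0, spline_space = 0,
                      random = FALSE, ma_order = 0, likelihood = "gaussian")
  fit <- fit_gammar(segs, spec)
  base <- tibble::tibble(
    humidity_pct = 0, wind_kmh = 0, intersections = 0, speed_kmh = 0,
    slope_pct = 0, share_trunk_motorway = 0, share_primary = 0,
    share_secondary = 0, share_tertiary = 0, share_unclassified_service = 0,
    clock_min = 300, x = 1000, y = 1000)
  p0 <- predict_exposure(fit, base)
  # with no smooths, reference covariates return the intercept
  expect_equal(p0$.pred, fit$coefficients$estimate[1], tolerance = 1e-9)
  # one full minute on a primary road adds exactly the primary coefficient
  p1 <- predict_exposure(fit, dplyr::mutate(base, share_primary = 1))
  beta_primary <- fit$coefficients$estimate[
    fit$coefficients$term == "share_primary"]
  expect_equal(p1$.pred - p0$.pred, beta_primary, tolerance = 1e-9)
})

test_that("random intercepts shift predictions by their estimate", {
  fit <- small_fit("no2")
  nd <- tibble::as_tibble(as.list(fit$covariate_means))
  nd$clock_min <- 300; nd$x <- 1200; nd$y <- 1200
  p_fixed <- predict_exposure(fit, nd, include_random = FALSE)
  nd$participant <- "III"; nd$day <- "Monday"
  p_re <- predict_exposure(fit, nd, include_random = TRUE)
  re <- fit$random
  shift <- re$estimate[re$group == "participant" & re$level == "III"] +
    re$estimate[re$group == "day" & re$level == "Monday"]
  expect_equal(p_re$.pred - p_fixed$.pred, shift, tolerance = 1e-6)
})

test_that("predictions outside the fitted support are flagged", {
  fit <- small_fit("no2")
  nd <- tibble::as_tibble(as.list(fit$covariate_means))
  nd$clock_min <- 300; nd$x <- 1e6; nd$y <- 1e6
  expect_warning(p <- predict_exposure(fit, nd), "support")
  expect_true(p$.extrapolated)
})

test_that("explained variance behaves like an R-squared", {
  # pure noise: near zero
  segs <- make_linear_segments(n = 300, seed = 52) %>%
    dplyr::mutate(no2_ugm3 = rnorm(dplyr::n()))
  spec0 <- gammar_spec("no2", spline_time = 0, spline_space = 0,
                       random = FALSE, ma_order = 0, likelihood = "gaussian")
  f0 <- fit_gammar(segs, spec0)
  expect_lt(bayes_r2(f0, "marginal"), 0.1)
  # noise-free linear signal: near one
  f1 <- fit_gammar(make_linear_segments(sd = 0), spec0)
  expect_gt(bayes_r2(f1, "marginal"), 0.999)
  # nesting on a full fit
  fit <- small_fit("no2")
  expect_lte(bayes_r2(fit, "marginal"), bayes_r2(fit, "conditional"))
  expect_gte(bayes_r2(fit, "marginal"), 0)
  expect_lte(bayes_r2(fit, "conditional"), 1)
})

test_that("ignoring the MA term leaves the generating lag-1 correlation", {
  sc <- default_scenario()
  segs <- simulate_study(sc, n_trips = 12, minutes_per_trip = 60, seed = 62)
  spec_noma <- gammar_spec("noise", spline_time = 8, spline_space = 20,
                           ma_order = 0)
  f <- fit_gammar(segs, spec_noma)
  rho1 <- ma_acf(sc$ma_coefs$noise)[1]
  expect_equal(f$resid_acf[1], rho1, tolerance = 0.12 / rho1)
  # independent-error data: residual ACF inside the white-noise band
  sc0 <- sc
  sc0$ma_coefs <- lapply(sc$ma_coefs, function(x) x * 0)
  segs0 <- simulate_study(sc0, n_trips = 12, minutes_per_trip = 60, seed = 63)
  f0 <- fit_gammar(segs0, spec_noma)
  expect_true(all(abs(f0$resid_acf) < 2 / sqrt(f0$n)))
})

test_that("tidy and glance return well-formed summaries", {
  fit <- small_fit("no2")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high",
                    "effect") %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate + 1e-12 &
                    td$estimate <= td$conf.high + 1e-12))
  expect_setequal(unique(td$effect), c("fixed", "ma", "random"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  dg <- residual_diagnostics(fit)
  expect_equal(nrow(dg$acf), 3)
  expect_gt(dg$tails$excess_kurtosis, 0)  # Student-t innovations
})

test_that("undersized data is rejected", {
  segs <- make_linear_segments(n = 60)
  expect_error(fit_gammar(segs, gammar_spec("no2")), "10 observations")
})
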