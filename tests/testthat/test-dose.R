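# Noise dose, intake thresholds, and hazard curves.

test_that("noise dose reproduces the guideline worked examples", {
  expect_equal(round(noise_dose(56.3, 24)), 50)
  expect_equal(round(noise_dose(75, 40 / 60)), 103)
  # criterion level for the criterion duration is exactly 100%
  crit <- dose_criteria()
  expect_equal(noise_dose(crit$l_c, crit$t_c, crit), 100, tolerance = 1e-12)
  expect_error(noise_dose(numeric(0), 1), "Empty")
})

test_that("noise dose is additive over interval partitions", {
  crit <- dose_criteria()
  set.seed(70)
  for (i in 1:10) {
    lv <- runif(6, 55, 90)
    hr <- runif(6, 0.1, 3)
    whole <- noise_dose(lv, hr, crit)
    parts <- sum(sapply(1:6, function(j) noise_dose(lv[j], hr[j], crit)))
    expect_equal(whole, parts, tolerance = 1e-12)
  }
})

test_that("intake thresholds follow guideline x ventilation x time", {
  expect_equal(intake_threshold(200, 15, 60), 180)
  expect_equal(intake_threshold(200, 35, 60), 420)
  expect_equal(intake_threshold(0, 35, 60), 0)
  expect_error(intake_threshold(200, -1, 60), "positive")
})

test_that("cumulative intake is a linear running sum", {
  ci <- cumulative_intake(rep(200, 60), 35)
  expect_equal(ci[60], 420)
  expect_equal(cumulative_intake(rep(0, 10), 35), rep(0, 10))
  a <- cumulative_intake(c(100, 150, 300), 35)
  b <- cumulative_intake(2 * c(100, 150, 300), 35)
  expect_equal(b, 2 * a)
  expect_true(all(diff(ci) >= 0))
})

test_that("minutes_to_noise_dose inverts noise_dose exactly", {
  crit <- dose_criteria()
  expect_equal(minutes_to_noise_dose(crit$l_c, crit), 1440)
  for (lv in c(60, 68.2, 75, 83, 91.4)) {
    m <- minutes_to_noise_dose(lv, crit)
    expect_equal(noise_dose(lv, m / 60, crit), 100, tolerance = 1e-9)
    m80 <- minutes_to_noise_dose(lv, crit, target_pct = 80)
    expect_equal(noise_dose(lv, m80 / 60, crit), 80, tolerance = 1e-9)
    # the 3 dB exchange rate: +10*log10(2) dB halves the time to dose
    expect_equal(minutes_to_noise_dose(lv + 10 * log10(2), crit), m / 2,
                 tolerance = 1e-9)
  }
  # 75 dB(A) reaches 100% just before the 40 min that give 103%:
  # closed form 1440 * 10^((59.3 - 75) / 10) = 38.76 min
  expect_equal(minutes_to_noise_dose(75), 1440 * 10^((59.3 - 75) / 10),
               tolerance = 1e-12)
  expect_lt(minutes_to_noise_dose(75), 40)
})

test_that("minutes_to_intake inverts the intake accumulation", {
  expect_equal(minutes_to_intake(200, 35, 420), 60)
  expect_equal(minutes_to_intake(400, 35, 420), 30)
  expect_equal(minutes_to_intake(200, 15, 180), 60)
  expect_warning(m0 <- minutes_to_intake(0, 35, 420), "never")
  expect_equal(m0, Inf)
})

test_that("hazard curves follow the fitted coefficients' dose algebra", {
  fit_noise <- small_fit("noise")
  fit_no2 <- small_fit("no2")
  locs <- pick_hazard_locations(default_scenario())
  curves <- hazard_curves(fit_noise, fit_no2, locs[2, ],
                          road_types = c("residential", "primary"),
                          duration_min = 60)
  # monotone accumulation
  curves %>%
    dplyr::group_by(location_label, road_type, response) %>%
    dplyr::summarise(mono = all(diff(value) >= -1e-12), .groups = "drop") %>%
    dplyr::pull(mono) %>%
    all() %>%
    expect_true()
  # moving residential -> primary multiplies the noise dose by 10^(delta/10)
  delta <- fit_noise$coefficients$estimate[
    fit_noise$coefficients$term == "share_primary"]
  d60 <- curves %>%
    dplyr::filter(response == "noise_dose_pct", minute == 60)
  ratio <- d60$value[d60$road_type == "primary"] /
    d60$value[d60$road_type == "residential"]
  expect_equal(ratio, 10^(delta / 10), tolerance = 1e-9)
  # crossing time is the first minute at or past the threshold
  cr <- dose_crossings(curves)
  expect_true(all(cr$crossing_min > 0))
  # zero duration: no curves
  empty <- hazard_curves(fit_noise, fit_no2, locs[1, ], duration_min = 0)
  expect_equal(nrow(empty), 0)
})

test_that("hazard locations span the generating field", {
  locs <- pick_hazard_locations(default_scenario())
  expect_equal(locs$label, c("low", "moderate", "high"))
  expect_true(all(diff(locs$field_value) > 0))
})
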