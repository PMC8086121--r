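# Stream merging and one-minute segmentation.

test_that("full sensor coverage joins every fix", {
  tr <- simulate_trip(tiny_network(), duration_min = 10, seed = 3)
  rec <- simulate_sensor_records(tr, default_scenario(), "I", "Monday",
                                 seed = 4)
  track <- merge_streams(tr, rec)
  expect_equal(nrow(track), 600)
  expect_true(all(!is.na(track$laeq_1min)))
})

test_that("fixes outside sensor coverage are dropped and reported", {
  tr <- simulate_trip(tiny_network(), duration_min = 2, seed = 3)
  rec <- simulate_sensor_records(tr, default_scenario(), "I", "Monday",
                                 seed = 4)
  rec_late <- rec[-1, ]  # sensors only cover the second minute
  expect_message(track <- merge_streams(tr, rec_late), "dropped 60")
  expect_equal(nrow(track), 60)
  expect_error(merge_streams(tr, rec[0, ]), "non-empty")
  rec_far <- rec %>% dplyr::mutate(timestamp_minute = timestamp_minute + 100)
  expect_error(merge_streams(tr, rec_far, quiet = TRUE), "overlap")
})

test_that("input order does not matter", {
  tr <- simulate_trip(tiny_network(), duration_min = 5, seed = 6)
  rec <- simulate_sensor_records(tr, default_scenario(), "I", "Monday",
                                 seed = 7)
  sorted <- merge_streams(tr, rec)
  shuffled <- merge_streams(tr[sample(nrow(tr)), ], rec[sample(nrow(rec)), ])
  expect_equal(as.data.frame(sorted), as.data.frame(shuffled))
})

test_that("road-class shares come from fix counts", {
  track <- manual_track(c(rep("primary", 40), rep("residential", 20)))
  seg <- segment_one_minute(track)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$share_primary, 2 / 3, tolerance = 1e-9)
  expect_equal(seg$share_residential, 1 / 3, tolerance = 1e-9)
})

test_that("shares sum to one and speed is preserved", {
  track <- manual_track(rep("residential", 120), speed_kmh = 15)
  seg <- segment_one_minute(track)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$share_residential, c(1, 1))
  shares <- rowSums(seg[, grep("^share_", names(seg))])
  expect_equal(shares, c(1, 1), tolerance = 1e-9)
  expect_equal(seg$speed_kmh, c(15, 15))
})

test_that("partial minutes follow the 30 s rule", {
  # 90 s: one complete minute plus a kept, flagged 30 s partial
  s90 <- segment_one_minute(manual_track(rep("primary", 90)))
  expect_equal(nrow(s90), 2)
  expect_equal(s90$partial, c(FALSE, TRUE))
  # 89 s: the 29 s remainder is discarded
  s89 <- segment_one_minute(manual_track(rep("primary", 89)))
  expect_equal(nrow(s89), 1)
  expect_false(s89$partial)
  # under 30 s in total: no segments, with a warning
  expect_warning(s20 <- segment_one_minute(manual_track(rep("primary", 20))),
                 "30 s")
  expect_equal(nrow(s20), 0)
})

test_that("segments satisfy the inhaled-dose identity", {
  segs <- small_study()
  expect_true(all(abs(
    segs$inhaled_ug - (segs$ve_lmin * 0.001) * segs$no2_ugm3) < 1e-9))
  shares <- rowSums(segs[, grep("^share_", names(segs))])
  expect_true(all(abs(shares - 1) < 1e-9))
  expect_true(all(is.finite(segs$laeq_1min)))
})

test_that("zero-noise simulation round-trips the mean structure", {
  sc <- zero_noise_scenario(default_scenario())
  net <- tiny_network()
  tr <- simulate_trip(net, duration_min = 20, seed = 21)
  rec <- simulate_sensor_records(tr, sc, "III", "Wednesday", seed = 22)
  truth <- attr(rec, "truth")
  track <- merge_streams(tr, rec)
  attr(track, "participant") <- "III"; attr(track, "day") <- "Wednesday"
  seg <- segment_one_minute(track)
  expect_equal(seg$laeq_1min, truth$mu_noise, tolerance = 1e-6)
  expect_equal(seg$no2_ugm3, truth$mu_no2, tolerance = 1e-6)
  # inhalation mean structure satisfies the dose equation
  expect_equal(seg$inhaled_ug, (seg$ve_lmin * 0.001) * truth$mu_no2,
               tolerance = 1e-6)
})

test_that("segment count is floor(seconds/60) plus at most one partial", {
  for (secs in c(60, 61, 135, 250)) {
    seg <- segment_one_minute(manual_track(rep("tertiary", secs)))
    full <- sum(!seg$partial)
    expect_equal(full, secs %/% 60)
    expect_lte(sum(seg$partial), 1)
  }
})
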