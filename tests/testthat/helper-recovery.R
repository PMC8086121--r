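# Simulate-then-refit replicate experiment shared by the acceptance tests:
# 20 independent studies of ~3,000 one-minute segments under the default
# scenario, each fitted with the NO2 and noise GAMMAR models.

recovery_replicates <- function() {
  cached("recovery_replicates", function() {
    purrr::map_dfr(1:20, function(i) {
      segs <- simulate_study(default_scenario(), n_trips = 50,
                             minutes_per_trip = 60, seed = 9000 + i)
      f_no2 <- fit_gammar(segs, gammar_spec("no2"))
      f_noise <- fit_gammar(segs, gammar_spec("noise"))
      cp <- f_no2$coefficients[f_no2$coefficients$term == "share_primary", ]
      np <- f_noise$coefficients[f_noise$coefficients$term == "share_primary", ]
      tibble::tibble(
        rep = i, n = nrow(segs),
        no2_primary = cp$estimate,
        no2_cover = cp$conf.low <= 47.21 & 47.21 <= cp$conf.high,
        noise_primary = np$estimate,
        noise_cover = np$conf.low <= 3.35 & 3.35 <= np$conf.high,
        ma1 = f_noise$ma$estimate[1],
        ma1_cover = f_noise$ma$conf.low[1] <= 0.61 &
          0.61 <= f_noise$ma$conf.high[1],
        racf_noise = max(abs(f_noise$resid_acf)),
        racf_no2 = max(abs(f_no2$resid_acf)),
        converged = f_no2$converged && f_noise$converged
      )
    })
  })
}
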