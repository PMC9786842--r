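test_that("environment generator is deterministic and physically consistent", {
  cfg <- season_config(start_date = "2018-06-01", end_date = "2018-06-10",
                       rng_seed = 5)
  e1 <- generate_environment(cfg)
  e2 <- generate_environment(cfg)
  expect_identical(e1, e2)
  # invariants of every record
  expect_true(all(e1$RH >= 0 & e1$RH <= 100))
  expect_true(all(e1$es >= e1$ea & e1$ea >= 0))
  expect_equal(e1$VPD, e1$es - e1$ea)
  expect_equal(e1$es, saturation_vapor_pressure(e1$T))
  expect_true(all(e1$PAR >= 0))
  # PAR is zero outside daylight and positive at midday
  h <- as.numeric(format(e1$timestamp, "%H"))
  expect_true(all(e1$PAR[h < 4 | h >= 22] == 0))
  expect_true(all(e1$PAR[h == 13] > 0))
  expect_error(season_config(timestep_minutes = -5), "timestep")
  expect_error(season_config(timestep_minutes = 7), "divide")
})

test_that("a dry period forces soil moisture toward its floor", {
  cfg <- season_config(start_date = "2018-08-01", end_date = "2018-09-20",
                       dry_period = list(start = "2018-08-16",
                                         end = "2018-09-10"),
                       rng_seed = 2)
  env <- generate_environment(cfg)
  dte <- as.Date(env$timestamp)
  inside <- dte >= as.Date("2018-08-25") & dte <= as.Date("2018-09-10")
  outside <- dte < as.Date("2018-08-10")
  expect_lt(mean(env$soil_moisture[inside]), 0.15)
  expect_gt(mean(env$soil_moisture[outside]), 0.25)
})

test_that("gas-exchange truth is self-consistent with the forward model", {
  env <- generate_environment(dry_season("2018-06-01", "2018-06-14"))
  rp <- resp_params(0.8, 40000)
  truth <- generate_gas_exchange(env, pine_physiology(), disc_params(), rp,
                                 seed = 3)
  night <- env$PAR == 0
  # night records respire at -R_d(T)
  expect_equal(truth$A[night], -mitochondrial_respiration(truth$Tl[night], rp))
  # ci follows ci = ca - 1.6 iWUE
  day <- !night
  expect_equal(truth$ci[day], env$ca[day] - 1.6 * truth$iwue_true[day])
  expect_true(all(truth$ci[day] > 0 & truth$ci[day] < env$ca[day]))
  # recomputing Delta through the discrimination module reproduces the truth
  D <- model_discrimination(truth$A[day], env$ca[day], truth$ci[day],
                            truth$Tl[day], disc_params(), rp)
  expect_lt(max(abs(D - truth$Delta_true[day])), 1e-9)
  dA <- delta_from_discrimination(env$delta13C_air[day], D)
  expect_lt(max(abs(dA - truth$deltaA_true[day])), 1e-9)
  # determinism of the full chain
  truth2 <- generate_gas_exchange(env, pine_physiology(), disc_params(), rp,
                                  seed = 3)
  expect_identical(truth, truth2)
  # an iWUE schedule forcing ci below Gamma* is rejected
  expect_error(
    generate_gas_exchange(env, pine_physiology(iwue_base = 245,
                                               iwue_daily_sd = 0,
                                               iwue_seasonal_amplitude = 0),
                          disc_params(), rp),
    "Gamma")
})

test_that("closure traces follow the dilution mass balance", {
  # zero flux, zero noise: constant at ambient
  tr0 <- make_trace(A = 0, E = 0)
  expect_true(all(tr0$c12 == tr0$c12[1]))
  expect_true(all(tr0$co2 == 400))
  # determinism under noise
  trA <- make_trace(A = 4, E = 1, noise_sd = 0.3, seed = 9)
  trB <- make_trace(A = 4, E = 1, noise_sd = 0.3, seed = 9)
  expect_identical(trA$c12, trB$c12)
  # generator/fitter round trip recovers the flux to < 0.1 %
  tr <- make_trace(A = 3.7, E = 0.8, deltaA = -27.3)
  expect_equal(fit_closure_flux(tr, "co2")$flux, 3.7, tolerance = 1e-3)
  expect_error(generate_closure_traces(data.frame(A = 1), data.frame(x = 1),
                                       chamber_spec(volume = -1)),
               "volume")
})

test_that("pool generation reproduces the stated mixing structure", {
  dates <- as.Date("2018-06-01") + 0:30
  dA <- data.frame(date = dates, value = -26 + sin(seq_along(dates) / 3))
  samp <- dates[10:25]
  # n = 0, zero noise: sucrose equals the assimilate series
  s0 <- generate_pool_series(dA, pool_mixing_spec("sucrose", n = 0,
                                                  lambda = 1, noise_sd = 0),
                             samp)
  expect_equal(s0$delta13c, dA$value[match(samp, dates)])
  # pinitol is invariant at -31
  pin <- generate_pool_series(dA, pool_mixing_spec("pinitol",
                                                   noise_sd = 0), samp)
  expect_true(all(pin$delta13c == -31))
  # WSC is a p / (1-p) mixture of pinitol and the sugar signal
  dA_const <- data.frame(date = dates, value = -26.4)
  wsc <- generate_pool_series(dA_const,
                              pool_mixing_spec("WSC", noise_sd = 0), samp)
  expect_equal(wsc$delta13c, rep(0.4 * -31 + 0.6 * -26.4, length(samp)))
  expect_equal(wsc$delta13c[1], -28.24)
  # lambda = 1 equals the unweighted (n+1)-day moving average
  s1 <- generate_pool_series(dA, pool_mixing_spec("sucrose", n = 2,
                                                  lambda = 1, noise_sd = 0),
                             samp)
  ma <- sapply(samp, function(d) mean(dA$value[match(d - 0:2, dates)]))
  expect_equal(s1$delta13c, ma)
  # missing look-back coverage is an error
  expect_error(generate_pool_series(dA, pool_mixing_spec("sucrose",
                                                         noise_sd = 0),
                                    dates[2]),
               "look-back")
  # TOM tracks assimilates during growth, then freezes at the window end
  gw <- list(start = dates[8], end = dates[20])
  tom <- generate_pool_series(dA, pool_mixing_spec("TOM", "0N",
                                                   growth_window = gw,
                                                   noise_sd = 0), samp)
  inside <- samp <= dates[20]
  w <- carryover_weights(4, 0.8)
  frozen <- sum(w * dA$value[match(dates[20] - 0:4, dates)])
  expect_true(all(tom$delta13c[!inside] == frozen))
  expect_equal(tom$delta13c[1],
               sum(w * dA$value[match(samp[1] - 0:4, dates)]))
})
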