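# shared builders for the test suite; everything is generated in code

# one-row environment record suitable for closure-trace generation
point_env <- function(T = 20, RH = 60, ca = 400, delta13C_air = -8.5,
                      P_amb = 101.3,
                      timestamp = as.POSIXct("2018-06-01 12:00:00",
                                             tz = "UTC")) {
  es <- saturation_vapor_pressure(T)
  data.frame(timestamp = timestamp, PAR = 1000, T = T, RH = RH,
             es = es, ea = es * RH / 100, P_amb = P_amb,
             ca = ca, delta13C_air = delta13C_air)
}

# one synthetic closure trace with known fluxes
make_trace <- function(A = 5, E = 1, deltaA = -26.68, noise_sd = 0,
                       chamber = chamber_spec(), seed = 1, env = point_env()) {
  truth <- data.frame(timestamp = env$timestamp, A = A, E = E,
                      deltaA_true = deltaA)
  generate_closure_traces(truth, env, chamber, noise_sd = noise_sd,
                          seed = seed)[[1]]
}

# a season in which no daytime record trips the RH filter, so the chamber,
# model and truth series are computed from identical record sets
dry_season <- function(start = "2018-06-01", end = "2018-07-15", seed = 7)
  season_config(start_date = start, end_date = end, timestep_minutes = 30,
                RH_base = 55, rng_seed = seed)

# daily flux-weighted daytime mean of the true assimilate delta13C
truth_deltaA_daily <- function(truth, sr = 4, ss = 22) {
  ok <- is.finite(truth$deltaA_true) & truth$A > 0
  out <- flux_weighted_daytime_mean(truth$timestamp[ok],
                                    truth$deltaA_true[ok], truth$A[ok],
                                    sr, ss)
  data.frame(date = out$date, value = out$mean)
}
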