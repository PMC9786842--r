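#' Configuration of a synthetic boreal growing season
#'
#' Parameterises the micrometeorological driver generator.  Defaults
#' emulate a boreal Scots pine site in midsummer conditions: long days,
#' maximum PAR around 1500 umol m-2 s-1 with day-to-day cloudiness, a mild
#' seasonal temperature arc with a diel cycle, RH anti-correlated with
#' temperature, ambient CO2 near 400 ppm and air delta13C near -8.5 permil.
#'
#' @param start_date,end_date calendar dates (coerced with as.Date).
#' @param timestep_minutes record spacing, minutes; must divide a day.
#' @param sunrise_hour,sunset_hour local hours of sunrise and sunset.
#' @param PAR_max clear-sky midday PAR, umol m-2 s-1.
#' @param cloud_range daily cloudiness multiplier range (uniform draw).
#' @param T_mean_seasonal season-mean air temperature, degC.
#' @param T_seasonal_amplitude half-range of the seasonal temperature arc, degC.
#' @param T_diel_amplitude amplitude of the diel temperature cycle, degC.
#' @param T_noise_sd Gaussian temperature noise, degC.
#' @param RH_base relative humidity at the season-mean temperature, percent.
#' @param RH_T_slope RH change per degC of temperature anomaly, percent/degC.
#' @param RH_noise_sd Gaussian RH noise, percent.
#' @param P_amb air pressure, kPa.
#' @param ca_ambient ambient CO2, ppm.
#' @param delta13C_air delta13C of ambient CO2, permil vs V-PDB.
#' @param rain_prob daily probability of a rain day.
#' @param rain_mean_mm mean daily rainfall on rain days, mm.
#' @param soil_moisture_base volumetric soil moisture outside dry spells.
#' @param dry_period optional \code{list(start=, end=, floor=)} forcing soil
#'   moisture toward \code{floor} (default 0.1 m3 m-3) over the interval.
#' @param rng_seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class \code{"season_config"}.
#' @export
season_config <- function(start_date = "2018-05-01", end_date = "2018-09-30",
                          timestep_minutes = 30,
                          sunrise_hour = 4, sunset_hour = 22,
                          PAR_max = 1500, cloud_range = c(0.35, 1),
                          T_mean_seasonal = 12, T_seasonal_amplitude = 6,
                          T_diel_amplitude = 5, T_noise_sd = 0.5,
                          RH_base = 70, RH_T_slope = -1.5, RH_noise_sd = 3,
                          P_amb = 101.3, ca_ambient = 400,
                          delta13C_air = -8.5,
                          rain_prob = 0.25, rain_mean_mm = 5,
                          soil_moisture_base = 0.30, dry_period = NULL,
                          rng_seed = 1L) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (!(start_date < end_date)) stop("start_date must precede end_date", call. = FALSE)
  stop_if_not_number(timestep_minutes, "timestep_minutes", positive = TRUE)
  if (1440 %% timestep_minutes != 0)
    stop("timestep_minutes must divide a day (1440 min)", call. = FALSE)
  stop_if_not_number(PAR_max, "PAR_max", positive = TRUE)
  if (RH_base <= 0 || RH_base > 100)
    stop("RH_base must lie in (0, 100]", call. = FALSE)
  if (!is.null(dry_period)) {
    dry_period$start <- as.Date(dry_period$start)
    dry_period$end <- as.Date(dry_period$end)
    if (is.null(dry_period$floor)) dry_period$floor <- 0.1
  }
  structure(as.list(environment()), class = "season_config")
}

#' Generate a synthetic environmental record series
#'
#' Produces one record per timestep with diurnal PAR (half-sine between
#' sunrise and sunset scaled by a daily cloudiness factor, zero at night),
#' temperature as seasonal arc + diel cycle + Gaussian noise, RH
#' anti-correlated with the temperature anomaly, es/ea/VPD from the Tetens
#' formula, daily precipitation, soil moisture with an optional dry spell,
#' and constant ca and delta13C of air.  Deterministic for a given
#' \code{rng_seed}.
#'
#' @param config a \code{\link{season_config}}.
#' @return data.frame with columns \code{timestamp} (POSIXct UTC),
#'   \code{PAR}, \code{T}, \code{RH}, \code{es}, \code{ea}, \code{VPD},
#'   \code{P_amb}, \code{precipitation}, \code{soil_moisture}, \code{ca},
#'   \code{delta13C_air}, \code{is_daytime}.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "season_config"))
  cf <- config
  with_seed(cf$rng_seed, {
    ts <- seq(as.POSIXct(paste(cf$start_date, "00:00:00"), tz = "UTC"),
              as.POSIXct(paste(cf$end_date, "23:59:59"), tz = "UTC"),
              by = cf$timestep_minutes * 60)
    dte <- as.Date(ts)
    days <- sort(unique(dte))
    D <- length(days)
    day_idx <- match(dte, days)
    frac <- if (D > 1) (day_idx - 1) / (D - 1) else rep(0.5, length(ts))
    h <- hour_of_day(ts)
    # PAR: half-sine over daylight, daily cloudiness multiplier
    cloud <- runif(D, cf$cloud_range[1], cf$cloud_range[2])
    daylight <- h > cf$sunrise_hour & h < cf$sunset_hour
    PAR <- numeric(length(ts))
    PAR[daylight] <- cf$PAR_max * cloud[day_idx[daylight]] *
      sin(pi * (h[daylight] - cf$sunrise_hour) /
            (cf$sunset_hour - cf$sunrise_hour))
    # temperature: seasonal arc + diel cycle (warmest mid-afternoon) + noise
    T_season <- cf$T_mean_seasonal + cf$T_seasonal_amplitude * sin(pi * frac)
    T_diel <- cf$T_diel_amplitude * sin(2 * pi * (h - 9) / 24)
    T <- T_season + T_diel + rnorm(length(ts), sd = cf$T_noise_sd)
    # RH anti-correlated with the temperature anomaly
    RH <- cf$RH_base + cf$RH_T_slope * (T - cf$T_mean_seasonal) +
      rnorm(length(ts), sd = cf$RH_noise_sd)
    RH <- pmin(100, pmax(5, RH))
    es <- saturation_vapor_pressure(T)
    ea <- es * RH / 100
    # daily precipitation spread uniformly over the day's records
    rain_day <- rbinom(D, 1, cf$rain_prob) *
      rexp(D, rate = 1 / cf$rain_mean_mm)
    per_rec <- 1440 / cf$timestep_minutes
    precipitation <- rain_day[day_idx] / per_rec
    # soil moisture, optionally drawn down over a dry period
    sm_day <- rep(cf$soil_moisture_base, D) + rnorm(D, sd = 0.005)
    if (!is.null(cf$dry_period)) {
      inside <- days >= cf$dry_period$start & days <= cf$dry_period$end
      if (any(inside)) {
        k <- seq_len(sum(inside))
        ramp <- cf$soil_moisture_base +
          (cf$dry_period$floor - cf$soil_moisture_base) *
          pmin(1, k / max(3, length(k) / 2))
        sm_day[inside] <- ramp + rnorm(sum(inside), sd = 0.003)
      }
    }
    data.frame(timestamp = ts, PAR = PAR, T = T, RH = RH,
               es = es, ea = ea, VPD = es - ea,
               P_amb = cf$P_amb, precipitation = precipitation,
               soil_moisture = sm_day[day_idx],
               ca = cf$ca_ambient, delta13C_air = cf$delta13C_air,
               is_daytime = daylight)
  })
}

#' Shoot physiology parameters for the gas-exchange generator
#'
#' @param Amax light-saturated assimilation, umol m-2 s-1 (all-sided area).
#' @param K_par half-saturation PAR of the light response, umol m-2 s-1.
#' @param T_opt,T_width optimum and width (degC) of the Gaussian temperature
#'   modifier of assimilation.
#' @param iwue_base season-mean intrinsic water-use efficiency, ppm.
#' @param iwue_seasonal_amplitude seasonal arc of the iWUE schedule, ppm.
#' @param iwue_daily_sd day-to-day Gaussian jitter of the schedule, ppm.
#' @param gs_night residual night-time stomatal conductance, mol m-2 s-1.
#' @param resp_delta13C delta13C of night-time respired CO2, permil.
#' @return a list of class \code{"pine_physiology"}.
#' @export
pine_physiology <- function(Amax = 6, K_par = 250, T_opt = 18, T_width = 20,
                            iwue_base = 82, iwue_seasonal_amplitude = 20,
                            iwue_daily_sd = 15, gs_night = 0.002,
                            resp_delta13C = -26) {
  structure(as.list(environment()), class = "pine_physiology")
}

#' Generate gas-exchange ground truth for an environmental series
#'
#' Daytime assimilation follows a saturating light response with a Gaussian
#' temperature modifier; a per-day iWUE schedule (seasonal arc plus daily
#' jitter, constant within a day) sets stomatal conductance gs = A/iWUE,
#' transpiration E = gs (es - ea)/P_amb, and ci = ca - 1.6 iWUE.  The true
#' discrimination Delta and delta13C of assimilates are computed with the
#' forward discrimination model, so the truth is self-consistent by
#' construction.  Night records carry A = -R_d(T) (efflux) and no
#' discrimination.
#'
#' @param env environment records from \code{\link{generate_environment}}.
#' @param physiology a \code{\link{pine_physiology}} list.
#' @param params a \code{\link{disc_params}} object.
#' @param resp a \code{\link{resp_params}} object.
#' @param seed integer seed for the iWUE schedule jitter.
#' @return data.frame with \code{timestamp}, \code{A}, \code{E}, \code{gs},
#'   \code{Tl}, \code{ci}, \code{iwue_true}, \code{Delta_true},
#'   \code{deltaA_true}.
#' @export
generate_gas_exchange <- function(env, physiology = pine_physiology(),
                                  params = disc_params(), resp,
                                  seed = 1L) {
  stopifnot(nrow(env) > 0, inherits(resp, "resp_params"))
  ph <- physiology
  with_seed(seed, {
    dte <- as.Date(env$timestamp)
    days <- sort(unique(dte))
    D <- length(days)
    frac <- if (D > 1) (match(dte, days) - 1) / (D - 1) else rep(0.5, nrow(env))
    iwue_day <- ph$iwue_base +
      ph$iwue_seasonal_amplitude * sin(pi * (seq_len(D) - 1) / max(1, D - 1)) +
      rnorm(D, sd = ph$iwue_daily_sd)
    iwue_day <- pmax(40, iwue_day)
    iwue <- iwue_day[match(dte, days)]
    day <- env$PAR > 0
    Tl <- env$T
    R_d <- mitochondrial_respiration(Tl, resp)
    tmod <- exp(-((Tl - ph$T_opt) / ph$T_width)^2)
    A <- ifelse(day,
                ph$Amax * env$PAR / (env$PAR + ph$K_par) * tmod,
                -R_d)
    ci <- ifelse(day, env$ca - 1.6 * iwue, NA_real_)
    G <- gamma_star(Tl, params$R_gas)
    if (any(day & ci <= G))
      stop("iWUE schedule forces ci <= Gamma* (model outside validity)",
           call. = FALSE)
    gs <- ifelse(day, A / iwue, ph$gs_night)
    E <- gs * 1000 * (env$es - env$ea) / env$P_amb
    Delta <- rep(NA_real_, nrow(env))
    deltaA <- rep(NA_real_, nrow(env))
    if (any(day)) {
      Delta[day] <- model_discrimination(A[day], env$ca[day], ci[day],
                                         Tl[day], params, resp)
      deltaA[day] <- delta_from_discrimination(env$delta13C_air[day], Delta[day])
    }
    data.frame(timestamp = env$timestamp, A = A, E = E, gs = gs, Tl = Tl,
               ci = ci, iwue_true = ifelse(day, iwue, NA_real_),
               Delta_true = Delta, deltaA_true = deltaA)
  })
}

#' Chamber geometry and sampling setup
#'
#' @param volume chamber volume, dm3 (the field systems used 1 and 2.1 dm3).
#' @param needle_area enclosed all-sided needle area, m2.
#' @param sample_flow sample air flow, dm3 min-1.
#' @return a list of class \code{"chamber_spec"}.
#' @export
chamber_spec <- function(volume = 1, needle_area = 0.02, sample_flow = 2) {
  stop_if_not_number(volume, "volume", positive = TRUE)
  stop_if_not_number(needle_area, "needle_area", positive = TRUE)
  stop_if_not_number(sample_flow, "sample_flow", positive = TRUE)
  structure(list(volume = volume, needle_area = needle_area,
                 sample_flow = sample_flow), class = "chamber_spec")
}

#' Generate chamber-closure concentration traces from gas-exchange truth
#'
#' For each paired truth/environment record, simulates a 65 s closure of a
#' non-airtight chamber under the first-order dilution mass balance
#' dC/dt = (q/V)(C_amb - C) - F S/(V rho): the concentrations relax
#' exponentially from ambient toward C_amb - F S/(q rho).  The 13CO2 trace
#' is built so that the 13C/12C flux ratio matches the record's true
#' delta13C of assimilates (respired delta13C at night); 12CO2/13CO2 are
#' sampled at 0.5 s, bulk CO2 and H2O at 5 s.  Optional additive Gaussian
#' noise; deterministic given \code{seed}.
#'
#' @param truth gas-exchange records from \code{\link{generate_gas_exchange}}.
#' @param env matching environment records (same rows).
#' @param chamber a \code{\link{chamber_spec}}.
#' @param noise_sd Gaussian noise SD on the 12CO2 and bulk CO2 traces, ppm.
#' @param noise_sd_c13 noise SD on the 13CO2 trace, ppm.
#' @param noise_sd_h2o noise SD on the H2O trace, ppm.
#' @param resp_delta13C delta13C assigned to night-time respiratory efflux,
#'   permil.
#' @param closure_length closure duration, s.
#' @param seed integer seed for the noise.
#' @return a list of \code{\link{closure_trace}} objects.
#' @export
generate_closure_traces <- function(truth, env, chamber = chamber_spec(),
                                    noise_sd = 0,
                                    noise_sd_c13 = noise_sd * 0.012,
                                    noise_sd_h2o = noise_sd * 50,
                                    resp_delta13C = -26,
                                    closure_length = 65, seed = 1L) {
  stopifnot(inherits(chamber, "chamber_spec"), nrow(truth) == nrow(env))
  q <- chamber$sample_flow / 60 / 1000   # m3 s-1
  V <- chamber$volume / 1000             # m3
  S <- chamber$needle_area
  k <- q / V
  t12 <- seq(0, closure_length, by = 0.5)
  t5 <- seq(0, closure_length, by = 5)
  with_seed(seed, {
    lapply(seq_len(nrow(truth)), function(i) {
      rho <- air_molar_density(env$P_amb[i], env$T[i])
      F_co2 <- truth$A[i]                       # uptake positive
      dflux <- if (is.finite(truth$deltaA_true[i]))
        truth$deltaA_true[i] else resp_delta13C
      R_F <- R_VPDB * (1 + dflux / 1000)
      F12 <- F_co2 / (1 + R_F)
      F13 <- F_co2 - F12
      amb <- ambient_isotopologues(env$ca[i], env$delta13C_air[i])
      h2o_amb <- env$ea[i] / env$P_amb[i] * 1e6
      F_h2o <- -truth$E[i] * 1000               # release -> negative uptake
      curve <- function(tt, C_amb, FF) {
        C_eq <- C_amb - FF * S / (q * rho)
        C_eq + (C_amb - C_eq) * exp(-k * tt)
      }
      c12 <- curve(t12, amb$c12, F12) + rnorm(length(t12), sd = noise_sd)
      c13 <- curve(t12, amb$c13, F13) + rnorm(length(t12), sd = noise_sd_c13)
      co2 <- curve(t5, env$ca[i], F_co2) + rnorm(length(t5), sd = noise_sd)
      h2o <- curve(t5, h2o_amb, F_h2o) + rnorm(length(t5), sd = noise_sd_h2o)
      closure_trace(closure_id = sprintf("closure_%05d", i),
                    t12 = t12, c12 = c12, c13 = c13,
                    t5 = t5, co2 = co2, h2o = h2o,
                    chamber_volume = chamber$volume,
                    needle_area = chamber$needle_area,
                    sample_flow = chamber$sample_flow,
                    ca = env$ca[i], delta13C_air = env$delta13C_air[i],
                    T_chamber = env$T[i], RH_chamber = env$RH[i],
                    P_amb = env$P_amb[i], timestamp = env$timestamp[i])
    })
  })
}

#' Mixing specification of one leaf carbon pool
#'
#' Describes how a pool's delta13C is generated from the daily assimilate
#' delta13C series: a geometric carry-over of the assimilate signal
#' (sucrose; sugars inside WSC; TOM during leaf growth), an isotopically
#' invariant value (pinitol, starch, mature 1N TOM), or a two-member
#' mixture (WSC = pinitol share p plus sugar signal).  Defaults per pool
#' follow needle observations for Scots pine: sucrose memory n = 4 d with
#' lambda = 0.8 and 0.24 permil noise, pinitol invariant at -31 permil (1N;
#' -30.1 for 0N) with 0.19 permil noise, WSC a 40/60 pinitol/sugar mixture
#' with a +0.6 permil 0N offset, invariant starch, and TOM tracking the
#' assimilate signal only during the needle growth window.
#'
#' @param pool_name one of "sucrose", "pinitol", "WSC", "starch", "TOM".
#' @param generation "1N" (one-year-old) or "0N" (current-year needles).
#' @param n carry-over memory, days.
#' @param lambda previous-day weight, (0, 1].
#' @param invariant_value permil; if set, the pool is invariant at it.
#' @param pinitol_share fraction p of WSC carbon that is pinitol (WSC only).
#' @param pinitol_value delta13C of the pinitol member, permil (WSC only).
#' @param growth_window \code{list(start=, end=)} Dates (TOM 0N only).
#' @param noise_sd Gaussian measurement noise, permil.
#' @param offset additive offset versus the assimilate signal, permil.
#' @param flat use flat carry-over weights.
#' @return an object of class \code{"pool_mixing_spec"}.
#' @export
pool_mixing_spec <- function(pool_name, generation = "1N",
                             n = NULL, lambda = NULL,
                             invariant_value = NULL,
                             pinitol_share = NULL, pinitol_value = -31,
                             growth_window = NULL,
                             noise_sd = NULL, offset = NULL,
                             flat = FALSE) {
  pool_name <- match.arg(pool_name,
                         c("sucrose", "pinitol", "WSC", "starch", "TOM"))
  generation <- match.arg(generation, c("1N", "0N"))
  def <- switch(pool_name,
    sucrose = list(n = 4, lambda = 0.8, noise_sd = 0.24, offset = 0),
    pinitol = list(invariant_value = if (generation == "1N") -31 else -30.1,
                   noise_sd = 0.19, offset = 0, n = 0, lambda = 1),
    WSC = list(n = 4, lambda = 0.8, pinitol_share = 0.4, noise_sd = 0.1,
               offset = if (generation == "1N") 0 else 0.6),
    starch = list(invariant_value = if (generation == "1N") -25.5 else -24.8,
                  noise_sd = 0.1, offset = 0, n = 0, lambda = 1),
    TOM = list(n = 4, lambda = 0.8, noise_sd = 0.1, offset = 0,
               invariant_value = if (generation == "1N") -29.6 else NULL))
  pick <- function(x, d) if (is.null(x)) d else x
  n <- pick(n, def$n); lambda <- pick(lambda, def$lambda)
  invariant_value <- pick(invariant_value, def$invariant_value)
  pinitol_share <- pick(pinitol_share, def$pinitol_share)
  noise_sd <- pick(noise_sd, def$noise_sd)
  offset <- pick(offset, def$offset)
  if (!is.null(lambda) && (lambda < 0 || lambda > 1))
    stop("lambda must lie in [0, 1]", call. = FALSE)
  if (!is.null(n) && n < 0) stop("n must be >= 0", call. = FALSE)
  if (!is.null(pinitol_share) && (pinitol_share < 0 || pinitol_share > 1))
    stop("pinitol_share must lie in [0, 1]", call. = FALSE)
  if (pool_name == "TOM" && generation == "0N" && is.null(growth_window))
    stop("TOM 0N requires a growth_window", call. = FALSE)
  if (!is.null(growth_window)) {
    growth_window$start <- as.Date(growth_window$start)
    growth_window$end <- as.Date(growth_window$end)
  }
  structure(list(pool_name = pool_name, generation = generation,
                 n = n, lambda = lambda, invariant_value = invariant_value,
                 pinitol_share = pinitol_share, pinitol_value = pinitol_value,
                 growth_window = growth_window, noise_sd = noise_sd,
                 offset = offset, flat = flat),
            class = "pool_mixing_spec")
}

#' Generate a delta13C series of one leaf carbon pool
#'
#' Applies the pool's mixing specification to a daily assimilate delta13C
#' series: carry-over weighting for sucrose (and the sugar member of WSC,
#' and TOM during leaf growth), constant values for invariant pools, and
#' linear mixing for WSC.  TOM (0N) tracks the weighted assimilate signal
#' during its growth window and is frozen at the window-end value
#' afterwards; dates before the window yield NA.
#'
#' @param deltaA_daily data.frame with \code{date} and \code{value}: the
#'   daily delta13C of assimilates, covering each sampling date back n days.
#' @param spec a \code{\link{pool_mixing_spec}}.
#' @param sampling_dates Dates at which the pool is sampled.
#' @param seed integer seed for the measurement noise.
#' @return data.frame with \code{date}, \code{pool}, \code{generation},
#'   \code{delta13c}.
#' @export
generate_pool_series <- function(deltaA_daily, spec, sampling_dates,
                                 seed = 1L) {
  stopifnot(inherits(spec, "pool_mixing_spec"))
  sampling_dates <- as.Date(sampling_dates)
  sugar_at <- function(at) {
    integrate_carryover(deltaA_daily$date, deltaA_daily$value,
                        spec$n, spec$lambda, at = at, flat = spec$flat)$value
  }
  base <- switch(spec$pool_name,
    sucrose = sugar_at(sampling_dates),
    pinitol = rep(spec$invariant_value, length(sampling_dates)),
    starch = rep(spec$invariant_value, length(sampling_dates)),
    WSC = spec$pinitol_share * spec$pinitol_value +
      (1 - spec$pinitol_share) * sugar_at(sampling_dates),
    TOM = {
      if (!is.null(spec$invariant_value) && spec$generation == "1N") {
        rep(spec$invariant_value, length(sampling_dates))
      } else {
        gw <- spec$growth_window
        out <- rep(NA_real_, length(sampling_dates))
        inside <- sampling_dates >= gw$start & sampling_dates <= gw$end
        after <- sampling_dates > gw$end
        if (any(inside)) out[inside] <- sugar_at(sampling_dates[inside])
        if (any(after)) out[after] <- sugar_at(gw$end)
        out
      }
    })
  value <- base + spec$offset +
    with_seed(seed, rnorm(length(sampling_dates), sd = spec$noise_sd))
  data.frame(date = sampling_dates, pool = spec$pool_name,
             generation = spec$generation, delta13c = value)
}
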