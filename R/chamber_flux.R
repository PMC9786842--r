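#' A single chamber-closure concentration trace
#'
#' Container for one 65 s closure of a non-airtight shoot chamber: the
#' isotopologue concentrations (12CO2, 13CO2) sampled at 0.5 s by the
#' spectrometer and bulk CO2/H2O sampled at 5 s by the IRGA, together with
#' the chamber geometry, sample flow and ambient conditions at closure.
#'
#' @param closure_id identifier.
#' @param t12,c12,c13 time (s since closure) and concentrations (ppm) of the
#'   0.5 s isotopologue channel; \code{c12}/\code{c13} share \code{t12}.
#' @param t5,co2,h2o time (s) and concentrations (ppm) of the 5 s channel.
#' @param chamber_volume chamber volume, dm3.
#' @param needle_area enclosed needle area, m2 (all-sided).
#' @param sample_flow sample air flow, dm3 min-1 (ambient air leaks in to
#'   compensate).
#' @param ca ambient CO2 before closure, ppm.
#' @param delta13C_air ambient delta13C of CO2, permil.
#' @param T_chamber chamber air temperature, degC.
#' @param RH_chamber chamber relative humidity, percent.
#' @param P_amb air pressure, kPa.
#' @param timestamp optional POSIXct of the closure.
#' @return an object of class \code{"closure_trace"}.
#' @export
closure_trace <- function(closure_id, t12, c12, c13, t5, co2, h2o,
                          chamber_volume, needle_area, sample_flow,
                          ca, delta13C_air, T_chamber, RH_chamber, P_amb,
                          timestamp = NULL) {
  stop_if_not_number(chamber_volume, "chamber_volume", positive = TRUE)
  stop_if_not_number(needle_area, "needle_area", positive = TRUE)
  stop_if_not_number(sample_flow, "sample_flow", positive = TRUE)
  if (is.unsorted(t12, strictly = TRUE) || is.unsorted(t5, strictly = TRUE))
    stop("trace timestamps must be strictly increasing", call. = FALSE)
  if (any(t12 < 0) || any(t12 > 65) || any(t5 < 0) || any(t5 > 65))
    stop("trace times must lie within [0, 65] s", call. = FALSE)
  if (length(t12) != length(c12) || length(t12) != length(c13) ||
      length(t5) != length(co2) || length(t5) != length(h2o))
    stop("trace time and concentration vectors must match in length", call. = FALSE)
  structure(list(closure_id = closure_id, t12 = t12, c12 = c12, c13 = c13,
                 t5 = t5, co2 = co2, h2o = h2o,
                 chamber_volume = chamber_volume, needle_area = needle_area,
                 sample_flow = sample_flow, ca = ca,
                 delta13C_air = delta13C_air, T_chamber = T_chamber,
                 RH_chamber = RH_chamber, P_amb = P_amb,
                 timestamp = timestamp),
            class = "closure_trace")
}

#' Ambient isotopologue concentrations from bulk CO2 and its delta13C
#'
#' Splits a bulk CO2 mole fraction into 12CO2 and 13CO2 using the V-PDB
#' ratio (R_VPDB = 0.0111802).
#'
#' @param ca bulk CO2, ppm.
#' @param delta13C delta13C of that CO2, permil vs V-PDB.
#' @return list with elements \code{c12} and \code{c13}, ppm.
#' @export
ambient_isotopologues <- function(ca, delta13C) {
  R <- R_VPDB * (1 + delta13C / 1000)
  list(c12 = ca / (1 + R), c13 = ca * R / (1 + R))
}

# molar density of air, mol m-3, from pressure (kPa) and temperature (degC)
air_molar_density <- function(P_kPa, T_C) {
  P_kPa * 1000 / (R_GAS * (T_C + 273.15))
}

# ambient concentration of one species of a trace, ppm
trace_ambient <- function(trace, species) {
  iso <- ambient_isotopologues(trace$ca, trace$delta13C_air)
  switch(species,
         c12 = iso$c12,
         c13 = iso$c13,
         co2 = trace$ca,
         h2o = actual_vapor_pressure(trace$T_chamber, trace$RH_chamber) /
           trace$P_amb * 1e6,
         stop("unknown species: ", species, call. = FALSE))
}

#' Fit the closure-curve model and estimate a flux for one species
#'
#' The chamber obeys a first-order dilution mass balance: sampled air (flow
#' q) is replaced by ambient air while the shoot exchanges with the head
#' space, so the concentration follows
#' \deqn{C(t) = C_{eq} + (C_0 - C_{eq}) e^{-(q/V) t}.}
#' The model is fitted by nonlinear least squares (parameters C_eq, C_0 and
#' the rate k, initialised at q/V), over the window 5-50 s for the
#' isotopologue channels and 5-35 s for bulk CO2/H2O.  The flux follows
#' from the fitted equilibrium deficit,
#' \eqn{F = q \rho (C_{amb} - C_{eq}) / S} with the ideal-gas molar density
#' \eqn{\rho = P / (R T_K)}; uptake is positive.
#'
#' @param trace a \code{\link{closure_trace}}.
#' @param species one of \code{"c12"}, \code{"c13"}, \code{"co2"}, \code{"h2o"}.
#' @param calibration optional affine correction applied to the raw
#'   concentrations first, \code{list(intercept=, slope=)}; identity default.
#' @param fit_rate also estimate the rate constant k instead of fixing it
#'   at the chamber turnover q/V; useful as a diagnostic of the chamber
#'   metadata, at the cost of extra variance on short windows.
#' @return list with \code{flux} (umol m-2 s-1, uptake positive),
#'   \code{C_eq}, \code{C0}, \code{k} (s-1), \code{rmse} (ppm),
#'   \code{flat} flag (TRUE when the trace carried no signal and flux 0 was
#'   returned without fitting) and \code{n} points used.
#' @export
fit_closure_flux <- function(trace, species = c("c12", "c13", "co2", "h2o"),
                             calibration = NULL, fit_rate = FALSE) {
  stopifnot(inherits(trace, "closure_trace"))
  species <- match.arg(species)
  if (species %in% c("c12", "c13")) {
    t <- trace$t12; C <- trace[[species]]; win <- c(5, 50)
  } else {
    t <- trace$t5; C <- trace[[species]]; win <- c(5, 35)
  }
  if (!is.null(calibration))
    C <- calibration$intercept + calibration$slope * C
  keep <- t >= win[1] & t <= win[2] & is.finite(C)
  t <- t[keep]; C <- C[keep]
  if (length(t) < 6L)
    stop("fewer than 6 points in the ", win[1], "-", win[2],
         " s fit window", call. = FALSE)
  C_amb <- trace_ambient(trace, species)
  q <- trace$sample_flow / 60 / 1000        # dm3 min-1 -> m3 s-1
  V <- trace$chamber_volume / 1000          # dm3 -> m3
  S <- trace$needle_area
  rho <- air_molar_density(trace$P_amb, trace$T_chamber)
  # degenerate flat trace: no information beyond the ambient level
  if (diff(range(C)) <= 1e-9 * max(1, abs(mean(C)))) {
    warning("flat closure trace for species '", species,
            "'; returning zero flux", call. = FALSE)
    return(list(flux = 0, C_eq = mean(C), C0 = mean(C), k = q / V,
                rmse = 0, flat = TRUE, n = length(t)))
  }
  k0 <- q / V
  # linear pre-fit in the basis {1, exp(-k0 t)} for starting values
  b0 <- exp(-k0 * t)
  pre <- coef(lm(C ~ b0))
  dat <- data.frame(t = t, C = C)
  fit <- tryCatch(
    if (fit_rate)
      minpack.lm::nlsLM(C ~ C_eq + dC * exp(-k * t), data = dat,
                        start = list(C_eq = unname(pre[1]),
                                     dC = unname(pre[2]), k = k0),
                        lower = c(-Inf, -Inf, k0 / 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(C ~ C_eq + dC * exp(-k0 * t), data = dat,
                        start = list(C_eq = unname(pre[1]),
                                     dC = unname(pre[2])),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("closure fit did not converge for species '",
                             species, "': ", conditionMessage(e), call. = FALSE))
  est <- coef(fit)
  C_eq <- unname(est["C_eq"])
  flux <- q * rho * (C_amb - C_eq) / S
  list(flux = flux, C_eq = C_eq, C0 = C_eq + unname(est["dC"]),
       k = if (fit_rate) unname(est["k"]) else k0,
       rmse = sqrt(mean(residuals(fit)^2)),
       flat = FALSE, n = length(t))
}

#' delta13C of the assimilation flux from isotopologue fluxes
#'
#' \eqn{\delta = (F_{13}/F_{12}/R_{VPDB} - 1) \times 1000}, i.e. the delta
#' notation applied to the 13CO2/12CO2 flux ratio against V-PDB.
#'
#' @param F13 13CO2 flux, umol m-2 s-1.
#' @param F12 12CO2 flux, umol m-2 s-1; must be positive.
#' @return delta13C of the flux, permil vs V-PDB.
#' @export
delta13c_from_fluxes <- function(F13, F12) {
  if (any(!is.finite(F12)) || any(F12 <= 0))
    stop("F12 must be positive and finite", call. = FALSE)
  (F13 / F12 / R_VPDB - 1) * 1000
}

#' Fit all four species of a closure and assemble a flux record
#'
#' @param trace a \code{\link{closure_trace}}.
#' @param calibration optional named list of per-species affine corrections
#'   (see \code{\link{fit_closure_flux}}).
#' @return a one-row data.frame (a "flux record") with the isotopologue and
#'   bulk fluxes, delta13C_A_Picarro, QC flags and fit RMSEs.  F_H2O is the
#'   transpiration flux in mmol m-2 s-1 (release positive).
#' @export
fit_closure_fluxes <- function(trace, calibration = NULL) {
  cal <- function(sp) if (is.null(calibration)) NULL else calibration[[sp]]
  f12 <- fit_closure_flux(trace, "c12", cal("c12"))
  f13 <- fit_closure_flux(trace, "c13", cal("c13"))
  fco2 <- fit_closure_flux(trace, "co2", cal("co2"))
  fh2o <- fit_closure_flux(trace, "h2o", cal("h2o"))
  dA <- if (f12$flux > 0) delta13c_from_fluxes(f13$flux, f12$flux) else NA_real_
  data.frame(
    closure_id = trace$closure_id,
    timestamp = if (is.null(trace$timestamp)) as.POSIXct(NA) else trace$timestamp,
    F12 = f12$flux, F13 = f13$flux, F_CO2 = fco2$flux,
    F_H2O = -fh2o$flux / 1000,
    delta13C_A_Picarro = dA,
    RH_chamber = trace$RH_chamber, T_chamber = trace$T_chamber,
    qc_co2_pass = !(fco2$flux < 0.5),
    qc_h2o_pass = !(trace$RH_chamber > 75),
    rmse_c12 = f12$rmse, rmse_c13 = f13$rmse,
    rmse_co2 = fco2$rmse, rmse_h2o = fh2o$rmse)
}

#' Quality-control filter for chamber flux records
#'
#' Nulls delta13C_A_Picarro where the CO2 flux is below the threshold
#' (strictly "lower than", default 0.5 umol m-2 s-1) and nulls the H2O flux
#' where chamber RH strictly exceeds the threshold (default 75 percent).
#' Retained values are never altered.
#'
#' @param records data.frame of flux records (see
#'   \code{\link{fit_closure_fluxes}}).
#' @param co2_min CO2 flux threshold, umol m-2 s-1.
#' @param rh_max RH threshold, percent.
#' @param quiet suppress the removal-count message.
#' @return the records with filtered entries set NA and refreshed
#'   \code{qc_co2_pass}/\code{qc_h2o_pass} flags; counts of removals in
#'   attributes \code{"n_delta_removed"} and \code{"n_h2o_removed"}.
#' @export
qc_filter <- function(records, co2_min = 0.5, rh_max = 75, quiet = FALSE) {
  stopifnot(is.data.frame(records))
  out <- records
  drop_delta <- is.finite(out$F_CO2) & out$F_CO2 < co2_min
  drop_delta[is.na(out$F_CO2)] <- TRUE
  drop_h2o <- out$RH_chamber > rh_max
  out$qc_co2_pass <- !drop_delta
  out$qc_h2o_pass <- !drop_h2o
  out$delta13C_A_Picarro[drop_delta] <- NA_real_
  out$F_H2O[drop_h2o] <- NA_real_
  if (!quiet)
    message(sprintf("qc_filter: removed %d delta13C record(s) (F_CO2 < %g), %d H2O flux record(s) (RH > %g%%)",
                    sum(drop_delta), co2_min, sum(drop_h2o), rh_max))
  attr(out, "n_delta_removed") <- sum(drop_delta)
  attr(out, "n_h2o_removed") <- sum(drop_h2o)
  out
}

#' Daytime window from sunrise and sunset
#'
#' Daytime is defined as 2 h after sunrise to 2 h before sunset; the day
#' must be longer than 4 h.
#'
#' @param sunrise,sunset local hours (numeric, e.g. 4 and 22).
#' @return numeric vector \code{c(start, end)} in hours.
#' @export
daytime_window <- function(sunrise, sunset) {
  if (sunset - sunrise <= 4)
    stop("day length must exceed 4 h for a non-empty daytime window",
         call. = FALSE)
  c(start = sunrise + 2, end = sunset - 2)
}

# decimal hour-of-day of POSIXct timestamps
hour_of_day <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Arithmetic per-day daytime mean of a record series
#'
#' @param timestamp POSIXct record times.
#' @param value values to average.
#' @param sunrise_hour,sunset_hour local hours bounding the solar day.
#' @return data.frame with \code{date}, \code{mean}, \code{n}.
#' @export
daytime_mean <- function(timestamp, value, sunrise_hour = 4, sunset_hour = 22) {
  win <- daytime_window(sunrise_hour, sunset_hour)
  h <- hour_of_day(timestamp)
  inside <- h >= win[1] & h <= win[2] & is.finite(value)
  if (!any(inside)) stop("no records inside the daytime window", call. = FALSE)
  d <- as.Date(timestamp[inside])
  agg <- tapply(value[inside], d, mean)
  data.frame(date = as.Date(names(agg)), mean = as.numeric(agg),
             n = as.integer(tapply(value[inside], d, length)),
             row.names = NULL)
}

#' Flux-weighted per-day daytime mean
#'
#' \eqn{\sum w_i x_i / \sum w_i} over records inside the daytime window,
#' per day.  Records with NA value or weight are skipped; a day whose
#' weights sum to zero yields NA with a warning.
#'
#' @param timestamp POSIXct record times.
#' @param value values (e.g. delta13C), with NAs allowed.
#' @param weight nonnegative weights (e.g. CO2 flux).
#' @param sunrise_hour,sunset_hour local hours bounding the solar day.
#' @return data.frame with \code{date}, \code{mean}, \code{n}.
#' @export
flux_weighted_daytime_mean <- function(timestamp, value, weight,
                                       sunrise_hour = 4, sunset_hour = 22) {
  if (any(weight < 0, na.rm = TRUE))
    stop("weights must be nonnegative", call. = FALSE)
  win <- daytime_window(sunrise_hour, sunset_hour)
  h <- hour_of_day(timestamp)
  inside <- h >= win[1] & h <= win[2] & is.finite(value) & is.finite(weight)
  d_all <- sort(unique(as.Date(timestamp)))
  if (!any(inside)) {
    warning("no weighted records inside the daytime window; all days NA")
    return(data.frame(date = d_all, mean = rep(NA_real_, length(d_all)),
                      n = rep(0L, length(d_all))))
  }
  d <- as.Date(timestamp[inside])
  v <- value[inside]; w <- weight[inside]
  wsum <- tapply(w, d, sum)
  if (any(wsum == 0))
    warning("day(s) with all-zero weights yield NA: ",
            paste(names(wsum)[wsum == 0], collapse = ", "))
  wv <- tapply(w * v, d, sum)
  m <- ifelse(wsum > 0, wv / wsum, NA_real_)
  data.frame(date = as.Date(names(wsum)), mean = as.numeric(m),
             n = as.integer(tapply(v, d, length)), row.names = NULL)
}
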