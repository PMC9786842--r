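#' Fractionation constants of the discrimination model
#'
#' Bundles the fractionation factors of the steady-state photosynthetic
#' carbon isotope discrimination model for C3 leaves.  Defaults are the
#' standard conifer values: stomatal diffusion a = 4.4 permil, carboxylation
#' b = 29 permil, mesophyll transfer a_m = 1.8 permil, photorespiration
#' f = 8 permil (sensitivity option 11), day respiration e = -6 permil, net
#' carboxylation b' = 27 permil for the simple inversion, and a constant
#' mesophyll conductance g_m = 0.127 mol m-2 s-1 expressed per all-sided
#' needle area.  Set \code{g_m = Inf} to drop the mesophyll drawdown term.
#'
#' @param a stomatal diffusion fractionation, permil.
#' @param b carboxylation fractionation, permil.
#' @param a_m mesophyll transfer fractionation, permil.
#' @param f photorespiratory fractionation, permil (8 default, 11 optional).
#' @param e day-respiratory fractionation, permil.
#' @param b_prime net carboxylation fractionation for the simple inversion, permil.
#' @param g_m mesophyll conductance, mol m-2 s-1 (all-sided area); may be Inf.
#' @param R_gas universal gas constant, J mol-1 K-1.
#' @return an object of class \code{"disc_params"}.
#' @export
disc_params <- function(a = 4.4, b = 29, a_m = 1.8, f = 8, e = -6,
                        b_prime = 27, g_m = 0.127, R_gas = R_GAS) {
  if (!(b > a && a > 0)) stop("need b > a > 0", call. = FALSE)
  if (!(is.infinite(g_m) || g_m > 0)) stop("g_m must be > 0 or Inf", call. = FALSE)
  structure(list(a = a, b = b, a_m = a_m, f = f, e = e,
                 b_prime = b_prime, g_m = g_m, R_gas = R_gas),
            class = "disc_params")
}

#' Mitochondrial respiration parameters
#'
#' Temperature-response parameters of dark respiration,
#' \eqn{R_d = R_{d0} \exp[H_\alpha (T_l - 25) / (298 R (T_l + 273.15))]},
#' normally obtained by fitting night-time chamber fluxes with
#' \code{\link{fit_respiration}}.  \code{light_inhibited = TRUE} sets
#' R_d = 0 inside the discrimination model (sensitivity switch).
#'
#' @param R_d0 respiration rate at 25 degC, umol m-2 s-1 (all-sided area).
#' @param H_alpha activation-energy-like parameter, J mol-1.
#' @param light_inhibited logical; if TRUE the model uses R_d = 0 in daylight.
#' @return an object of class \code{"resp_params"}.
#' @export
resp_params <- function(R_d0, H_alpha, light_inhibited = FALSE) {
  stop_if_not_number(R_d0, "R_d0")
  stop_if_not_number(H_alpha, "H_alpha")
  if (R_d0 < 0) stop("R_d0 must be >= 0", call. = FALSE)
  structure(list(R_d0 = R_d0, H_alpha = H_alpha,
                 light_inhibited = isTRUE(light_inhibited)),
            class = "resp_params")
}

#' CO2 compensation point without dark respiration
#'
#' \deqn{\Gamma^* = 42.75 \exp[37830 (T_l - 25) / (298 R (T_l + 273.15))]}
#' in umol mol-1; equals 42.75 at 25 degC and increases with temperature.
#'
#' @param Tl leaf temperature, degrees C (vectorised).
#' @param R_gas universal gas constant, J mol-1 K-1.
#' @return Gamma-star, umol mol-1.
#' @examples
#' gamma_star(25) # 42.75
#' @export
gamma_star <- function(Tl, R_gas = R_GAS) {
  if (any(Tl <= -273.15)) stop("Tl must be above absolute zero", call. = FALSE)
  42.75 * exp(37830 * (Tl - 25) / (298 * R_gas * (Tl + 273.15)))
}

#' Mitochondrial (dark) respiration rate at a given leaf temperature
#'
#' @param Tl leaf temperature, degrees C (vectorised).
#' @param resp a \code{\link{resp_params}} object.
#' @return respiration rate, umol m-2 s-1 (positive efflux).
#' @export
mitochondrial_respiration <- function(Tl, resp) {
  stopifnot(inherits(resp, "resp_params"))
  resp$R_d0 * exp(resp$H_alpha * (Tl - 25) / (298 * R_GAS * (Tl + 273.15)))
}

#' Fit the respiration temperature response to night-time chamber fluxes
#'
#' Nonlinear least squares of efflux = R_d0 * exp(H_alpha * (Tl - 25) /
#' (298 R (Tl + 273.15))) over (R_d0, H_alpha), started from R_d0 = mean
#' efflux and H_alpha = 5e4 J mol-1.
#'
#' @param Tl leaf (chamber air) temperatures of night records, degrees C.
#' @param efflux night-time CO2 efflux, umol m-2 s-1, positive.
#' @return a \code{\link{resp_params}} object with attributes \code{rmse}
#'   and \code{fit} (the nls object).
#' @export
fit_respiration <- function(Tl, efflux) {
  ok <- is.finite(Tl) & is.finite(efflux)
  Tl <- Tl[ok]; efflux <- efflux[ok]
  if (length(Tl) < 5L)
    stop("need at least 5 night-time flux records", call. = FALSE)
  if (diff(range(Tl)) < 5)
    stop("night temperatures must span at least 5 degC (H_alpha unidentifiable)",
         call. = FALSE)
  dat <- data.frame(Tl = Tl, efflux = efflux)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      efflux ~ R_d0 * exp(H_alpha * (Tl - 25) / (298 * R_GAS * (Tl + 273.15))),
      data = dat,
      start = list(R_d0 = mean(efflux), H_alpha = 5e4),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("respiration fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- coef(fit)
  if (est[["R_d0"]] < 0)
    stop("respiration fit returned negative R_d0", call. = FALSE)
  out <- resp_params(est[["R_d0"]], est[["H_alpha"]])
  attr(out, "rmse") <- sqrt(mean(residuals(fit)^2))
  attr(out, "fit") <- fit
  out
}

#' Photosynthetic carbon isotope discrimination (steady-state model)
#'
#' \deqn{\Delta = a + (b - a)\frac{c_i}{c_a} - (b - a_m)\frac{A}{g_m c_a}
#'  - f\frac{\Gamma^*}{c_a} - \frac{R_d}{A + R_d} e \frac{c_i - \Gamma^*}{c_a}}
#' All delta/Delta quantities are carried in permil.  With \code{g_m = Inf}
#' the mesophyll term vanishes; with \code{light_inhibited} respiration the
#' R_d term vanishes.
#'
#' @param A net assimilation rate, umol m-2 s-1 (all-sided area).
#' @param ca ambient CO2 mole fraction, ppm.
#' @param ci intercellular CO2 mole fraction, ppm.
#' @param Tl leaf temperature, degrees C.
#' @param params a \code{\link{disc_params}} object.
#' @param resp a \code{\link{resp_params}} object.
#' @return discrimination Delta, permil (vectorised over the inputs).
#' @export
model_discrimination <- function(A, ca, ci, Tl, params = disc_params(),
                                 resp = resp_params(0, 0)) {
  stopifnot(inherits(params, "disc_params"), inherits(resp, "resp_params"))
  if (any(ca <= 0)) stop("ca must be > 0", call. = FALSE)
  R_d <- if (resp$light_inhibited) 0 * A else mitochondrial_respiration(Tl, resp)
  if (any(A + R_d <= 0))
    stop("model requires A + R_d > 0", call. = FALSE)
  G <- gamma_star(Tl, params$R_gas)
  meso <- if (is.infinite(params$g_m)) 0 else
    (params$b - params$a_m) * A / (params$g_m * ca)
  k <- R_d / (A + R_d)
  params$a + (params$b - params$a) * ci / ca - meso -
    params$f * G / ca - k * params$e * (ci - G) / ca
}

#' Convert discrimination to delta13C of assimilates, and back
#'
#' Forward: \eqn{\delta^{13}C_A = 1000 (\delta^{13}C_{air} - \Delta) /
#' (\Delta + 1000)}.  The inverse solves the same relation for Delta.
#' The round trip is an identity.
#'
#' @param delta13C_air delta13C of ambient CO2, permil vs V-PDB.
#' @param Delta photosynthetic discrimination, permil.
#' @return delta13C of assimilates, permil vs V-PDB.
#' @export
delta_from_discrimination <- function(delta13C_air, Delta) {
  if (any(Delta <= -1000)) stop("Delta must be > -1000 permil", call. = FALSE)
  1000 * (delta13C_air - Delta) / (Delta + 1000)
}

#' @rdname delta_from_discrimination
#' @param deltaA delta13C of assimilates, permil vs V-PDB.
#' @return for the inverse, discrimination Delta in permil.
#' @export
discrimination_from_delta <- function(delta13C_air, deltaA) {
  if (any(deltaA <= -1000)) stop("deltaA must be > -1000 permil", call. = FALSE)
  1000 * (delta13C_air - deltaA) / (1000 + deltaA)
}

#' Daily flux-weighted modeled delta13C of assimilates
#'
#' Runs the discrimination model over a joined gas-exchange/environment
#' record table and aggregates to daily flux-weighted daytime means.  For
#' each record, stomatal conductance and iWUE are derived from A and E
#' (see \code{\link{iwue_gas}}), ci from ci = ca - 1.6 iWUE, Delta from the
#' discrimination model and delta13C_A from the air delta13C.  Records with
#' A <= 0 or E <= 0 are dropped (counted in the \code{"n_dropped"} attribute).
#'
#' @param records data.frame with columns \code{timestamp} (POSIXct),
#'   \code{A} (umol m-2 s-1), \code{E} (mmol m-2 s-1), \code{Tl} (degC),
#'   \code{ca} (ppm), \code{delta13C_air} (permil), \code{es}, \code{ea},
#'   \code{P_amb} (kPa).
#' @param params a \code{\link{disc_params}} object.
#' @param resp a \code{\link{resp_params}} object.
#' @param sunrise_hour,sunset_hour local hours defining the solar day; the
#'   daytime window is sunrise + 2 h to sunset - 2 h.
#' @return data.frame with \code{date}, \code{delta13C_A_model} (permil),
#'   \code{Delta_model} (flux-weighted, permil) and \code{n} records used.
#' @export
model_delta_series <- function(records, params = disc_params(), resp,
                               sunrise_hour = 4, sunset_hour = 22) {
  need <- c("timestamp", "A", "E", "Tl", "ca", "delta13C_air", "es", "ea", "P_amb")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ok <- is.finite(records$A) & records$A > 0 &
    is.finite(records$E) & records$E > 0 & records$es > records$ea
  n_dropped <- sum(!ok)
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) == 0L) {
    warning("no usable daytime records for the discrimination model")
    out <- data.frame(date = as.Date(character()), delta13C_A_model = numeric(),
                      Delta_model = numeric(), n = integer())
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  gw <- iwue_gas(rec$A, rec$E, rec$es, rec$ea, rec$P_amb)
  ci <- rec$ca - 1.6 * gw$iwue
  Delta <- model_discrimination(rec$A, rec$ca, ci, rec$Tl, params, resp)
  deltaA <- delta_from_discrimination(rec$delta13C_air, Delta)
  fw_d <- flux_weighted_daytime_mean(rec$timestamp, deltaA, rec$A,
                                     sunrise_hour, sunset_hour)
  fw_D <- flux_weighted_daytime_mean(rec$timestamp, Delta, rec$A,
                                     sunrise_hour, sunset_hour)
  out <- data.frame(date = fw_d$date, delta13C_A_model = fw_d$mean,
                    Delta_model = fw_D$mean, n = fw_d$n)
  attr(out, "n_dropped") <- n_dropped
  out
}
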