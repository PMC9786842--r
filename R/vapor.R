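#' Saturation vapor pressure of air (Tetens formula)
#'
#' \deqn{e_s = 610.7 \times 10^{7.5 T / (237.3 + T)} / 1000}
#' with \code{T} in degrees Celsius and the result in kPa.
#'
#' @param T air temperature, degrees C (vectorised); must exceed -237.3.
#' @return saturation vapor pressure, kPa.
#' @examples
#' saturation_vapor_pressure(25) # about 3.167 kPa
#' @export
saturation_vapor_pressure <- function(T) {
  if (any(!is.finite(T)) || any(T <= -237.3))
    stop("temperature must be finite and > -237.3 degC", call. = FALSE)
  610.7 * 10^(7.5 * T / (237.3 + T)) / 1000
}

#' Vapor pressure deficit from temperature and relative humidity
#'
#' VPD = es - ea = es * (100 - RH) / 100, in kPa.
#'
#' @param T air temperature, degrees C.
#' @param RH relative humidity, percent, in [0, 100].
#' @return vapor pressure deficit, kPa.
#' @examples
#' vpd(25, 50) # half of es(25)
#' @export
vpd <- function(T, RH) {
  if (any(!is.finite(RH)) || any(RH < 0) || any(RH > 100))
    stop("RH must lie in [0, 100] percent", call. = FALSE)
  saturation_vapor_pressure(T) * (100 - RH) / 100
}

#' Actual vapor pressure of air
#'
#' ea = es * RH / 100, in kPa.
#'
#' @inheritParams vpd
#' @return actual vapor pressure, kPa.
#' @export
actual_vapor_pressure <- function(T, RH) {
  if (any(!is.finite(RH)) || any(RH < 0) || any(RH > 100))
    stop("RH must lie in [0, 100] percent", call. = FALSE)
  saturation_vapor_pressure(T) * RH / 100
}
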