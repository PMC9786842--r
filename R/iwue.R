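#' Intrinsic water-use efficiency from gas exchange
#'
#' Stomatal conductance follows from transpiration and the leaf-to-air
#' vapor pressure gradient, \eqn{g_s = E P_{amb} / (e_s - e_a)}, and
#' iWUE = A / g_s in umol CO2 per mol H2O (ppm).
#'
#' @param A net assimilation, umol m-2 s-1 (all-sided area).
#' @param E transpiration, mmol m-2 s-1.
#' @param es,ea saturated and actual vapor pressure, kPa (es > ea).
#' @param P_amb air pressure, kPa.
#' @return data.frame with \code{gs} (mol m-2 s-1) and \code{iwue} (ppm).
#' @examples
#' iwue_gas(A = 5, E = 1, es = 2, ea = 1, P_amb = 100)
#' @export
iwue_gas <- function(A, E, es, ea, P_amb) {
  if (any(es <= ea)) stop("need es > ea (VPD > 0); gs undefined", call. = FALSE)
  if (any(E <= 0)) stop("E must be > 0", call. = FALSE)
  gs_mmol <- E * P_amb / (es - ea)
  gs <- gs_mmol / 1000
  data.frame(gs = gs, iwue = A / gs)
}

#' iWUE from discrimination: full inversion of the discrimination model
#'
#' Algebraic inverse of the steady-state discrimination model
#' (\code{\link{model_discrimination}}) solved for iWUE = (ca - ci)/1.6:
#' \deqn{iWUE = \frac{c_a}{1.6}\;
#'  \frac{b - \Delta - f\Gamma^*/c_a - (b - a_m) A/(g_m c_a)
#'        + k e \Gamma^*/c_a - k e}{b - a - k e}, \quad k = R_d/(A+R_d).}
#' Composing the forward model with this inverse is an identity to machine
#' precision, which fixes every grouping ambiguity.  Nonphysical results
#' (iWUE < 0 or > ca/1.6) are flagged with a warning, never clipped.
#'
#' @param Delta discrimination, permil (e.g. from a carbon-pool delta13C via
#'   \code{\link{delta_from_pool}}).
#' @param ca ambient CO2, ppm.
#' @param A assimilation rate, umol m-2 s-1.
#' @param Tl leaf temperature, degC.
#' @param params a \code{\link{disc_params}} object.
#' @param resp a \code{\link{resp_params}} object.
#' @return iWUE, ppm (vectorised).
#' @export
iwue_iso_complex <- function(Delta, ca, A, Tl, params = disc_params(), resp) {
  stopifnot(inherits(params, "disc_params"), inherits(resp, "resp_params"))
  R_d <- if (resp$light_inhibited) 0 * A else mitochondrial_respiration(Tl, resp)
  if (any(A + R_d <= 0)) stop("requires A + R_d > 0", call. = FALSE)
  k <- R_d / (A + R_d)
  G <- gamma_star(Tl, params$R_gas)
  meso <- if (is.infinite(params$g_m)) 0 else
    (params$b - params$a_m) * A / (params$g_m * ca)
  denom <- params$b - params$a - k * params$e
  if (any(abs(denom) < 1e-12))
    stop("vanishing denominator b - a - k e", call. = FALSE)
  iwue <- ca / 1.6 *
    (params$b - Delta - params$f * G / ca - meso +
       k * params$e * G / ca - k * params$e) / denom
  bad <- iwue < 0 | iwue > ca / 1.6
  if (any(bad, na.rm = TRUE))
    warning(sum(bad, na.rm = TRUE),
            " nonphysical iWUE value(s) (outside [0, ca/1.6]); not clipped")
  iwue
}

#' iWUE from discrimination: simple inversion without g_m
#'
#' \deqn{iWUE' = c_a (b' - \Delta) / [1.6 (b' - a)]}
#' with the net carboxylation fractionation b' = 27 permil; the exact
#' inverse of the two-term model Delta = a + (b' - a) ci/ca.
#'
#' @param Delta discrimination, permil.
#' @param ca ambient CO2, ppm.
#' @param params a \code{\link{disc_params}} object (uses a and b_prime).
#' @return iWUE, ppm.
#' @export
iwue_iso_simple <- function(Delta, ca, params = disc_params()) {
  if (params$b_prime <= params$a) stop("need b_prime > a", call. = FALSE)
  if (any(Delta > params$b_prime, na.rm = TRUE))
    warning("Delta exceeds b_prime; negative iWUE flagged, not clipped")
  ca * (params$b_prime - Delta) / (1.6 * (params$b_prime - params$a))
}

#' Discrimination implied by the delta13C of a leaf carbon pool
#'
#' Treats the pool delta13C as the delta13C of assimilates and inverts the
#' delta/Delta relation against ambient air delta13C.
#'
#' @param pool_delta delta13C of the pool, permil vs V-PDB.
#' @param delta13C_air delta13C of ambient CO2, permil vs V-PDB.
#' @return discrimination Delta, permil.
#' @export
delta_from_pool <- function(pool_delta, delta13C_air) {
  discrimination_from_delta(delta13C_air, pool_delta)
}

#' Remove the pinitol contribution from WSC delta13C
#'
#' Water-soluble carbohydrates are a two-member mixture of an isotopically
#' near-invariant pinitol pool and a sugar pool carrying the assimilate
#' signal.  Given the pinitol share p and its delta13C, the sugar signal is
#' recovered by mixing inversion:
#' \deqn{\delta_{corr} = (\delta_{WSC} - p\,\delta_{pinitol}) / (1 - p).}
#'
#' @param delta_wsc delta13C of WSC, permil.
#' @param p pinitol share of WSC carbon, fraction in [0, 1); may be a
#'   per-date vector of measured shares or the constant 0.40.
#' @param delta_pinitol delta13C of pinitol, permil (default -31).
#' @return corrected delta13C, permil.
#' @export
correct_wsc_for_pinitol <- function(delta_wsc, p = 0.40, delta_pinitol = -31) {
  if (any(p < 0) || any(p >= 1)) stop("p must lie in [0, 1)", call. = FALSE)
  (delta_wsc - p * delta_pinitol) / (1 - p)
}

#' Documented helper: iWUE offset expected from a CO2 difference
#'
#' Leaf chambers can run at a lower CO2 mole fraction than the ambient air
#' used for isotope-based estimates.  With a sensitivity of iWUE to ca of
#' 0.28 ppm ppm-1, a ca difference of delta_ca translates into an iWUE
#' offset of delta_ca * 0.28 ppm (about 8 ppm for a 30 ppm difference).
#'
#' @param delta_ca CO2 mole fraction difference, ppm.
#' @param sensitivity iWUE sensitivity to ca, ppm ppm-1.
#' @return expected iWUE offset, ppm (unrounded).
#' @export
iwue_ca_offset <- function(delta_ca = 30, sensitivity = 0.28) {
  delta_ca * sensitivity
}

#' Compare isotope-derived and gas-exchange iWUE series
#'
#' Aligns the two daily series by date and reports descriptive agreement
#' statistics: Pearson correlation, the mean offset (iso - gas), and the
#' offsets stratified at a gas-exchange iWUE of 105 ppm (mean and SD in
#' each stratum).  Pure description, no inference.
#'
#' @param iso data.frame with \code{date} and \code{iwue} (isotope-derived).
#' @param gas data.frame with \code{date} and \code{iwue} (gas exchange).
#' @param split stratification threshold on the gas-exchange iWUE, ppm.
#' @return list with \code{n}, \code{r}, \code{p}, \code{mean_offset},
#'   \code{offset_below}, \code{offset_above} (each a c(mean, sd, n)).
#' @export
compare_iwue <- function(iso, gas, split = 105) {
  m <- merge(iso, gas, by = "date", suffixes = c("_iso", "_gas"))
  m <- m[complete.cases(m[, c("iwue_iso", "iwue_gas")]), ]
  if (nrow(m) < 3L) stop("need at least 3 overlapping dates", call. = FALSE)
  ct <- pearson_cor(m$iwue_iso, m$iwue_gas)
  off <- m$iwue_iso - m$iwue_gas
  strat <- function(idx) {
    c(mean = if (any(idx)) mean(off[idx]) else NA_real_,
      sd = if (sum(idx) > 1) sd(off[idx]) else NA_real_,
      n = sum(idx))
  }
  list(n = nrow(m), r = ct$r, p = ct$p, mean_offset = mean(off),
       offset_below = strat(m$iwue_gas < split),
       offset_above = strat(m$iwue_gas >= split),
       split = split)
}
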