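#' Configuration of the full synthetic-season analysis pipeline
#'
#' Bundles every stage's parameters: the season generator, shoot
#' physiology, discrimination constants, the respiration truth used by the
#' generator, chamber geometry, the closure schedule, trace noise, the leaf
#' pool specifications and sampling schedule, QC thresholds, and the
#' carry-over grid.
#'
#' @param season a \code{\link{season_config}}.
#' @param physiology a \code{\link{pine_physiology}}.
#' @param disc a \code{\link{disc_params}}.
#' @param resp the generating \code{\link{resp_params}} (the analysis
#'   refits its own respiration parameters from night closures).
#' @param chamber a \code{\link{chamber_spec}}.
#' @param closure_interval_minutes one chamber closure every this many
#'   minutes.
#' @param trace_noise_sd Gaussian noise on the closure traces, ppm.
#' @param pool_specs list of \code{\link{pool_mixing_spec}} objects; by
#'   default sucrose and WSC in both needle generations plus 1N pinitol.
#' @param sampling_every_days pool sampling interval, days; sampling starts
#'   once the longest grid lag is covered.
#' @param qc list with \code{co2_min} (umol m-2 s-1) and \code{rh_max} (%).
#' @param grid list with \code{n} and \code{lambda} vectors for the
#'   carry-over search.
#' @param carryover_best list with \code{n} and \code{lambda} used when
#'   integrating iWUE_gas for the iso-vs-gas comparison.
#' @param out_dir optional directory; stage CSVs are written there.
#' @param rng_seed master seed; stage seeds are derived from it.
#' @return an object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(season = season_config(),
                            physiology = pine_physiology(),
                            disc = disc_params(),
                            resp = resp_params(0.8, 4e4),
                            chamber = chamber_spec(),
                            closure_interval_minutes = 60,
                            trace_noise_sd = 0,
                            pool_specs = NULL,
                            sampling_every_days = 7,
                            qc = list(co2_min = 0.5, rh_max = 75),
                            grid = list(n = 0:12,
                                        lambda = seq(0.1, 1, by = 0.1)),
                            carryover_best = list(n = 4, lambda = 0.8),
                            out_dir = NULL,
                            rng_seed = 1L) {
  if (qc$co2_min < 0 || qc$rh_max <= 0)
    stop("QC thresholds must be positive", call. = FALSE)
  if (is.null(pool_specs))
    pool_specs <- list(pool_mixing_spec("sucrose", "1N"),
                       pool_mixing_spec("sucrose", "0N"),
                       pool_mixing_spec("WSC", "1N"),
                       pool_mixing_spec("WSC", "0N"),
                       pool_mixing_spec("pinitol", "1N"))
  structure(as.list(environment()), class = "pipeline_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full synthetic-season pipeline
#'
#' Executes simulate -> closure fitting -> QC -> daily chamber-derived
#' delta13C -> respiration refit -> modeled delta13C -> iWUE (gas and
#' isotope inversions) -> carry-over grid search, and returns every stage's
#' table.  Each stage logs record counts to stderr; per-stage errors are
#' re-signalled with the stage name.  With \code{config$out_dir} set, stage
#' CSVs (env, gasex, fluxes, daily delta13C, pools, iwue, surface) are
#' written there.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param quiet suppress stage log messages.
#' @return an object of class \code{"pinedisc_pipeline"}: a list with
#'   \code{env}, \code{truth}, \code{fluxes}, \code{resp_fit},
#'   \code{daily} (date, delta13C_A_Picarro, delta13C_A_model,
#'   delta13C_A_true, iwue_gas), \code{pools}, \code{pools_combined},
#'   \code{iwue} (per-date gas and isotope estimates from sucrose and WSC),
#'   \code{surface} (carry-over grid search vs the modeled series),
#'   \code{comparison} (iso vs carry-over-integrated gas iWUE) and
#'   \code{config}.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  note <- function(...) if (!quiet) message("[pinedisc] ", sprintf(...))
  seed <- cf$rng_seed

  env <- stage_try("simulate", generate_environment(cf$season))
  truth <- stage_try("simulate",
                     generate_gas_exchange(env, cf$physiology, cf$disc,
                                           cf$resp, seed = seed + 1L))
  note("simulate: %d environment records over %d days", nrow(env),
       length(unique(as.Date(env$timestamp))))

  minutes <- as.numeric(format(env$timestamp, "%H")) * 60 +
    as.numeric(format(env$timestamp, "%M"))
  take <- minutes %% cf$closure_interval_minutes == 0
  traces <- stage_try("traces",
    generate_closure_traces(truth[take, ], env[take, ], cf$chamber,
                            noise_sd = cf$trace_noise_sd, seed = seed + 2L))
  note("traces: %d chamber closures", length(traces))

  fluxes <- stage_try("fluxes",
                      do.call(rbind, lapply(traces, fit_closure_fluxes)))
  ei <- env[take, ]
  fluxes$PAR <- ei$PAR
  fluxes$es <- ei$es; fluxes$ea <- ei$ea; fluxes$P_amb <- ei$P_amb
  fluxes$ca <- ei$ca; fluxes$delta13C_air <- ei$delta13C_air

  night <- fluxes$PAR == 0 & fluxes$F_CO2 < 0
  resp_fit <- stage_try("respiration",
                        fit_respiration(fluxes$T_chamber[night],
                                        -fluxes$F_CO2[night]))
  note("respiration: refit from %d night closures (R_d0 = %.3f, H_alpha = %.0f)",
       sum(night), resp_fit$R_d0, resp_fit$H_alpha)

  fluxes <- stage_try("qc",
                      qc_filter(fluxes, cf$qc$co2_min, cf$qc$rh_max,
                                quiet = TRUE))
  note("qc: removed %d delta13C and %d H2O flux records",
       attr(fluxes, "n_delta_removed"), attr(fluxes, "n_h2o_removed"))

  sr <- cf$season$sunrise_hour; ss <- cf$season$sunset_hour
  ok <- fluxes$qc_co2_pass & fluxes$F_CO2 > 0
  picarro <- stage_try("picarro_daily",
    flux_weighted_daytime_mean(fluxes$timestamp[ok],
                               fluxes$delta13C_A_Picarro[ok],
                               fluxes$F_CO2[ok], sr, ss))

  mrec <- data.frame(timestamp = fluxes$timestamp, A = fluxes$F_CO2,
                     E = fluxes$F_H2O, Tl = fluxes$T_chamber,
                     ca = fluxes$ca, delta13C_air = fluxes$delta13C_air,
                     es = fluxes$es, ea = fluxes$ea, P_amb = fluxes$P_amb)
  mrec <- mrec[fluxes$qc_co2_pass & fluxes$qc_h2o_pass &
                 is.finite(mrec$E) & mrec$E > 0 & mrec$A > 0, ]
  empty_daily <- data.frame(date = as.Date(character()), mean = numeric(),
                            n = integer())
  if (nrow(mrec) == 0L)
    warning("no QC-passing daytime records; model and iWUE_gas series empty")
  model <- if (nrow(mrec) == 0L)
    data.frame(date = as.Date(character()), delta13C_A_model = numeric(),
               Delta_model = numeric(), n = integer())
  else stage_try("model",
                 model_delta_series(mrec, cf$disc, resp_fit, sr, ss))

  ti <- truth[take, ]
  okt <- is.finite(ti$deltaA_true) & ti$A > 0
  truth_daily <- stage_try("truth_daily",
    flux_weighted_daytime_mean(ti$timestamp[okt], ti$deltaA_true[okt],
                               ti$A[okt], sr, ss))

  if (nrow(mrec) > 0L) {
    gw <- stage_try("iwue_gas", iwue_gas(mrec$A, mrec$E, mrec$es, mrec$ea,
                                         mrec$P_amb))
    gas_daily <- stage_try("iwue_gas",
      flux_weighted_daytime_mean(mrec$timestamp, gw$iwue, mrec$A, sr, ss))
    tl_daily <- daytime_mean(mrec$timestamp, mrec$Tl, sr, ss)
    a_daily <- flux_weighted_daytime_mean(mrec$timestamp, mrec$A, mrec$A,
                                          sr, ss)
  } else {
    gas_daily <- tl_daily <- a_daily <- empty_daily
  }

  daily <- Reduce(function(a, b) merge(a, b, by = "date", all = TRUE), list(
    setNames(picarro[c("date", "mean")], c("date", "delta13C_A_Picarro")),
    setNames(model[c("date", "delta13C_A_model")],
             c("date", "delta13C_A_model")),
    setNames(truth_daily[c("date", "mean")], c("date", "delta13C_A_true")),
    setNames(gas_daily[c("date", "mean")], c("date", "iwue_gas"))))

  # daily assimilate delta13C with full coverage for the pool generator
  okf <- is.finite(truth$deltaA_true) & truth$A > 0
  deltaA_daily <- stage_try("pools",
    setNames(flux_weighted_daytime_mean(truth$timestamp[okf],
                                        truth$deltaA_true[okf],
                                        truth$A[okf], sr, ss)[c("date", "mean")],
             c("date", "value")))

  n_max <- max(cf$grid$n)
  all_days <- deltaA_daily$date
  sampling_dates <- all_days[seq(n_max + 2, length(all_days),
                                 by = cf$sampling_every_days)]
  pools <- stage_try("pools", do.call(rbind, lapply(
    seq_along(cf$pool_specs), function(i)
      generate_pool_series(deltaA_daily, cf$pool_specs[[i]], sampling_dates,
                           seed = seed + 10L + i))))
  note("pools: %d series x %d sampling dates", length(cf$pool_specs),
       length(sampling_dates))

  pull <- function(pool, gen) {
    s <- pools[pools$pool == pool & pools$generation == gen, ]
    if (nrow(s) == 0) NULL else data.frame(date = s$date, value = s$delta13c)
  }
  combine_if <- function(pool) {
    s0 <- pull(pool, "0N"); s1 <- pull(pool, "1N")
    if (!is.null(s0) && !is.null(s1))
      combine_generations(s0, s1, pool)
    else if (!is.null(s1)) s1 else s0
  }
  pools_combined <- list(sucrose = combine_if("sucrose"),
                         WSC = combine_if("WSC"))

  iwue <- stage_try("iwue", {
    base <- merge(merge(setNames(a_daily[c("date", "mean")], c("date", "A")),
                        setNames(tl_daily[c("date", "mean")], c("date", "Tl")),
                        by = "date"),
                  data.frame(date = all_days, ca = cf$season$ca_ambient,
                             delta13C_air = cf$season$delta13C_air),
                  by = "date")
    invert <- function(series, label) {
      if (is.null(series)) return(NULL)
      m <- merge(series, base, by = "date")
      m <- m[complete.cases(m), ]
      if (nrow(m) == 0L) return(NULL)
      D <- delta_from_pool(m$value, m$delta13C_air)
      data.frame(date = m$date, source_pool = label, delta13c = m$value,
                 Delta = D,
                 iwue_iso_complex = iwue_iso_complex(D, m$ca, m$A, m$Tl,
                                                     cf$disc, resp_fit),
                 iwue_iso_simple = iwue_iso_simple(D, m$ca, cf$disc))
    }
    wsc_corr <- if (!is.null(pools_combined$WSC)) {
      w <- pools_combined$WSC
      data.frame(date = w$date,
                 value = correct_wsc_for_pinitol(w$value))
    } else NULL
    rbind(invert(pools_combined$sucrose, "sucrose"),
          invert(pools_combined$WSC, "WSC"),
          invert(wsc_corr, "WSC_pinitol_corrected"))
  })

  surface <- stage_try("carryover", {
    drv <- model[is.finite(model$delta13C_A_model), ]
    suc <- pools_combined$sucrose
    enough <- !is.null(suc) &&
      sum(suc$date %in% drv$date[drv$date - max(cf$grid$n) >=
                                   min(drv$date)]) >= 8
    if (!enough) {
      note("carryover: fewer than 8 usable sampling dates; surface skipped")
      NULL
    } else
      carryover_grid_search(suc,
                            data.frame(date = drv$date,
                                       value = drv$delta13C_A_model),
                            cf$grid$n, cf$grid$lambda)
  })
  if (!is.null(surface))
    note("carryover: best n = %d d, lambda = %.1f (rho = %.3f)",
         surface$best$n, surface$best$lambda, surface$best$rho)

  comparison <- stage_try("compare", {
    suc <- if (is.null(iwue)) data.frame() else
      iwue[iwue$source_pool == "sucrose", ]
    gas_ok <- daily[is.finite(daily$iwue_gas), c("date", "iwue_gas")]
    if (nrow(suc) >= 3 && nrow(gas_ok) >= 8) {
      gi <- integrate_carryover(gas_ok$date, gas_ok$iwue_gas,
                                cf$carryover_best$n, cf$carryover_best$lambda,
                                at = suc$date[suc$date - cf$carryover_best$n >=
                                                min(gas_ok$date)])
      compare_iwue(data.frame(date = suc$date, iwue = suc$iwue_iso_complex),
                   setNames(gi, c("date", "iwue")))
    } else NULL
  })

  out <- structure(list(env = env, truth = truth, fluxes = fluxes,
                        resp_fit = resp_fit, daily = daily, pools = pools,
                        pools_combined = pools_combined, iwue = iwue,
                        surface = surface, comparison = comparison,
                        config = cf),
                   class = "pinedisc_pipeline")
  if (!is.null(cf$out_dir)) {
    dir.create(cf$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stage_csv(env, file.path(cf$out_dir, "env.csv"))
    write_stage_csv(truth, file.path(cf$out_dir, "gasex.csv"))
    write_stage_csv(fluxes, file.path(cf$out_dir, "fluxes.csv"))
    write_stage_csv(daily, file.path(cf$out_dir, "daily_delta.csv"))
    write_stage_csv(pools, file.path(cf$out_dir, "pools.csv"))
    write_stage_csv(iwue, file.path(cf$out_dir, "iwue.csv"))
    if (!is.null(surface))
      write_stage_csv(surface$surface, file.path(cf$out_dir, "surface.csv"))
    note("wrote stage CSVs to %s", cf$out_dir)
  }
  out
}

#' @export
print.pinedisc_pipeline <- function(x, ...) {
  d <- x$daily
  fin <- function(v) v[is.finite(v)]
  cat("pinedisc pipeline result\n")
  cat(sprintf("  %d days; delta13C_A_Picarro %.1f +/- %.1f permil; model %.1f +/- %.1f permil\n",
              nrow(d), mean(fin(d$delta13C_A_Picarro)),
              sd(fin(d$delta13C_A_Picarro)),
              mean(fin(d$delta13C_A_model)), sd(fin(d$delta13C_A_model))))
  cat(sprintf("  iWUE_gas %.0f +/- %.0f ppm\n", mean(fin(d$iwue_gas)),
              sd(fin(d$iwue_gas))))
  if (!is.null(x$surface))
    cat(sprintf("  carry-over best: n = %d d, lambda = %.1f (rho = %.2f)\n",
                x$surface$best$n, x$surface$best$lambda, x$surface$best$rho))
  if (!is.null(x$comparison))
    cat(sprintf("  sucrose iWUE_iso vs iWUE_gas: r = %.2f, mean offset %.1f ppm\n",
                x$comparison$r, x$comparison$mean_offset))
  invisible(x)
}
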