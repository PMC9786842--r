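#' Carry-over weights for previous-day integration
#'
#' A leaf carbon pool retains a fraction lambda of its carbon from one day
#' to the next, so day t-i contributes with weight proportional to
#' lambda^i over a memory of n days; the weights are normalised to sum
#' to one.  \code{flat = TRUE} gives equal weights instead (a plain
#' (n+1)-day moving average), for sensitivity checks of the geometric
#' reading.
#'
#' @param n memory length, integer days >= 0.
#' @param lambda previous-day weight, in (0, 1].
#' @param flat use flat instead of geometric weights.
#' @return numeric vector of length n + 1 (weight for lags 0..n).
#' @export
carryover_weights <- function(n, lambda, flat = FALSE) {
  if (length(n) != 1L || n < 0 || n != round(n))
    stop("n must be a single integer >= 0", call. = FALSE)
  if (length(lambda) != 1L || lambda <= 0 || lambda > 1)
    stop("lambda must lie in (0, 1]", call. = FALSE)
  w <- if (flat) rep(1, n + 1) else lambda^(0:n)
  w / sum(w)
}

#' Integrate a daily series with a previous-day carry-over
#'
#' \deqn{X^*_t = \sum_{i=0}^{n} \lambda^i X_{t-i} \big/ \sum_{i=0}^{n} \lambda^i}
#' n = 0 is the identity; lambda = 1 is the unweighted (n+1)-day moving
#' average.  The series is indexed by calendar date and every lagged date
#' must be present.
#'
#' @param dates Date vector of the daily driver series.
#' @param values driver values at those dates.
#' @param n memory length, days.
#' @param lambda previous-day weight, in (0, 1].
#' @param at Dates at which to evaluate the integrated series; defaults to
#'   all input dates with full look-back coverage.
#' @param flat use flat weights (see \code{\link{carryover_weights}}).
#' @return data.frame with \code{date} and \code{value}.
#' @export
integrate_carryover <- function(dates, values, n, lambda, at = NULL,
                                flat = FALSE) {
  dates <- as.Date(dates)
  if (length(dates) != length(values))
    stop("dates and values must match in length", call. = FALSE)
  w <- carryover_weights(n, lambda, flat)
  if (is.null(at)) at <- dates[dates - n >= min(dates)]
  at <- as.Date(at)
  out <- numeric(length(at))
  for (j in seq_along(at)) {
    idx <- match(at[j] - (0:n), dates)
    if (anyNA(idx) || anyNA(values[idx]))
      stop("driver series does not cover the ", n,
           "-day look-back window before ", format(at[j]), call. = FALSE)
    out[j] <- sum(w * values[idx])
  }
  data.frame(date = at, value = out)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Rank transform (average ranks for ties) followed by the product-moment
#' correlation of the ranks; two-sided p from the t approximation with
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, length >= 3, no constant input.
#' @return list with \code{rho} (or \code{r}) and \code{p}.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired finite values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  rho <- cor(rank(x), rank(y))
  list(rho = rho, p = cor_t_pvalue(rho, n))
}

#' @rdname spearman_cor
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired finite values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  r <- cor(x, y)
  list(r = r, p = cor_t_pvalue(r, n))
}

cor_t_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Grid search for the carry-over parameters (n, lambda)
#'
#' For every cell of the (n, lambda) grid, integrates the daily driver
#' series with \code{\link{integrate_carryover}}, evaluates it at the pool
#' sampling dates, and correlates it against the pool delta13C series
#' (Spearman by default).  Returns the full correlation surface plus the
#' argmax cell; ties are broken by smaller n, then larger lambda (the most
#' parsimonious memory).  Cells with p < 0.05 carry a significance flag.
#'
#' @param pool data.frame with \code{date} and \code{value} (pool delta13C).
#' @param driver data.frame with \code{date} and \code{value} (daily driver,
#'   e.g. modeled delta13C of assimilates, iWUE_gas, or an environmental
#'   variable).
#' @param n_range integer lags to scan (default 0:12 days).
#' @param lambda_range lambda values to scan (default 0.1 to 1 by 0.1).
#' @param method "spearman" or "pearson".
#' @param flat use flat carry-over weights.
#' @return an object of class \code{"carryover_surface"}: a list with
#'   \code{surface} (long data.frame n, lambda, rho, p, significant),
#'   \code{best} (the argmax row) and \code{method}.
#' @export
carryover_grid_search <- function(pool, driver, n_range = 0:12,
                                  lambda_range = seq(0.1, 1, by = 0.1),
                                  method = c("spearman", "pearson"),
                                  flat = FALSE) {
  method <- match.arg(method)
  pool <- pool[is.finite(pool$value), , drop = FALSE]
  pd <- as.Date(pool$date)
  dd <- as.Date(driver$date)
  n_max <- max(n_range)
  usable <- pd %in% dd[dd - n_max >= min(dd)]
  if (sum(usable) < 8L)
    stop("fewer than 8 pool sampling dates with full driver coverage",
         call. = FALSE)
  pd <- pd[usable]; pv <- pool$value[usable]
  cells <- expand.grid(n = n_range, lambda = lambda_range)
  rho <- p <- numeric(nrow(cells))
  corfun <- if (method == "spearman") spearman_cor else pearson_cor
  # lag matrix: column i + 1 holds the driver value i days before each
  # sampling date, so each grid cell is one weighted row sum
  lagm <- sapply(0:n_max, function(i) driver$value[match(pd - i, dd)])
  if (anyNA(lagm))
    stop("driver series has gaps inside the look-back window", call. = FALSE)
  for (i in seq_len(nrow(cells))) {
    w <- carryover_weights(cells$n[i], cells$lambda[i], flat)
    xt <- as.vector(lagm[, seq_along(w), drop = FALSE] %*% w)
    ct <- corfun(pv, xt)
    rho[i] <- ct[[1]]
    p[i] <- ct$p
  }
  surface <- data.frame(n = cells$n, lambda = cells$lambda,
                        rho = rho, p = p, significant = p < 0.05)
  ord <- order(-surface$rho, surface$n, -surface$lambda)
  structure(list(surface = surface, best = surface[ord[1], ],
                 method = method, n_dates = length(pd)),
            class = "carryover_surface")
}

#' @export
print.carryover_surface <- function(x, ...) {
  cat("Carry-over correlation surface (", x$method, ", ",
      x$n_dates, " sampling dates)\n", sep = "")
  cat(sprintf("best cell: n = %d d, lambda = %.1f, rho = %.3f, p = %.3g\n",
              x$best$n, x$best$lambda, x$best$rho, x$best$p))
  cat(sum(x$surface$significant), "of", nrow(x$surface),
      "cells significant at p < 0.05\n")
  invisible(x)
}

#' Combine the needle-generation series of a leaf carbon pool
#'
#' Sucrose delta13C does not differ between current-year (0N) and one-year-
#' old (1N) needles once 0N mature, so the two series are combined by a
#' simple average on overlapping dates (single-generation dates pass
#' through).  WSC shows a stable 0N-1N offset (default 0.6 permil) which is
#' first subtracted from the 0N series so the combination represents 1N.
#' Starch, pinitol and TOM have unstable generation offsets and are refused
#' unless \code{force = TRUE}.
#'
#' @param series_0N,series_1N data.frames with \code{date} and \code{value}.
#' @param pool_name one of "sucrose", "WSC", "starch", "pinitol", "TOM".
#' @param wsc_offset the 0N-minus-1N WSC offset to subtract, permil.
#' @param force combine a refused pool anyway (plain average, no offset).
#' @return data.frame with \code{date} and \code{value}.
#' @export
combine_generations <- function(series_0N, series_1N, pool_name,
                                wsc_offset = 0.6, force = FALSE) {
  pool_name <- match.arg(pool_name,
                         c("sucrose", "WSC", "starch", "pinitol", "TOM"))
  if (!pool_name %in% c("sucrose", "WSC") && !force)
    stop("generation series of '", pool_name,
         "' have unstable offsets and are not combined (use force = TRUE to override)",
         call. = FALSE)
  s0 <- data.frame(date = as.Date(series_0N$date), v0 = series_0N$value)
  s1 <- data.frame(date = as.Date(series_1N$date), v1 = series_1N$value)
  if (pool_name == "WSC" && !force) s0$v0 <- s0$v0 - wsc_offset
  m <- merge(s0, s1, by = "date", all = TRUE)
  value <- rowMeans(cbind(m$v0, m$v1), na.rm = TRUE)
  value[is.nan(value)] <- NA_real_
  data.frame(date = m$date, value = value)
}
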