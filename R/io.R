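#' Write a pipeline stage table to CSV
#'
#' POSIXct columns are written as ISO-8601 UTC strings
#' (\code{YYYY-MM-DDTHH:MM:SSZ}) and Date columns as \code{YYYY-MM-DD};
#' numeric columns keep full precision.
#'
#' @param x data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_stage_csv <- function(x, path) {
  out <- x
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct"))
      out[[nm]] <- format(out[[nm]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    else if (inherits(out[[nm]], "Date"))
      out[[nm]] <- format(out[[nm]], "%Y-%m-%d")
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline stage table from CSV
#'
#' Validates the presence of required columns (a missing column is a named
#' error; extra columns are preserved) and re-parses \code{timestamp} and
#' \code{date} columns written by \code{\link{write_stage_csv}}.
#'
#' @param path CSV file.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_stage_csv <- function(path, required = character()) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("file '", basename(path), "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if ("timestamp" %in% names(x))
    x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  if ("date" %in% names(x))
    x$date <- as.Date(x$date)
  x
}

# write one closure trace in long CSV form (t_s, species, ppm)
write_trace_csv <- function(trace, path) {
  df <- rbind(
    data.frame(t_s = trace$t12, species = "c12", ppm = trace$c12),
    data.frame(t_s = trace$t12, species = "c13", ppm = trace$c13),
    data.frame(t_s = trace$t5, species = "co2", ppm = trace$co2),
    data.frame(t_s = trace$t5, species = "h2o", ppm = trace$h2o))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
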