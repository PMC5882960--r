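#' Monthly environmental series
#'
#' Calendar-monthly values of one environmental variable (sea surface
#' temperature, heat flux, precipitation, dynamic-topography index, ...).
#' Gaps are allowed and tracked as absent (year, month) keys; they are never
#' interpolated.
#'
#' @param year integer vector of calendar years.
#' @param month integer vector of months, 1-12.
#' @param value numeric values; may contain `NA` (treated as gaps).
#' @param variable variable name, e.g. `"SST"`.
#' @param units unit string, e.g. `"degC"`.
#' @return An object of class `monthly_series`: a data frame with columns
#'   `year`, `month`, `value`, sorted chronologically.
#' @export
monthly_series <- function(year, month, value, variable = "", units = "") {
  year <- as.integer(year)
  month <- as.integer(month)
  value <- as.numeric(value)
  stopifnot(length(year) == length(month), length(month) == length(value))
  if (any(month < 1L | month > 12L))
    stop("month outside 1-12")
  key <- year * 12L + month
  if (anyDuplicated(key))
    stop("duplicate (year, month) entries")
  ord <- order(key)
  keep <- !is.na(value[ord])
  df <- data.frame(year = year[ord][keep], month = month[ord][keep],
                   value = value[ord][keep])
  structure(df, class = c("monthly_series", "data.frame"),
            variable = variable, units = units)
}

#' @export
print.monthly_series <- function(x, ...) {
  n_gap <- monthly_gaps(x)
  cat(sprintf("<monthly_series> %s: %d monthly values, %d-%02d to %d-%02d, %d gap(s)\n",
              if (nzchar(attr(x, "variable"))) attr(x, "variable") else "(unnamed)",
              nrow(x), x$year[1], x$month[1],
              x$year[nrow(x)], x$month[nrow(x)], n_gap))
  invisible(x)
}

#' Count of interior gap months in a monthly series
#' @param series a `monthly_series`.
#' @return integer number of missing months between the first and last entry.
#' @export
monthly_gaps <- function(series) {
  key <- series$year * 12L + series$month
  as.integer(max(key) - min(key) + 1L - length(key))
}

#' Look up monthly values by (year, month)
#'
#' @param series a `monthly_series`.
#' @param year,month equal-length integer vectors.
#' @return numeric vector of values, `NA` where the month is a gap.
#' @export
monthly_lookup <- function(series, year, month) {
  key <- series$year * 12L + series$month
  series$value[match(year * 12L + month, key)]
}
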