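#' Annual growth-increment series
#'
#' An `increment_series` holds one specimen's crossdated annual increment
#' widths, stored oldest to youngest (even though measurement in the lab
#' proceeds from the shell margin toward the umbo) and anchored to the
#' calendar year of the first measured increment.
#'
#' @param specimen_id character scalar, at most 8 characters so the series
#'   can round-trip through the Tucson (RWL) decadal format.
#' @param first_year calendar year of the first (oldest) measured increment.
#' @param widths numeric vector of increment widths in mm; all values must be
#'   strictly positive and finite.
#' @return An object of class `increment_series`.
#' @export
increment_series <- function(specimen_id, first_year, widths) {
  specimen_id <- as.character(specimen_id)
  stopifnot(length(specimen_id) == 1L, nchar(specimen_id) >= 1L)
  if (nchar(specimen_id) > 8L)
    stop("specimen_id must be at most 8 characters: ", specimen_id)
  first_year <- as.integer(first_year)
  widths <- as.numeric(widths)
  if (length(widths) < 1L) stop("widths must be non-empty")
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("widths must be strictly positive and finite")
  structure(list(specimen_id = specimen_id,
                 first_year = first_year,
                 widths = widths),
            class = "increment_series")
}

#' Dimensionless detrended growth-index series
#'
#' @param specimen_id character scalar.
#' @param first_year calendar year of the first index value.
#' @param indices numeric vector of dimensionless growth indices.
#' @param mode `"ratio"` (observed / fitted, unit mean) or `"residual"`
#'   (observed - fitted in transformed space, zero mean).
#' @param power_exponent exponent of the power transform applied before
#'   detrending; 1 means no transform, 0 means log.
#' @return An object of class `detrended_series`.
#' @export
detrended_series <- function(specimen_id, first_year, indices,
                             mode = c("ratio", "residual"),
                             power_exponent = 1) {
  mode <- match.arg(mode)
  indices <- as.numeric(indices)
  if (any(!is.finite(indices))) stop("indices must be finite")
  if (mode == "ratio" && any(indices <= 0))
    stop("ratio-mode indices must be strictly positive")
  structure(list(specimen_id = as.character(specimen_id),
                 first_year = as.integer(first_year),
                 indices = indices,
                 mode = mode,
                 power_exponent = power_exponent),
            class = "detrended_series")
}

#' Collection of series
#'
#' Bundles `increment_series` (or `detrended_series`) objects, enforcing
#' unique specimen ids. Individual studies are subsettable with `[`.
#'
#' @param series list of `increment_series` or `detrended_series` objects.
#' @return An object of class `series_collection`.
#' @export
series_collection <- function(series) {
  if (!is.list(series)) series <- list(series)
  ids <- vapply(series, `[[`, character(1), "specimen_id")
  if (anyDuplicated(ids))
    stop("duplicate specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(series) <- ids
  structure(series, class = "series_collection")
}

#' @export
`[.series_collection` <- function(x, i) {
  series_collection(unclass(x)[i])
}

series_values <- function(s) {
  if (!is.null(s$widths)) s$widths else s$indices
}

#' Calendar years covered by a series
#' @param s an `increment_series` or `detrended_series`.
#' @return integer vector of calendar years, oldest first.
#' @export
series_years <- function(s) {
  s$first_year + seq_along(series_values(s)) - 1L
}

#' Calendar span of a collection
#' @param collection a `series_collection`.
#' @return integer vector `c(first, last)` over all members.
#' @export
collection_span <- function(collection) {
  first <- min(vapply(collection, `[[`, integer(1), "first_year"))
  last <- max(vapply(collection, function(s) max(series_years(s)), integer(1)))
  c(first, last)
}

#' Year-by-series matrix view of a collection
#'
#' The workhorse layout for crossdating statistics: rows are consecutive
#' calendar years over the collection span, columns are specimens, cells are
#' widths or indices, `NA` where a specimen does not cover a year.
#'
#' @param collection a `series_collection`.
#' @return numeric matrix with year rownames and specimen-id colnames.
#' @export
as_year_matrix <- function(collection) {
  span <- collection_span(collection)
  years <- span[1]:span[2]
  m <- matrix(NA_real_, nrow = length(years), ncol = length(collection),
              dimnames = list(years, names(collection)))
  for (s in collection) {
    m[as.character(series_years(s)), s$specimen_id] <- series_values(s)
  }
  m
}

#' @export
print.increment_series <- function(x, ...) {
  yrs <- series_years(x)
  cat(sprintf("<increment_series> %s: %d increments, %d-%d, mean width %.3f mm\n",
              x$specimen_id, length(x$widths), min(yrs), max(yrs),
              mean(x$widths)))
  invisible(x)
}

#' @export
print.detrended_series <- function(x, ...) {
  yrs <- series_years(x)
  cat(sprintf("<detrended_series> %s: %d indices (%s mode, power %.2f), %d-%d\n",
              x$specimen_id, length(x$indices), x$mode, x$power_exponent,
              min(yrs), max(yrs)))
  invisible(x)
}

#' @export
print.series_collection <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<series_collection> empty\n")
    return(invisible(x))
  }
  span <- collection_span(x)
  cat(sprintf("<series_collection> %d series spanning %d-%d\n",
              length(x), span[1], span[2]))
  invisible(x)
}
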