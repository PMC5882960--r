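#' Read a Tucson (RWL) decadal ring-width file
#'
#' Parses the decadal layout used by COFECHA/ARSTAN-era tooling: each line
#' carries a series id (columns 1-8), the calendar year of the line's first
#' value, and up to ten integer widths per decade. Two stop-marker dialects
#' are supported: `999` terminating a series stored in 0.01 mm units, and
#' `-9999` terminating a series stored in 0.001 mm units. Stop markers are
#' not data.
#'
#' @param path path to an RWL file.
#' @param dialect `"auto"` (detect from the stop marker), `"precision_0.01mm"`
#'   or `"precision_0.001mm"`.
#' @return A `series_collection` with widths in mm.
#' @export
read_rwl <- function(path, dialect = c("auto", "precision_0.01mm",
                                       "precision_0.001mm")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(series_collection(list()))

  parsed <- lapply(lines, function(ln) {
    id <- trimws(substr(ln, 1L, 8L))
    rest <- strsplit(trimws(substr(ln, 9L, nchar(ln))), "\\s+")[[1]]
    if (length(rest) < 2L) stop("malformed RWL line: ", ln)
    year <- suppressWarnings(as.integer(rest[1]))
    if (is.na(year)) stop("malformed RWL year field in line: ", ln)
    list(id = id, year = year, tokens = rest[-1])
  })

  if (dialect == "auto") {
    all_tokens <- unlist(lapply(parsed, `[[`, "tokens"))
    dialect <- if (any(all_tokens == "-9999")) "precision_0.001mm"
               else "precision_0.01mm"
  }
  scale <- if (dialect == "precision_0.01mm") 100 else 1000
  marker <- if (dialect == "precision_0.01mm") "999" else "-9999"

  out <- list()
  state <- new.env(parent = emptyenv())   # per-id: first_year, next_year, vals, done
  for (p in parsed) {
    st <- state[[p$id]]
    if (is.null(st)) {
      st <- list(first_year = p$year, next_year = p$year,
                 vals = numeric(0), done = FALSE)
    } else {
      if (st$done)
        stop("overlapping duplicate series id in RWL file: ", p$id)
      if (p$year != st$next_year)
        stop("non-monotone or gapped decades for series ", p$id,
             ": expected ", st$next_year, ", got ", p$year)
    }
    for (tok in p$tokens) {
      if (tok == marker) { st$done <- TRUE; break }
      v <- suppressWarnings(as.numeric(tok))
      if (is.na(v)) stop("non-numeric width token '", tok,
                         "' for series ", p$id)
      st$vals <- c(st$vals, v / scale)
    }
    st$next_year <- st$first_year + length(st$vals)
    state[[p$id]] <- st
  }
  ids <- vapply(parsed, `[[`, character(1), "id")
  for (id in unique(ids)) {
    st <- state[[id]]
    out[[id]] <- increment_series(id, st$first_year, st$vals)
  }
  series_collection(out)
}

#' Write a collection to a Tucson (RWL) decadal file
#'
#' Inverse of [read_rwl()]: ids are space-padded to 8 characters, rows are
#' decade-aligned, widths are scaled to the dialect's integer units and the
#' dialect's stop marker terminates each series. Round-trips with
#' [read_rwl()] value-exactly at the dialect precision.
#'
#' @param collection a `series_collection` of `increment_series`.
#' @param path output path.
#' @param dialect `"precision_0.01mm"` (marker 999) or `"precision_0.001mm"`
#'   (marker -9999).
#' @return `path`, invisibly.
#' @export
write_rwl <- function(collection, path,
                      dialect = c("precision_0.01mm", "precision_0.001mm")) {
  dialect <- match.arg(dialect)
  scale <- if (dialect == "precision_0.01mm") 100 else 1000
  marker <- if (dialect == "precision_0.01mm") 999L else -9999L
  lines <- character(0)
  for (s in collection) {
    if (nchar(s$specimen_id) > 8L)
      stop("specimen id longer than 8 characters: ", s$specimen_id)
    vals <- as.integer(round(s$widths * scale))
    if (any(vals <= 0L))
      stop("width not representable at dialect precision for series ",
           s$specimen_id)
    if (any(nchar(as.character(vals)) > 5L))
      stop("width exceeds RWL field width after scaling for series ",
           s$specimen_id)
    cells <- c(as.character(vals), as.character(marker))
    years <- s$first_year + seq_along(cells) - 1L   # marker occupies next slot
    row_start <- 1L
    while (row_start <= length(cells)) {
      y0 <- years[row_start]
      row_end <- min(length(cells), row_start + (9L - y0 %% 10L))
      lines <- c(lines, paste0(
        formatC(s$specimen_id, width = -8L),
        formatC(y0, width = 4L),
        paste0(formatC(cells[row_start:row_end], width = 6L), collapse = "")))
      row_start <- row_end + 1L
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a (year, month, value) monthly table
#'
#' @param path CSV file with header columns `year`, `month`, `value`.
#' @param variable,units optional metadata attached to the result.
#' @return A `monthly_series`; gap months are recorded as missing, never
#'   interpolated.
#' @export
read_monthly_table <- function(path, variable = "", units = "") {
  df <- utils::read.csv(path)
  need <- c("year", "month", "value")
  if (!all(need %in% names(df)))
    stop("monthly table must have columns year, month, value")
  monthly_series(df$year, df$month, df$value,
                 variable = variable, units = units)
}

#' Write a monthly series as a (year, month, value) CSV
#' @param series a `monthly_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_monthly_table <- function(series, path) {
  utils::write.csv(as.data.frame(series)[c("year", "month", "value")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a chronology as a tabular CSV
#'
#' One row per retained year with columns `year`, `index`, `sample_depth`,
#' `running_eps` (the expressed-population-signal status of the year,
#' taken from its covering running window; `NA` where no window is defined)
#' and `provisional` (TRUE for years before the truncation year).
#' Sample depth is not required to be monotone backward in time: staggered
#' specimen lifespans are allowed.
#'
#' @param chronology a `chronology` object.
#' @param path output path.
#' @param retained_only drop years before the truncation year (default TRUE).
#' @return `path`, invisibly.
#' @export
write_chronology_table <- function(chronology, path, retained_only = TRUE) {
  df <- as.data.frame(chronology)
  if (retained_only && !is.na(chronology$truncation_year))
    df <- df[df$year >= chronology$truncation_year, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read back a chronology table written by [write_chronology_table()]
#' @param path CSV path.
#' @return data frame with columns `year`, `index`, `sample_depth`,
#'   `running_eps`.
#' @export
read_chronology_table <- function(path) {
  utils::read.csv(path)
}
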