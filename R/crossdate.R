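#' Mean sensitivity of a series
#'
#' The classic index of year-to-year variability: the mean absolute
#' difference between successive values scaled by their mean,
#' `MS = mean(|2 (x[t+1] - x[t]) / (x[t+1] + x[t])|)`. Scale-invariant and
#' bounded by 2 for positive series.
#'
#' @param series an `increment_series`, `detrended_series`, or numeric vector
#'   of length at least 2.
#' @return Mean sensitivity in `[0, 2]`.
#' @export
mean_sensitivity <- function(series) {
  x <- if (is.numeric(series)) series else series_values(series)
  if (length(x) < 2L) stop("mean sensitivity needs at least 2 values")
  s <- x[-1] + x[-length(x)]
  if (any(s == 0)) stop("adjacent pair sums to zero; mean sensitivity undefined")
  mean(abs(2 * diff(x) / s))
}

#' Lag-1 sample autocorrelation
#'
#' Mean-centered first-order autocorrelation with the biased (n) denominator,
#' as used in chronology descriptive statistics.
#'
#' @param series numeric vector or series object, length at least 10.
#' @return Autocorrelation in `[-1, 1]`.
#' @export
first_order_autocorrelation <- function(series) {
  x <- if (is.numeric(series)) series else series_values(series)
  n <- length(x)
  if (n < 10L) stop("lag-1 autocorrelation needs at least 10 values")
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den == 0) stop("zero variance; autocorrelation undefined")
  sum(xc[-n] * xc[-1]) / den
}

# leave-one-out master values by calendar year: arithmetic mean of all
# other series' indices (COFECHA convention)
loo_master <- function(m, i) {
  others <- m[, -i, drop = FALSE]
  out <- rowMeans(others, na.rm = TRUE)
  out[rowSums(!is.na(others)) == 0L] <- NA_real_
  out
}

#' Interseries correlation against the leave-one-out mean
#'
#' Each detrended series is correlated (Pearson, over its common years) with
#' the arithmetic mean of all other detrended series; the overall series
#' intercorrelation is the mean of the per-series values. Series with fewer
#' than `min_overlap` common years are reported as `NA` and excluded from
#' the overall mean with a warning.
#'
#' @param detrended a `series_collection` of `detrended_series` (>= 3).
#' @param min_overlap minimum common years for a series to be computable.
#' @return List with `overall` (mean r) and `per_series` (named vector).
#' @export
interseries_correlation <- function(detrended, min_overlap = 10) {
  if (length(detrended) < 3L)
    stop("interseries correlation needs at least 3 series")
  m <- as_year_matrix(detrended)
  r <- vapply(seq_len(ncol(m)), function(i) {
    master <- loo_master(m, i)
    ok <- !is.na(m[, i]) & !is.na(master)
    if (sum(ok) < min_overlap) return(NA_real_)
    stats::cor(m[ok, i], master[ok])
  }, numeric(1))
  names(r) <- colnames(m)
  if (anyNA(r))
    warning("series with insufficient overlap excluded from overall mean: ",
            paste(names(r)[is.na(r)], collapse = ", "))
  list(overall = mean(r, na.rm = TRUE), per_series = r)
}

# one-tailed p-value for r > 0 via the t-approximation with n - 2 df
r_pvalue_onetail <- function(r, n) {
  if (n < 3L || is.na(r)) return(NA_real_)
  r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
  t <- r * sqrt((n - 2) / (1 - r^2))
  stats::pt(t, df = n - 2, lower.tail = FALSE)
}

#' Best dating lag against a master series
#'
#' Slides the series against the leave-one-out master over lags in
#' `[-max_lag, max_lag]` and reports the lag maximizing the Pearson
#' correlation; a lag of `L` means the series matches the master dated `L`
#' years later (so an undetected inserted increment shows up as `+1`, a
#' missed increment as `-1`). Ties break toward 0, then toward the negative
#' lag.
#'
#' @param series a `detrended_series` (or any series object).
#' @param master a year-aligned master: a series object, or a numeric vector
#'   named by calendar year.
#' @param max_lag maximum absolute lag tested.
#' @param min_overlap minimum overlap (years) required at every tested lag.
#' @return List with `lag` and `r_at_lag`.
#' @export
best_lag <- function(series, master, max_lag = 5, min_overlap = 10) {
  sy <- series_years(series)
  sv <- series_values(series)
  if (is.numeric(master) && !is.null(names(master))) {
    my <- as.integer(names(master)); mv <- as.numeric(master)
  } else {
    my <- series_years(master); mv <- series_values(master)
  }
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(L) {
    idx <- match(sy + L, my)
    ok <- !is.na(idx) & !is.na(sv)
    ok[ok] <- !is.na(mv[idx[ok]])
    if (sum(ok) < min_overlap) return(NA_real_)
    stats::cor(sv[ok], mv[idx[ok]])
  }, numeric(1))
  if (all(is.na(r))) stop("insufficient overlap at every tested lag")
  # tie-break: highest r, then smallest |lag|, then negative before positive
  ord <- order(-r, abs(lags), lags, na.last = TRUE)
  best <- ord[1]
  list(lag = lags[best], r_at_lag = r[best])
}

#' Segment-wise crossdating flags
#'
#' COFECHA-style dating verification: each detrended series is cut into
#' segments of `seg_len` years lagged by `seg_len - overlap` and each
#' segment is correlated with the leave-one-out mean of the other series.
#' Two kinds of segments are flagged, mirroring COFECHA's B and A flags:
#' segments whose correlation fails a one-tailed significance test at
#' `alpha` (`flag = "low_correlation"`), and segments that correlate higher
#' (by more than `lag_margin`) at a shifted dating position
#' (`flag = "better_lag"`). Every flag reports the
#' lag that best realigns the segment. A short tail segment is evaluated
#' when at least 15 years long (or the full segment length if smaller),
#' otherwise skipped.
#'
#' @param detrended a `series_collection` of `detrended_series`.
#' @param seg_len segment length in years (>= 10).
#' @param overlap overlap between successive segments.
#' @param alpha one-tailed significance level; a segment is flagged when its
#'   p-value is >= `alpha`.
#' @param max_lag maximum alternative-dating lag examined.
#' @param lag_margin minimum correlation improvement for a `better_lag`
#'   flag; 0 is COFECHA's convention (flag whenever another position is
#'   strictly higher; ties prefer the dated position).
#' @return Data frame of flags: `specimen_id`, `start_year`, `end_year`,
#'   `r`, `p`, `best_lag`, `r_at_best_lag`, `flag`.
#' @export
segment_flags <- function(detrended, seg_len = 30, overlap = 15,
                          alpha = 0.01, max_lag = 5, lag_margin = 0) {
  if (seg_len < 10L) stop("seg_len must be at least 10")
  if (overlap >= seg_len) stop("overlap must be smaller than seg_len")
  m <- as_year_matrix(detrended)
  years <- as.integer(rownames(m))
  min_tail <- min(15L, seg_len)
  flags <- list()
  for (i in seq_len(ncol(m))) {
    master <- loo_master(m, i)
    s <- detrended[[i]]
    sy <- series_years(s)
    starts <- seq(min(sy), max(sy), by = seg_len - overlap)
    for (st in starts) {
      en <- min(st + seg_len - 1L, max(sy))
      if (en - st + 1L < seg_len && en - st + 1L < min_tail) next
      rows <- which(years >= st & years <= en)
      ok <- !is.na(m[rows, i]) & !is.na(master[rows])
      n <- sum(ok)
      if (n < 5L) next
      r <- stats::cor(m[rows, i][ok], master[rows][ok])
      p <- r_pvalue_onetail(r, n)
      if (is.na(p)) next
      present <- !is.na(m[rows, i])
      seg <- detrended_series(s$specimen_id, years[rows][present][1],
                              m[rows, i][present], mode = s$mode)
      bl <- tryCatch(best_lag(seg, stats::setNames(master, years),
                              max_lag = max_lag),
                     error = function(e) list(lag = NA_integer_,
                                              r_at_lag = NA_real_))
      type <- if (p >= alpha) {
        "low_correlation"
      } else if (!is.na(bl$lag) && bl$lag != 0L &&
                 bl$r_at_lag > r + lag_margin) {
        "better_lag"
      } else NA_character_
      if (!is.na(type)) {
        flags[[length(flags) + 1L]] <- data.frame(
          specimen_id = s$specimen_id, start_year = st, end_year = en,
          r = r, p = p, best_lag = bl$lag, r_at_best_lag = bl$r_at_lag,
          flag = type)
      }
    }
  }
  if (length(flags) == 0L)
    return(data.frame(specimen_id = character(0), start_year = integer(0),
                      end_year = integer(0), r = numeric(0), p = numeric(0),
                      best_lag = integer(0), r_at_best_lag = numeric(0),
                      flag = character(0)))
  do.call(rbind, flags)
}

#' COFECHA-style quality-control report
#'
#' Runs the full crossdating verification on a collection of raw increment
#' series: spline-ratio detrending at the given cutoff, per-series
#' leave-one-out correlations, mean sensitivity and lag-1 autocorrelation of
#' the raw widths, and segment flags.
#'
#' @param collection a `series_collection` of `increment_series`.
#' @param cutoff_years spline 50% frequency cutoff for the QC detrending.
#' @param seg_len,seg_overlap,alpha segment-flagging settings, see
#'   [segment_flags()].
#' @return An object of class `qc_report`: list with `per_series` (data
#'   frame), `flags` (data frame) and `overall` (list with
#'   `series_intercorrelation`, `average_mean_sensitivity`,
#'   `mean_segment_length`).
#' @export
qc_report <- function(collection, cutoff_years = 15, seg_len = 30,
                      seg_overlap = 15, alpha = 0.01) {
  detrended <- standardize_collection(collection, "spline_ratio",
                                      cutoff_years = cutoff_years)
  ic <- interseries_correlation(detrended)
  per <- data.frame(
    specimen_id = names(collection),
    leave_one_out_r = unname(ic$per_series[names(collection)]),
    mean_sensitivity = vapply(collection, mean_sensitivity, numeric(1)),
    lag1_autocorr = vapply(collection, function(s)
      tryCatch(first_order_autocorrelation(s), error = function(e) NA_real_),
      numeric(1)),
    n_years = vapply(collection, function(s) length(s$widths), integer(1)),
    row.names = NULL)
  flags <- segment_flags(detrended, seg_len = seg_len, overlap = seg_overlap,
                         alpha = alpha)
  structure(list(
    per_series = per,
    flags = flags,
    overall = list(
      series_intercorrelation = ic$overall,
      average_mean_sensitivity = mean(per$mean_sensitivity),
      mean_segment_length = mean(per$n_years))),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %d series\n",
                     "  series intercorrelation: %.3f\n",
                     "  average mean sensitivity: %.3f\n",
                     "  mean segment length: %.1f yr\n",
                     "  flagged segments: %d\n"),
              nrow(x$per_series), x$overall$series_intercorrelation,
              x$overall$average_mean_sensitivity,
              x$overall$mean_segment_length, nrow(x$flags)))
  invisible(x)
}

#' Write a QC report to CSV files
#' @param report a `qc_report`.
#' @param per_series_path,flags_path output CSV paths (either may be NULL).
#' @return invisibly, the report.
#' @export
write_qc_report <- function(report, per_series_path = NULL,
                            flags_path = NULL) {
  if (!is.null(per_series_path))
    utils::write.csv(report$per_series, per_series_path, row.names = FALSE)
  if (!is.null(flags_path))
    utils::write.csv(report$flags, flags_path, row.names = FALSE)
  invisible(report)
}
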