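#' Tukey biweight robust mean
#'
#' The robust location estimate used for chronology averaging: weights
#' `(1 - u^2)^2` for `|u| < 1` with `u = (x - M) / (c S)`, `S` the median
#' absolute deviation, iterated from the median.
#'
#' @param x numeric vector (NAs removed).
#' @param c biweight tuning constant; 9 is the chronology convention.
#' @param max_iter maximum reweighting iterations.
#' @return The biweight mean; the median when the spread degenerates.
#' @export
tukey_biweight <- function(x, c = 9, max_iter = 10) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (length(x) <= 2L) return(mean(x))
  M <- stats::median(x)
  for (it in seq_len(max_iter)) {
    S <- stats::median(abs(x - M))
    if (S == 0) return(M)
    u <- (x - M) / (c * S)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(M)
    M_new <- sum(w * x) / sum(w)
    if (abs(M_new - M) < 1e-12) { M <- M_new; break }
    M <- M_new
  }
  M
}

#' Chronology object
#'
#' Yearly mean growth index with sample depth, interseries statistics, and
#' (after [running_eps()] / [truncate_chronology()]) signal-strength and
#' truncation metadata. The constructor is exported so engineered fixtures
#' and externally computed chronologies can be represented directly.
#'
#' @param years integer vector of consecutive calendar years.
#' @param index yearly growth index (dimensionless, mean ~ 1).
#' @param sample_depth yearly count of contributing series.
#' @param rbar whole-period mean pairwise interseries correlation.
#' @param running_eps data frame from [running_eps()], or NULL.
#' @param truncation_year first statistically robust year, or NA.
#' @param averaging `"biweight"` or `"mean"`.
#' @return An object of class `chronology`.
#' @export
chronology <- function(years, index, sample_depth, rbar = NA_real_,
                       running_eps = NULL, truncation_year = NA_integer_,
                       averaging = "biweight") {
  years <- as.integer(years)
  stopifnot(length(years) == length(index),
            length(years) == length(sample_depth),
            all(diff(years) == 1L))
  if (any(sample_depth < 1L))
    stop("every chronology year must have sample depth >= 1")
  structure(list(years = years, index = as.numeric(index),
                 sample_depth = as.integer(sample_depth), rbar = rbar,
                 running_eps = running_eps,
                 truncation_year = as.integer(truncation_year),
                 averaging = averaging),
            class = "chronology")
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("<chronology> %d-%d (%s averaging), max depth %d, rbar %.3f\n",
              min(x$years), max(x$years), x$averaging, max(x$sample_depth),
              x$rbar))
  if (!is.na(x$truncation_year))
    cat(sprintf("  robust from %d\n", x$truncation_year))
  invisible(x)
}

#' @export
as.data.frame.chronology <- function(x, ...) {
  prov <- if (!is.null(x$provisional)) x$provisional
          else rep(FALSE, length(x$years))
  data.frame(year = x$years, index = x$index,
             sample_depth = x$sample_depth,
             running_eps = chronology_year_eps(x),
             provisional = prov)
}

# whole-period mean pairwise Pearson correlation over pairs with >= minimum
# common years
pairwise_rbar <- function(m, min_overlap = 10) {
  k <- ncol(m)
  rs <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    if (sum(ok) >= min_overlap) rs <- c(rs, stats::cor(m[ok, i], m[ok, j]))
  }
  if (length(rs) == 0L) return(NA_real_)
  mean(rs)
}

#' Average detrended series into a chronology
#'
#' Residual-mode indices are first recentred to mean 1 per series so the
#' chronology is a dimensionless index; yearly values are then the Tukey
#' biweight robust mean (c = 9) or arithmetic mean of the indices available
#' that year, with sample depth recorded.
#'
#' @param detrended a `series_collection` of `detrended_series` (>= 2).
#' @param averaging `"biweight"` (default, the ARSTAN-style convention) or
#'   `"mean"`.
#' @return A `chronology` (without running EPS or truncation; see
#'   [running_eps()] and [truncate_chronology()]).
#' @export
build_chronology <- function(detrended, averaging = c("biweight", "mean")) {
  averaging <- match.arg(averaging)
  if (length(detrended) < 2L) stop("chronology needs at least 2 series")
  rescaled <- lapply(detrended, function(s) {
    if (!is.null(s$mode) && s$mode == "residual") {
      s$indices <- s$indices - mean(s$indices) + 1
    }
    s
  })
  m <- as_year_matrix(series_collection(rescaled))
  idx <- apply(m, 1L, if (averaging == "biweight") tukey_biweight else
                 function(v) mean(v, na.rm = TRUE))
  depth <- rowSums(!is.na(m))
  keep <- depth >= 1L
  # restrict to the contiguous covered span (collections are contiguous by
  # construction, but guard anyway)
  years <- as.integer(rownames(m))[keep]
  chronology(years, idx[keep], depth[keep],
             rbar = pairwise_rbar(m), averaging = averaging)
}

#' Expressed population signal from mean interseries correlation
#'
#' `EPS = n rbar / (n rbar + (1 - rbar))`: the expected squared correlation
#' between a mean chronology of `n` series with mean pairwise correlation
#' `rbar` and the (infinite-population) true chronology. Strictly increasing
#' in both arguments; ~0.85 is the conventional adequacy threshold.
#'
#' @param n number of contributing series (may be a non-integer effective
#'   sample depth).
#' @param rbar mean pairwise interseries correlation, in (0, 1].
#' @return EPS in `[0, 1]`; `NA` (with a warning) where `rbar <= 0`, for
#'   which the statistic is not meaningful.
#' @export
eps_from_rbar <- function(n, rbar) {
  if (any(n < 1, na.rm = TRUE)) stop("n must be >= 1")
  out <- n * rbar / (n * rbar + (1 - rbar))
  bad <- !is.na(rbar) & rbar <= 0
  if (any(bad)) {
    warning("EPS undefined for rbar <= 0")
    out[bad] <- NA_real_
  }
  out
}

#' Running expressed population signal
#'
#' Windowed signal-strength profile: windows of `window` years advance by
#' `window - overlap` years (stride 1 for the 30/29 convention); within each
#' window, `rbar` is the mean pairwise Pearson correlation among series
#' covering at least 2/3 of the window, `n_effective` is the mean yearly
#' sample depth, and EPS follows [eps_from_rbar()].
#'
#' @param detrended a `series_collection` of `detrended_series`.
#' @param window window length in years (>= 10).
#' @param overlap window overlap in years (< window).
#' @return Data frame with one row per window position: `start_year`,
#'   `center_year`, `end_year`, `rbar`, `n_effective`, `eps` (NA where fewer
#'   than 2 series qualify).
#' @export
running_eps <- function(detrended, window = 30, overlap = 29) {
  if (window < 10L) stop("window must be at least 10 years")
  if (overlap >= window) stop("overlap must be smaller than window")
  m <- as_year_matrix(detrended)
  years <- as.integer(rownames(m))
  stride <- window - overlap
  starts <- seq(years[1], years[length(years)] - window + 1L, by = stride)
  need <- ceiling(2 / 3 * window)
  res <- lapply(starts, function(st) {
    rows <- which(years >= st & years <= st + window - 1L)
    sub <- m[rows, , drop = FALSE]
    qual <- colSums(!is.na(sub)) >= need
    n_eff <- mean(rowSums(!is.na(sub)))
    if (sum(qual) < 2L)
      return(data.frame(start_year = st, center_year = st + (window - 1) / 2,
                        end_year = st + window - 1L, rbar = NA_real_,
                        n_effective = n_eff, eps = NA_real_))
    rb <- pairwise_rbar(sub[, qual, drop = FALSE],
                        min_overlap = max(3L, ceiling(window / 3)))
    eps <- if (is.na(rb) || rb <= 0) NA_real_
           else eps_from_rbar(max(n_eff, 1), rb)
    data.frame(start_year = st, center_year = st + (window - 1) / 2,
               end_year = st + window - 1L, rbar = rb,
               n_effective = n_eff, eps = eps)
  })
  do.call(rbind, res)
}

# per-year EPS status: each year takes the EPS of the most recent defined
# window covering it (NA where no defined window covers the year)
chronology_year_eps <- function(chron) {
  if (is.null(chron$running_eps)) return(rep(NA_real_, length(chron$years)))
  re <- chron$running_eps
  def <- re[!is.na(re$eps), , drop = FALSE]
  vapply(chron$years, function(y) {
    cov <- def[def$start_year <= y & def$end_year >= y, , drop = FALSE]
    if (nrow(cov) == 0L) return(NA_real_)
    cov$eps[which.max(cov$start_year)]
  }, numeric(1))
}

#' Truncate a chronology to its statistically robust span
#'
#' The truncation year is the earliest year from which, for all later years,
#' the sample depth meets `min_depth` and the year's covering running-EPS
#' window meets `eps_threshold` (a year's EPS status is taken from the most
#' recent defined window covering it). Earlier years are retained but
#' flagged provisional — the dashed-line convention of chronology plots.
#' With `eps_threshold = 0` the EPS condition is waived; with
#' `min_depth = 1` the depth condition always holds.
#'
#' @param chron a `chronology`; its `running_eps` field must be populated
#'   (e.g. via [running_eps()]) unless `eps_threshold <= 0`.
#' @param min_depth minimum sample depth (default 10).
#' @param eps_threshold EPS adequacy threshold (default 0.85).
#' @return The chronology with `truncation_year` set (NA, with a warning, if
#'   the rule is never satisfied) and a logical `provisional` element.
#' @export
truncate_chronology <- function(chron, min_depth = 10, eps_threshold = 0.85) {
  depth_ok <- chron$sample_depth >= min_depth
  if (eps_threshold <= 0) {
    eps_ok <- rep(TRUE, length(chron$years))
  } else {
    status <- chronology_year_eps(chron)
    eps_ok <- !is.na(status) & status >= eps_threshold
  }
  ok <- depth_ok & eps_ok
  # earliest year from which ok holds through the end
  ok_through_end <- rev(cumprod(rev(ok))) > 0
  if (!any(ok_through_end)) {
    warning("truncation rule never satisfied; retained span is empty")
    chron$truncation_year <- NA_integer_
    chron$truncation_failed <- TRUE
    chron$provisional <- rep(TRUE, length(chron$years))
    return(chron)
  }
  chron$truncation_year <- chron$years[which(ok_through_end)[1]]
  chron$truncation_failed <- FALSE
  chron$provisional <- chron$years < chron$truncation_year
  chron
}

#' Retained (robust) portion of a chronology as an annual series
#'
#' @param chron a truncated `chronology`.
#' @return Data frame with columns `year`, `index` for years at or after the
#'   truncation year (all years when no truncation is set; no rows when
#'   truncation was attempted but never satisfied).
#' @export
chronology_series <- function(chron) {
  if (isTRUE(chron$truncation_failed))
    return(data.frame(year = integer(0), index = numeric(0)))
  keep <- if (is.na(chron$truncation_year)) rep(TRUE, length(chron$years))
          else chron$years >= chron$truncation_year
  data.frame(year = chron$years[keep], index = chron$index[keep])
}
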