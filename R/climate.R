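#' Remove annual and semi-annual cycles from a monthly series
#'
#' Least-squares harmonic regression: a constant plus sine/cosine pairs at
#' periods 12 and 6 months is fitted to all non-gap values and subtracted.
#' Gap months are excluded from the fit and remain gaps.
#'
#' @param series a `monthly_series` with at least 3 years of data.
#' @return A `monthly_series` of anomalies (same keys, same gaps).
#' @export
deseasonalize <- function(series) {
  if (nrow(series) < 36L)
    stop("deseasonalization needs at least 3 years of monthly data")
  w <- 2 * pi * series$month
  X <- cbind(sin(w / 12), cos(w / 12), sin(w / 6), cos(w / 6))
  fit <- stats::lm.fit(cbind(1, X), series$value)
  monthly_series(series$year, series$month, stats::residuals(fit),
                 variable = attr(series, "variable"),
                 units = attr(series, "units"))
}

#' Dynamic-topography difference index (BiOS indicator)
#'
#' Monthly difference between a northern and a central box of
#' (deseasonalized) absolute dynamic topography. Positive values indicate
#' the cyclonic circulation regime that advects ultraoligotrophic Eastern
#' Mediterranean water into the Adriatic; swapping the boxes negates the
#' index.
#'
#' @param north_box,central_box `monthly_series` over the same (year, month)
#'   keys, already deseasonalized.
#' @return A `monthly_series` named `"ADT"`.
#' @export
adt_index <- function(north_box, central_box) {
  kn <- north_box$year * 12L + north_box$month
  kc <- central_box$year * 12L + central_box$month
  if (length(kn) != length(kc) || any(kn != kc))
    stop("box series spans do not align")
  monthly_series(north_box$year, north_box$month,
                 north_box$value - central_box$value,
                 variable = "ADT", units = attr(north_box, "units"))
}

growth_year_columns <- function() {
  c("pApr", "pMay", "pJun", "pJul", "pAug", "pSep",
    "Oct", "Nov", "Dec", "Jan", "Feb", "Mar",
    "Apr", "May", "Jun", "Jul", "Aug", "Sep")
}

# calendar (year offset from growth year, month) for each of the 18 columns
growth_year_calendar <- function() {
  data.frame(
    column = growth_year_columns(),
    year_offset = c(rep(-1L, 6L), rep(-1L, 3L), rep(0L, 9L)),
    month = c(4:9, 10:12, 1:9))
}

#' Align monthly anomalies to the growth year
#'
#' Builds the 18-column month matrix used for climate-growth correlation:
#' for growth year `y` (the increment labeled `y`, formed October of
#' calendar `y - 1` through September of `y`), the columns are the six
#' months April-September of calendar `y - 1` (months preceding increment
#' deposition, prefixed `p`) followed by the twelve growth-year months
#' October (`y - 1`) through September (`y`). Growth years with any missing
#' month are dropped with a warning.
#'
#' @param series a `monthly_series` of anomalies.
#' @param growth_years optional integer vector of growth years to include;
#'   defaults to all years the series can complete.
#' @return A data frame of class `growth_year_frame`: column `growth_year`
#'   plus the 18 month columns in fixed order.
#' @export
align_to_growth_year <- function(series, growth_years = NULL) {
  cal <- growth_year_calendar()
  if (is.null(growth_years)) {
    growth_years <- (min(series$year) + 1L):max(series$year)
  }
  rows <- lapply(growth_years, function(y) {
    vals <- monthly_lookup(series, y + cal$year_offset, cal$month)
    stats::setNames(as.list(vals), cal$column)
  })
  df <- cbind(data.frame(growth_year = growth_years),
              do.call(rbind, lapply(rows, as.data.frame)))
  complete <- stats::complete.cases(df)
  if (any(!complete))
    warning(sum(!complete), " incomplete growth year(s) dropped")
  df <- df[complete, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("growth_year_frame", "data.frame"),
            variable = attr(series, "variable"))
}

# all permutations of 1..n as an (n! x n) matrix, built by insertion
all_permutations <- function(n) {
  P <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      block <- (pos - 1L) * m + seq_len(m)
      if (pos > 1L) out[block, seq_len(pos - 1L)] <- P[, seq_len(pos - 1L)]
      out[block, pos] <- k
      if (pos < k) out[block, (pos + 1L):k] <- P[, pos:(k - 1L), drop = FALSE]
    }
    P <- out
  }
  P
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties). The two-tailed
#' p-value uses the t-approximation with `n - 2` degrees of freedom; for
#' `n < 10` an exact permutation p over all `n!` orderings is used instead.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return List with `r`, `p`, `n`. `r` is `NA` (undefined) when either rank
#'   vector has zero variance.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("spearman correlation needs at least 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(rx, ry)
  if (n < 10L) {
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    P <- all_permutations(n)
    s <- matrix(ryc[P], nrow(P), n) %*% rxc
    r_all <- as.numeric(s) / sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(r_all) >= abs(r) - 1e-12)
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

significance_tier <- function(p) {
  ifelse(is.na(p), "none",
         ifelse(p < 0.05, "95%", ifelse(p < 0.10, "90%", "none")))
}

#' Monthly climate-growth correlation table
#'
#' Spearman correlations between an annual chronology and each of the 18
#' growth-year-aligned month columns of each environmental variable, with
#' 90%/95% significance tiers (two-tailed p < 0.10 / < 0.05). No
#' multiple-testing correction is applied; the expected false-positive count
#' at the 95% tier is recorded as an attribute instead.
#'
#' @param chron a `chronology` (its retained span is used) or a data frame
#'   with columns `year`, `index`.
#' @param frames named list of `growth_year_frame`s, one per variable.
#' @param min_overlap overlap (growth years) below which results are flagged
#'   `low_overlap` with a warning (default 20).
#' @return Data frame of class `correlation_table`: `variable`, `month`,
#'   `r`, `p`, `n`, `tier`, `low_overlap`.
#' @export
monthly_correlation_table <- function(chron, frames, min_overlap = 20) {
  cs <- if (inherits(chron, "chronology")) chronology_series(chron)
        else chron[, c("year", "index")]
  if (is.null(names(frames)) || any(!nzchar(names(frames))))
    stop("frames must be a named list")
  cols <- growth_year_columns()
  out <- list()
  for (v in names(frames)) {
    fr <- frames[[v]]
    merged <- merge(cs, as.data.frame(fr),
                    by.x = "year", by.y = "growth_year")
    if (nrow(merged) < min_overlap)
      warning("overlap below ", min_overlap, " growth years for ", v)
    for (mc in cols) {
      sp <- spearman_cor(merged$index, merged[[mc]])
      out[[length(out) + 1L]] <- data.frame(
        variable = v, month = mc, r = sp$r, p = sp$p, n = sp$n,
        tier = significance_tier(sp$p),
        low_overlap = nrow(merged) < min_overlap)
    }
  }
  tab <- do.call(rbind, out)
  structure(tab, class = c("correlation_table", "data.frame"),
            expected_false_positives_95 = 0.05 * nrow(tab))
}

seasonal_presets <- function() {
  list(JJA = c("Jun", "Jul", "Aug"),
       FebMar = c("Feb", "Mar"),
       AprMay = c("Apr", "May"),
       OctSep = c("Oct", "Nov", "Dec", "Jan", "Feb", "Mar",
                  "Apr", "May", "Jun", "Jul", "Aug", "Sep"))
}

#' Seasonal mean over growth-year month columns
#'
#' Row-wise mean over a subset of the 18 month columns. Presets: `"JJA"`
#' (June-August), `"FebMar"`, `"AprMay"`, `"OctSep"` (the October-September
#' growth-year annual mean).
#'
#' @param frame a `growth_year_frame`.
#' @param months character vector of column names, or one preset name.
#' @return Data frame with columns `year`, `value`.
#' @export
seasonal_mean <- function(frame, months) {
  if (length(months) == 1L && months %in% names(seasonal_presets()))
    months <- seasonal_presets()[[months]]
  if (length(months) == 0L) stop("months must be nonempty")
  unknown <- setdiff(months, growth_year_columns())
  if (length(unknown) > 0L)
    stop("unknown month column(s): ", paste(unknown, collapse = ", "))
  data.frame(year = frame$growth_year,
             value = rowMeans(as.data.frame(frame)[, months, drop = FALSE]))
}

#' Forward stepwise least-squares regression
#'
#' Forward selection only: at each step the candidate with the smallest
#' partial-F p-value is added if that p-value is below `p_enter`, otherwise
#' selection stops. Perfectly collinear candidates are skipped with a
#' warning.
#'
#' @param response numeric response vector.
#' @param candidates data frame (or named list) of candidate predictors,
#'   row-aligned with `response`.
#' @param p_enter entry threshold on the partial-F p-value (default 0.05).
#' @return An object of class `stepwise_result`: `selected` (entry order),
#'   `entry_p`, `coefficients`, `multiple_r`, `r_signed` (sign of the first
#'   predictor's coefficient applied to the multiple r), `model_p`, `n`.
#' @export
stepwise_forward <- function(response, candidates, p_enter = 0.05) {
  X <- as.data.frame(candidates)
  ok <- stats::complete.cases(X) & !is.na(response)
  X <- X[ok, , drop = FALSE]
  y <- response[ok]
  n <- length(y)
  if (ncol(X) < 2L) stop("need at least 2 candidate predictors")
  if (n < 10L) stop("need at least 10 complete observations")
  selected <- character(0)
  entry_p <- numeric(0)
  remaining <- names(X)
  repeat {
    if (length(remaining) == 0L) break
    pvals <- vapply(remaining, function(cand) {
      dat <- data.frame(y = y, X[, c(selected, cand), drop = FALSE])
      fit <- stats::lm(y ~ ., data = dat)
      cf <- summary(fit)$coefficients
      if (!(cand %in% rownames(cf)) || is.na(stats::coef(fit)[cand]))
        return(NA_real_)   # collinear with current model
      cf[cand, "Pr(>|t|)"]
    }, numeric(1))
    collinear <- names(pvals)[is.na(pvals)]
    if (length(collinear) > 0L) {
      warning("candidate(s) collinear with the selected set skipped: ",
              paste(collinear, collapse = ", "))
      remaining <- setdiff(remaining, collinear)
      pvals <- pvals[!is.na(pvals)]
    }
    if (length(pvals) == 0L) break
    best <- names(which.min(pvals))
    if (pvals[best] < p_enter) {
      selected <- c(selected, best)
      entry_p <- c(entry_p, unname(pvals[best]))
      remaining <- setdiff(remaining, best)
    } else break
  }
  if (length(selected) == 0L) {
    return(structure(list(selected = character(0), entry_p = numeric(0),
                          coefficients = numeric(0), multiple_r = NA_real_,
                          r_signed = NA_real_, model_p = NA_real_, n = n),
                     class = "stepwise_result"))
  }
  dat <- data.frame(y = y, X[, selected, drop = FALSE])
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  model_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  multiple_r <- sqrt(sm$r.squared)
  structure(list(selected = selected, entry_p = entry_p,
                 coefficients = stats::coef(fit),
                 multiple_r = multiple_r,
                 r_signed = unname(sign(stats::coef(fit)[selected[1]]) *
                                     multiple_r),
                 model_p = unname(model_p), n = n),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  if (length(x$selected) == 0L) {
    cat("<stepwise_result> no predictor entered\n")
  } else {
    cat(sprintf("<stepwise_result> selected: %s | multiple r = %.3f (signed %.3f), p = %.4g, n = %d\n",
                paste(x$selected, collapse = " + "), x$multiple_r,
                x$r_signed, x$model_p, x$n))
  }
  invisible(x)
}

#' AR(1) prewhitening
#'
#' Removes first-order autocorrelation: the AR coefficient is estimated by
#' the lag-1 sample autocorrelation and the residual
#' `x[t] - phi x[t-1]` is returned with the original mean restored. Output
#' is one value shorter than the input.
#'
#' @param x numeric vector, length at least 10, nonzero variance.
#' @return Numeric vector of length `n - 1`; attribute `"phi"` records the
#'   estimate (clipped to ±0.99 with a warning if the estimate leaves
#'   (-1, 1)).
#' @export
prewhiten_ar1 <- function(x) {
  n <- length(x)
  phi <- first_order_autocorrelation(x)   # validates length and variance
  if (abs(phi) >= 1) {
    warning("AR(1) coefficient estimate clipped to +/-0.99")
    phi <- sign(phi) * 0.99
  }
  res <- x[-1] - phi * x[-n]
  out <- res - mean(res) + mean(x)
  attr(out, "phi") <- phi
  out
}

#' Full climate-growth analysis report
#'
#' Orchestrates the inference stage: deseasonalizes each monthly variable,
#' aligns it to growth years, computes the monthly Spearman correlation
#' table, forms seasonal-mean candidate predictors, and runs forward
#' stepwise regression before and (optionally) after AR(1) prewhitening of
#' the chronology and every candidate.
#'
#' @param chron a truncated `chronology` (or data frame `year`, `index`).
#' @param variables named list of raw `monthly_series`.
#' @param candidates named list defining stepwise candidates, each element
#'   `list(variable =, months =)` with `months` a preset name or column set;
#'   default: the October-September annual mean of every variable, or the
#'   four seasonal presets of the variable when only one is supplied.
#' @param p_enter stepwise entry threshold.
#' @param prewhiten run the prewhitened regression as well (default TRUE).
#' @return An object of class `analysis_report`: `correlations`,
#'   `seasonal` (candidate series), `stepwise`, `stepwise_prewhitened`.
#' @export
analysis_report <- function(chron, variables, candidates = NULL,
                            p_enter = 0.05, prewhiten = TRUE) {
  anomalies <- lapply(variables, deseasonalize)
  frames <- lapply(anomalies, align_to_growth_year)
  corr <- monthly_correlation_table(chron, frames)
  if (is.null(candidates)) {
    if (length(variables) == 1L) {
      # one variable: compare its seasonal windows against each other
      presets <- c("JJA", "FebMar", "AprMay", "OctSep")
      candidates <- lapply(presets, function(p)
        list(variable = names(variables), months = p))
      names(candidates) <- paste0(names(variables), "_", presets)
    } else {
      candidates <- lapply(names(variables), function(v)
        list(variable = v, months = "OctSep"))
      names(candidates) <- paste0(names(variables), "_OctSep")
    }
  }
  cs <- if (inherits(chron, "chronology")) chronology_series(chron)
        else chron[, c("year", "index")]
  seas <- lapply(candidates, function(cd)
    seasonal_mean(frames[[cd$variable]], cd$months))
  yrs <- Reduce(intersect, c(list(cs$year), lapply(seas, `[[`, "year")))
  yrs <- sort(yrs)
  y <- cs$index[match(yrs, cs$year)]
  X <- as.data.frame(lapply(seas, function(s) s$value[match(yrs, s$year)]))
  names(X) <- names(candidates)
  sw <- stepwise_forward(y, X, p_enter = p_enter)
  swp <- NULL
  if (prewhiten) {
    yp <- prewhiten_ar1(y)
    Xp <- as.data.frame(lapply(X, function(col) prewhiten_ar1(col)))
    swp <- stepwise_forward(as.numeric(yp), Xp, p_enter = p_enter)
  }
  structure(list(correlations = corr, seasonal = seas, years = yrs,
                 stepwise = sw, stepwise_prewhitened = swp),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d variables x 18 months, %d growth years\n",
              length(unique(x$correlations$variable)), length(x$years)))
  sig <- x$correlations[x$correlations$tier != "none", , drop = FALSE]
  cat(sprintf("  significant cells (90%% or better): %d of %d\n",
              nrow(sig), nrow(x$correlations)))
  cat("  stepwise: "); print(x$stepwise)
  if (!is.null(x$stepwise_prewhitened)) {
    cat("  prewhitened: "); print(x$stepwise_prewhitened)
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed); writes
#'   `correlations.csv` and `stepwise.json`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  corr_path <- file.path(dir, "correlations.csv")
  utils::write.csv(as.data.frame(report$correlations), corr_path,
                   row.names = FALSE)
  sw_path <- file.path(dir, "stepwise.json")
  unclass_sw <- function(s) {
    if (is.null(s)) return(NULL)
    list(selected = s$selected, entry_p = s$entry_p,
         coefficients = as.list(s$coefficients),
         multiple_r = s$multiple_r, r_signed = s$r_signed,
         model_p = s$model_p, n = s$n)
  }
  jsonlite::write_json(list(stepwise = unclass_sw(report$stepwise),
                            stepwise_prewhitened =
                              unclass_sw(report$stepwise_prewhitened)),
                       sw_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(correlations = corr_path, stepwise = sw_path))
}
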