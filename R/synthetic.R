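# run code with a private RNG state derived from a seed, restoring the
# caller's state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# per-shell substream seed: a counter-based expansion of the global seed so
# adding shells never perturbs existing ones; kept below 2^31
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 2654435761 + i * 40503) %% 2147483647)
}

#' Simulation scenario configuration
#'
#' Defines a synthetic shell population with the statistical structure the
#' chronology pipeline assumes: a shared monthly AR(1) environmental driver,
#' a negative-exponential ontogenetic trend, a multiplicative common signal
#' proportional to the growth-year (October-September) driver anomaly, and
#' individual lognormal noise. Defaults emulate the study population this
#' toolkit targets: ~30 specimens aged 35-72 years collected in 2015/2016,
#' with the first few juvenile increments unmeasurable.
#'
#' @param n_shells number of specimens (>= 1).
#' @param collection_year latest collection year.
#' @param collection_stagger number of distinct collection years ending at
#'   `collection_year` over which sampling is spread (1-3).
#' @param age_range integer `c(min, max)` specimen ages at collection.
#' @param growth_params `c(a, b, k)` of the age curve
#'   `a exp(-b age) + k` (mm, per-year decay, mm).
#' @param signal_beta sensitivity of log growth to the growth-year driver
#'   anomaly (dimensionless).
#' @param noise_sd SD of individual lognormal noise on the log scale.
#' @param env_phi monthly AR(1) coefficient of the driver, in [0, 1).
#' @param env_sd innovation SD of the driver.
#' @param env_mean mean level of the driver (e.g. degC for an SST-like
#'   driver).
#' @param seasonal_amp `c(annual, semiannual)` harmonic amplitudes of the
#'   driver's seasonal cycle.
#' @param missing_first number of earliest increments left unmeasured per
#'   shell.
#' @param seed integer master seed; identical configurations (including the
#'   seed) reproduce bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_shells = 30, collection_year = 2016,
                       collection_stagger = 2, age_range = c(35, 72),
                       growth_params = c(a = 1.5, b = 0.08, k = 0.15),
                       signal_beta = 0.5, noise_sd = 0.2,
                       env_phi = 0.6, env_sd = 0.6, env_mean = 15,
                       seasonal_amp = c(2, 0.5),
                       missing_first = 3, seed = 1) {
  stopifnot(n_shells >= 1, age_range[1] >= 1, age_range[1] <= age_range[2],
            noise_sd >= 0, env_sd >= 0, missing_first >= 0,
            collection_stagger >= 1, collection_stagger <= 3)
  if (env_phi < 0 || env_phi >= 1)
    stop("env_phi must be in [0, 1): the AR(1) driver must be stationary")
  structure(list(n_shells = as.integer(n_shells),
                 collection_year = as.integer(collection_year),
                 collection_stagger = as.integer(collection_stagger),
                 age_range = as.integer(age_range),
                 growth_params = stats::setNames(as.numeric(growth_params),
                                                 c("a", "b", "k")),
                 signal_beta = signal_beta, noise_sd = noise_sd,
                 env_phi = env_phi, env_sd = env_sd, env_mean = env_mean,
                 seasonal_amp = as.numeric(seasonal_amp),
                 missing_first = as.integer(missing_first),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation scenario from YAML
#'
#' Scenario files mirror the [sim_config()] field names; omitted fields take
#' the defaults.
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Simulate a monthly environmental driver
#'
#' Mean level plus annual and semi-annual harmonics plus a stationary AR(1)
#' anomaly with the given coefficient and innovation SD.
#'
#' @param years integer `c(from, to)` calendar span (at least 2 years).
#' @param phi AR(1) coefficient in [0, 1).
#' @param innovation_sd innovation SD.
#' @param seasonal_amp `c(annual, semiannual)` harmonic amplitudes.
#' @param mean_level constant level.
#' @param seed integer seed; identical seeds reproduce the series exactly.
#' @param variable variable name recorded on the series.
#' @return A `monthly_series`; the pure AR(1) anomaly is attached as
#'   attribute `"anomaly"`.
#' @export
simulate_environment_monthly <- function(years, phi, innovation_sd,
                                         seasonal_amp = c(0, 0),
                                         mean_level = 0, seed = 1,
                                         variable = "DRIVER") {
  if (length(years) != 2L || years[2] - years[1] + 1L < 2L)
    stop("years must span at least 2 calendar years")
  if (phi < 0 || phi >= 1)
    stop("phi must be in [0, 1): explosive AR(1) process")
  yr <- rep(years[1]:years[2], each = 12L)
  mo <- rep(1:12, times = years[2] - years[1] + 1L)
  n <- length(yr)
  anom <- with_seed(seed, {
    if (innovation_sd == 0) {
      rep(0, n)
    } else {
      e <- stats::rnorm(n, 0, innovation_sd)
      a <- numeric(n)
      a[1] <- stats::rnorm(1, 0, innovation_sd / sqrt(1 - phi^2))
      for (t in 2:n) a[t] <- phi * a[t - 1] + e[t]
      a
    }
  })
  seas <- seasonal_amp[1] * sin(2 * pi * mo / 12) +
    seasonal_amp[2] * sin(2 * pi * mo / 6)
  out <- monthly_series(yr, mo, mean_level + seas + anom, variable = variable)
  attr(out, "anomaly") <- anom
  out
}

# growth-year (Oct-Sep) means of a deseasonalized monthly driver
growth_year_signal <- function(anomalies, growth_years) {
  vapply(growth_years, function(y) {
    v <- c(monthly_lookup(anomalies, rep(y - 1L, 3L), 10:12),
           monthly_lookup(anomalies, rep(y, 9L), 1:9))
    if (anyNA(v)) return(NA_real_)
    mean(v)
  }, numeric(1))
}

#' Simulate a shell collection driven by a monthly environment
#'
#' Each shell's increment width for growth year `t` is
#' `(a exp(-b age) + k) * exp(beta Z_t + eps)`, where `Z_t` is the mean of
#' the driver's deseasonalized anomaly over October (`t - 1`) through
#' September (`t`) and `eps` is the shell's lognormal noise
#' (`Normal(0, noise_sd^2)` on the log scale). Ages are drawn uniformly on
#' the configured range and collection years are staggered over
#' `collection_stagger` years; the first `missing_first` increments of each
#' shell are omitted, so a shell of age `A` collected in year `c` yields a
#' measured series from `c - A + missing_first` through `c`. Per-shell
#' random substreams are derived from the master seed with a counter-based
#' scheme, so enlarging `n_shells` does not perturb existing shells.
#'
#' @param config a `sim_config`.
#' @param driver a `monthly_series` covering every growth year the
#'   configuration implies (October of the year before the earliest first
#'   increment through September of the last collection year).
#' @return List with `collection` (a `series_collection`),
#'   `true_signal` (data frame `year`, `z` over all simulated growth years)
#'   and `shells` (data frame of per-shell age and collection year).
#' @export
simulate_shell_collection <- function(config, driver) {
  stopifnot(inherits(config, "sim_config"))
  anomalies <- deseasonalize(driver)
  gp <- config$growth_params
  shells <- lapply(seq_len(config$n_shells), function(i) {
    with_seed(substream_seed(config$seed, i), {
      age <- sample(config$age_range[1]:config$age_range[2], 1L)
      offset <- sample(0:(config$collection_stagger - 1L), 1L)
      eps <- stats::rnorm(age + 1L, 0, config$noise_sd)
      list(age = age, cyear = config$collection_year - offset, eps = eps)
    })
  })
  all_years <- range(vapply(shells, function(s)
    c(s$cyear - s$age, s$cyear), integer(2)))
  z <- growth_year_signal(anomalies, all_years[1]:all_years[2])
  if (anyNA(z))
    stop("driver does not cover every needed growth year (",
         all_years[1], "-", all_years[2], " required)")
  names(z) <- all_years[1]:all_years[2]
  series <- lapply(seq_along(shells), function(i) {
    s <- shells[[i]]
    years <- (s$cyear - s$age):s$cyear      # ages 1 .. age + 1
    ages <- seq_along(years)
    w <- (gp["a"] * exp(-gp["b"] * ages) + gp["k"]) *
      exp(config$signal_beta * z[as.character(years)] + s$eps)
    keep <- ages > config$missing_first
    increment_series(sprintf("SIM%03d", i), years[keep][1],
                     unname(w[keep]))
  })
  list(collection = series_collection(series),
       true_signal = data.frame(year = as.integer(names(z)),
                                z = unname(z)),
       shells = data.frame(
         specimen_id = sprintf("SIM%03d", seq_along(shells)),
         age = vapply(shells, `[[`, integer(1), "age"),
         collection_year = vapply(shells, `[[`, numeric(1), "cyear")))
}

#' Inject a crossdating error into a series
#'
#' Test surrogate for an analyst's dating mistake. `"insert"` adds a false
#' increment at `year` (its width is the local mean of up to the five
#' surrounding values) and shifts all ontogenetically older values back one
#' calendar year; `"delete"` removes the increment at `year` and shifts all
#' older values forward one year. The margin (youngest) end stays anchored;
#' series length changes by one.
#'
#' @param series an `increment_series`.
#' @param year calendar year inside the series span.
#' @param mode `"insert"` or `"delete"`.
#' @return The damaged `increment_series`.
#' @export
inject_dating_error <- function(series, year, mode = c("insert", "delete")) {
  mode <- match.arg(mode)
  yrs <- series_years(series)
  if (year < min(yrs) || year > max(yrs))
    stop("year ", year, " outside series span ", min(yrs), "-", max(yrs))
  w <- series$widths
  n <- length(w)
  idx <- year - series$first_year + 1L
  if (mode == "insert") {
    local <- mean(w[max(1L, idx - 2L):min(n, idx + 2L)])
    new_w <- append(w, local, after = idx)
    increment_series(series$specimen_id, series$first_year - 1L, new_w)
  } else {
    if (n <= 2L) stop("series too short to delete from")
    increment_series(series$specimen_id, series$first_year + 1L, w[-idx])
  }
}

#' Simulate a complete synthetic study in memory
#'
#' Generates the monthly driver implied by a configuration (on its own
#' random substream) and the shell collection it drives.
#'
#' @param config a `sim_config`.
#' @return List with `collection`, `true_signal`, `shells` (see
#'   [simulate_shell_collection()]) and `driver`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  driver_span <- c(config$collection_year - config$age_range[2] - 2L,
                   config$collection_year)
  driver <- simulate_environment_monthly(
    driver_span, config$env_phi, config$env_sd,
    seasonal_amp = config$seasonal_amp, mean_level = config$env_mean,
    seed = substream_seed(config$seed, 0L))
  c(simulate_shell_collection(config, driver), list(driver = driver))
}

#' Run the full chronology pipeline on a simulated scenario
#'
#' Convenience wrapper for validation studies: simulates the driver and
#' shells, standardizes along the chronology path, builds, profiles and
#' truncates the chronology, and correlates the retained span with the true
#' growth-year signal.
#'
#' @param config a `sim_config`.
#' @param window,overlap,min_depth,eps_threshold chronology settings.
#' @param averaging chronology averaging method.
#' @return List with `chron`, `true_signal`, and `spearman_r` (Spearman
#'   correlation between the retained chronology and the true signal).
#' @export
simulate_and_recover <- function(config, window = 30, overlap = 29,
                                 min_depth = 10, eps_threshold = 0.85,
                                 averaging = "biweight") {
  sim <- simulate_study(config)
  detr <- standardize_collection(sim$collection, "powt_negexp")
  chron <- build_chronology(detr, averaging = averaging)
  chron$running_eps <- running_eps(detr, window = window, overlap = overlap)
  chron <- truncate_chronology(chron, min_depth = min_depth,
                               eps_threshold = eps_threshold)
  cs <- chronology_series(chron)
  if (nrow(cs) < 4L) {
    # signal-strength truncation degenerates when there is no common
    # signal; the recovery check then applies to the full span
    cs <- data.frame(year = chron$years, index = chron$index)
  }
  truth <- sim$true_signal$z[match(cs$year, sim$true_signal$year)]
  r <- if (nrow(cs) >= 4L && !all(is.na(truth)))
    spearman_cor(cs$index, truth)$r else NA_real_
  list(chron = chron, true_signal = sim$true_signal, spearman_r = r,
       collection = sim$collection, detrended = detr)
}
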