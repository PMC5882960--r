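#' Canonical analysis settings
#'
#' The package's single canonical preset: 15-year spline cutoff for QC
#' detrending, 30-year/29-year-overlap running EPS windows, minimum sample
#' depth 10, EPS threshold 0.85, stepwise entry p 0.05.
#'
#' @return Named list of defaults consumed by [run_chronology()] and
#'   [run_correlate()].
#' @export
paper_defaults <- function() {
  list(cutoff_years = 15, window = 30, overlap = 29, min_depth = 10,
       eps_threshold = 0.85, p_enter = 0.05, averaging = "biweight",
       seg_len = 30, seg_overlap = 15, alpha = 0.01)
}

provenance_block <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  list(config_hash = unname(tools::md5sum(tmp)),
       package_version = as.character(utils::packageVersion("bivalvechron")),
       r_version = R.version.string,
       timestamp_utc = format(Sys.time(), tz = "UTC"))
}

resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(paper_defaults(), config)
}

#' Simulate a complete synthetic study to disk
#'
#' Writes an RWL file of simulated increment series, a monthly driver CSV, a
#' truth CSV holding the generating growth-year signal, and a provenance
#' JSON (configuration hash, package and R versions).
#'
#' @param scenario a `sim_config`, or the path of a YAML scenario file.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly; the
#'   simulated objects as attribute `"objects"`.
#' @export
run_simulate <- function(scenario, out_dir) {
  config <- if (is.character(scenario)) read_scenario(scenario) else scenario
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_study(config)
  driver <- sim$driver
  paths <- c(rwl = file.path(out_dir, "shells.rwl"),
             driver = file.path(out_dir, "driver.csv"),
             truth = file.path(out_dir, "truth.csv"),
             provenance = file.path(out_dir, "provenance.json"))
  write_rwl(sim$collection, paths[["rwl"]], "precision_0.001mm")
  write_monthly_table(driver, paths[["driver"]])
  utils::write.csv(sim$true_signal, paths[["truth"]], row.names = FALSE)
  jsonlite::write_json(c(provenance_block(unclass(config)),
                         list(config = unclass(config))),
                       paths[["provenance"]], auto_unbox = TRUE, digits = NA)
  out <- invisible(paths)
  attr(out, "objects") <- c(sim, list(driver = driver))
  out
}

#' Build and write a chronology (with QC) from an RWL file
#'
#' Reads the increment series, runs the COFECHA-style QC report, detrends
#' along the chronology path (adaptive power transform + negative
#' exponential, residual indices), builds the biweight chronology with
#' running EPS, truncates it, and writes `chronology.csv`,
#' `qc_series.csv` and `qc_flags.csv`.
#'
#' @param config list (or YAML path) with at least `rwl` (input path) and
#'   `out_dir`; optional settings override [paper_defaults()].
#' @return List with `chron`, `qc`, `detrended`, and `files`, invisibly.
#' @export
run_chronology <- function(config) {
  cfg <- resolve_config(config)
  if (is.null(cfg$rwl) || !file.exists(cfg$rwl))
    stop("config must name an existing RWL input as 'rwl'")
  if (is.null(cfg$out_dir)) stop("config must name 'out_dir'")
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  collection <- read_rwl(cfg$rwl)
  qc <- qc_report(collection, cutoff_years = cfg$cutoff_years,
                  seg_len = cfg$seg_len, seg_overlap = cfg$seg_overlap,
                  alpha = cfg$alpha)
  detr <- standardize_collection(collection, "powt_negexp")
  chron <- build_chronology(detr, averaging = cfg$averaging)
  chron$running_eps <- running_eps(detr, window = cfg$window,
                                   overlap = cfg$overlap)
  chron <- truncate_chronology(chron, min_depth = cfg$min_depth,
                               eps_threshold = cfg$eps_threshold)
  files <- c(chronology = file.path(cfg$out_dir, "chronology.csv"),
             qc_series = file.path(cfg$out_dir, "qc_series.csv"),
             qc_flags = file.path(cfg$out_dir, "qc_flags.csv"))
  write_chronology_table(chron, files[["chronology"]], retained_only = FALSE)
  write_qc_report(qc, files[["qc_series"]], files[["qc_flags"]])
  invisible(list(chron = chron, qc = qc, detrended = detr, files = files))
}

#' Correlate a chronology with monthly environmental variables
#'
#' Reads monthly variable tables, runs the full climate-growth inference
#' stage ([analysis_report()]) against the chronology, and writes the
#' correlation table CSV and stepwise JSON.
#'
#' @param config list (or YAML path) with `chronology` (CSV path from
#'   [run_chronology()], or an in-memory `chronology`), `variables` (named
#'   list of monthly CSV paths) and `out_dir`; optional `candidates`,
#'   `p_enter`, `prewhiten`.
#' @return The `analysis_report`, invisibly, with a `"files"` attribute.
#' @export
run_correlate <- function(config) {
  cfg <- resolve_config(config)
  if (is.null(cfg$out_dir)) stop("config must name 'out_dir'")
  chron <- cfg$chronology
  if (is.character(chron)) {
    tab <- read_chronology_table(chron)
    if ("provisional" %in% names(tab)) {
      keep <- tab[!tab$provisional, , drop = FALSE]
      if (nrow(keep) > 0L) tab <- keep   # provisional-only tables used as-is
    }
    chron <- tab[, c("year", "index")]
  }
  if (is.null(cfg$variables) || is.null(names(cfg$variables)))
    stop("config must provide a named list of monthly variable tables")
  variables <- lapply(names(cfg$variables), function(v) {
    p <- cfg$variables[[v]]
    if (is.character(p)) {
      if (!file.exists(p)) stop("missing monthly table for variable ", v,
                                ": ", p)
      read_monthly_table(p, variable = v)
    } else p
  })
  names(variables) <- names(cfg$variables)
  report <- analysis_report(chron, variables, candidates = cfg$candidates,
                            p_enter = cfg$p_enter,
                            prewhiten = !isFALSE(cfg$prewhiten))
  files <- write_analysis_report(report, cfg$out_dir)
  attr(report, "files") <- files
  invisible(report)
}

#' End-to-end synthetic study: simulate, build, correlate
#'
#' @param scenario a `sim_config` or YAML scenario path.
#' @param out_dir output directory.
#' @param ... settings forwarded over [paper_defaults()].
#' @return List with `simulate`, `chronology` and `report` results,
#'   invisibly.
#' @export
run_report <- function(scenario, out_dir, ...) {
  sim_files <- run_simulate(scenario, out_dir)
  chron_res <- run_chronology(c(list(rwl = sim_files[["rwl"]],
                                     out_dir = out_dir), list(...)))
  report <- run_correlate(c(list(chronology = chron_res$files[["chronology"]],
                                 variables = list(
                                   DRIVER = sim_files[["driver"]]),
                                 out_dir = out_dir), list(...)))
  invisible(list(simulate = sim_files, chronology = chron_res,
                 report = report))
}
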