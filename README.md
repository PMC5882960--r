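# bivalvechron

Growth-increment chronology construction and climate-growth analysis for
bivalve shells (sclerochronology), in R.

Annual growth increments in long-lived bivalves such as *Glycymeris* are
exactly datable by crossdating, the technique borrowed from tree-ring
science: synchronous growth patterns shared across individuals pin every
increment to a calendar year. Averaging many detrended series yields a
chronology — an annually resolved, population-level record of growth
anomalies — that can be correlated with oceanographic drivers (sea surface
temperature, heat flux, river discharge, circulation indices) far beyond
the reach of most biological monitoring series. This package implements
that workflow end to end for analysts who have increment-width
measurements (or want to study the method itself):

* **Crossdating quality control** in the style of COFECHA: each series is
  detrended with a cubic smoothing spline whose stiffness is set by a
  50% frequency cutoff (default 15 yr), divided by the fitted curve, and
  correlated with the mean of all other series; segments (default
  30 yr / 15 yr overlap) failing a one-tailed significance test at
  p ≥ 0.01, or correlating higher at a shifted dating position, are
  flagged with the best realignment lag. Series intercorrelation, mean
  sensitivity `MS = mean(|2(x[t+1]-x[t])/(x[t+1]+x[t])|)` and lag-1
  autocorrelation are reported.
* **Chronology construction** in the style of ARSTAN: adaptive power
  transform (exponent `p = 1 - b` from the log spread-vs-level
  regression), negative-exponential age-trend removal
  `w(age) = a·e^(-b·age) + k` with linear/mean fallback, residual indices,
  Tukey biweight robust mean, sample depth, and signal strength via the
  Expressed Population Signal, `EPS = n·r̄ / (n·r̄ + (1 - r̄))`, computed
  in running 30-yr windows with 29-yr overlap. The chronology is truncated
  to the span where sample depth ≥ 10 and windowed EPS ≥ 0.85.
* **Climate-growth inference**: harmonic removal of annual and semi-annual
  cycles from monthly environmental series, a north-minus-central
  dynamic-topography difference index of the Adriatic–Ionian Bimodal
  Oscillating System (BiOS), alignment of months to the October–September
  growth year (increment "2015" = Oct 2014–Sep 2015, plus the six months
  preceding deposition), Spearman correlation tables with 90%/95% tiers,
  seasonal-mean predictors, forward stepwise regression (p < 0.05 to
  enter), and AR(1) prewhitening for a conservative re-test.
* **Synthetic shell populations** with known signal structure — a monthly
  AR(1) driver, growth-year integration, lognormal individual noise,
  staggered collections, unmeasurable juvenile increments, and injectable
  dating errors — so the whole pipeline is testable without field data.
* **Tucson (RWL) decadal format** I/O for increment widths (both the 999
  and -9999 stop-marker dialects), plus CSV carriers for monthly tables
  and chronologies.

## Worked example

```r
library(bivalvechron)

# a synthetic study: 30 shells aged 35-72, collected 2015/2016, driven by
# a monthly AR(1) environment integrated over the Oct-Sep growth year
cfg <- sim_config(seed = 42)
sim <- simulate_study(cfg)

# COFECHA-style crossdating verification
qc <- qc_report(sim$collection)
qc
#> <qc_report> 30 series
#>   series intercorrelation: 0.669
#>   average mean sensitivity: 0.304
#>   mean segment length: 49.8 yr
#>   flagged segments: 3

# ARSTAN-style chronology with running EPS and truncation
detr  <- standardize_collection(sim$collection, "powt_negexp")
chron <- build_chronology(detr)
chron$running_eps <- running_eps(detr, window = 30, overlap = 29)
chron <- truncate_chronology(chron, min_depth = 10, eps_threshold = 0.85)
chron
#> <chronology> 1946-2016 (biweight averaging), max depth 30, rbar 0.494
#>   robust from 1961

# how well does the retained chronology track the true growth-year signal?
cs <- chronology_series(chron)
spearman_cor(cs$index, sim$true_signal$z[match(cs$year, sim$true_signal$year)])$r
#> [1] 0.908339

# climate-growth inference against the (raw, seasonal) driver series
report <- analysis_report(chron, list(DRIVER = sim$driver))
report
#> <analysis_report> 1 variables x 18 months, 56 growth years
#>   significant cells (90% or better): 13 of 18
#>   stepwise: <stepwise_result> selected: DRIVER_OctSep | multiple r = 0.917 (signed 0.917), p = 3.419e-23, n = 56
#>   prewhitened: <stepwise_result> selected: DRIVER_OctSep | multiple r = 0.926 (signed 0.926), p = 5.074e-24, n = 55
```

The intercorrelation (0.67 here) is the mean correlation of each
spline-detrended series with the mean of the others — the standard
crossdating quality statistic. "Robust from 1961" marks the first year
from which sample depth and windowed EPS stay above their thresholds; the
retained chronology tracks the generating growth-year signal at Spearman
r ≈ 0.93. In the inference stage the stepwise selection recovers the
October–September mean of the driving variable as the sole predictor, and
the relationship survives AR(1) prewhitening, as it should when the driver
is real.

Config-file-driven runs (`run_simulate`, `run_chronology`,
`run_correlate`, `run_report`) write RWL/CSV/JSON outputs with a
provenance block; a thin command-line wrapper lives at
`inst/scripts/bivalvechron.R`.

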