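---
title: "Methods: growth-increment chronologies and climate-growth inference"
author: "bivalvechron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-increment chronologies and climate-growth inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalvechron)
```

This vignette is the package's own account of the statistics it
implements: the models, the tunable parameters and why their defaults are
what they are, the numerical choices, and what validation on synthetic
data does and does not establish.

## The measurement model

The raw datum is one specimen's sequence of annual growth-increment widths
(mm), stored oldest to youngest and anchored by the calendar year of the
first measured increment. Widths are strictly positive. Because the
growth line forms in autumn, the increment labeled with year $y$ accretes
from roughly October of $y-1$ through September of $y$; that
October–September window is the *growth year* and governs every alignment
between growth and monthly environmental data.

Observed width is modeled as an ontogenetic trend modulated
multiplicatively by a common environmental signal and individual noise:

$$ w_{i,t} \;=\; \big(a_i e^{-b_i \cdot \mathrm{age}_{i,t}} + k_i\big)\,
   \exp\!\big(\beta Z_t + \varepsilon_{i,t}\big), $$

where $Z_t$ is the growth-year mean of the deseasonalized monthly driver
and $\varepsilon_{i,t} \sim N(0, \sigma^2)$. Multiplicative (lognormal)
noise is the natural choice here: widths cannot be negative, and the
ratio-type indices used downstream are then well defined and positive.

## Detrending: two paths for two purposes

**QC path (spline ratio).** For crossdating verification each series is
fitted with a cubic smoothing spline whose stiffness is expressed as a
*50% frequency cutoff*: a sinusoid of wavelength equal to the cutoff
(default 15 yr) is attenuated to exactly half amplitude. Writing
$g(\omega) = 6(1-\cos\omega)^2/(2+\cos\omega)$ for the discrete roughness
weight at angular frequency $\omega = 2\pi/T$, the amplitude response is

$$ A(T) \;=\; \frac{1}{1 + g(2\pi/T)\,/\,g(2\pi/\lambda)}, $$

which is exactly $1/2$ at $T=\lambda$, monotone in $T$, and
$\to 1$ as $T \to \infty$. The fit itself uses `stats::smooth.spline`
with the penalty $\mu = (\lambda/2\pi)^4$ implied by the same response
(converted to the solver's unit-interval parameterization); the empirical
attenuation of fitted sinusoids matches $A(T)$ to well under 0.01 at
periods from $\lambda/2$ to $5\lambda$ (tested at 7.5, 15, 30 and 75 yr
on 300-yr series). Edge behavior of any smoother is ill-defined, so all
frequency-response checks evaluate interior years only, trimming one
cutoff length from each end. Indices are ratios (observed/fitted), which
requires the fitted curve to stay positive; the fit refuses to produce a
ratio otherwise.

**Chronology path (power transform + negative exponential).** For the
chronology itself, each series is first passed through the adaptive power
transform: local spread $|x_{t+1}-x_t|$ is regressed on local level
$(x_{t+1}+x_t)/2$ on log–log axes and the exponent is $p = 1 - b$ with
$b$ the slope. Homoscedastic series give $p \approx 1$ (no change);
spread proportional to level gives $p \approx 0$, which we snap to the
log transform when $|p| < 0.05$. The exponent is clamped to $[0,1]$ so
the transform can only stabilize, never inflate, variance. The
transformed series is then detrended with the negative-exponential age
curve $a e^{-b\,\mathrm{age}} + k$ fit by bounded Levenberg–Marquardt
($a, b > 0$, $k \ge 0$); when the optimizer fails or collapses onto a
constraint boundary the fallback is a straight line with nonpositive
slope, then the horizontal mean — an expected-growth curve is never
allowed to increase with age. Log-transformed series can be nonpositive,
so the exponential is fitted on an internally shifted scale (the model
family is closed under shifts) and reported on the input scale.

Indices on this path are *residuals* in transformed space. The classic
variance-stabilization argument is exactly that subtraction becomes
appropriate after the power transform; ratio mode remains available as an
option. Residual-mode series are recentred to mean 1 per series before
averaging so the chronology is a dimensionless index either way.

## Crossdating quality control

The master for each series is the arithmetic (not biweight) mean of all
*other* detrended series — the COFECHA convention. Reported statistics:

* per-series leave-one-out Pearson correlation and their mean (the
  *series intercorrelation*), over common years (at least 10);
* *mean sensitivity* $\mathrm{MS} = \frac{1}{n-1}\sum_t
  \big|2(x_{t+1}-x_t)/(x_{t+1}+x_t)\big|$, scale-invariant and bounded by
  2;
* lag-1 autocorrelation with the biased ($n$) denominator;
* segment flags: segments of 30 yr lagged by 15 (both configurable; the
  segmentation convention is stated rather than inherited, since COFECHA
  settings vary between labs). A segment is flagged when its correlation
  with the master fails a one-tailed $t$-test at $\alpha = 0.01$ — dating
  errors destroy *positive* correlation, hence one-tailed — or when it
  correlates higher at a shifted dating position within ±5 yr, the two
  flag types COFECHA prints. Flagged segments report the best
  realignment lag; ties break toward lag 0, then toward the negative lag.
  Tail segments shorter than 15 yr are skipped as uninformative.

A lag of $+1$ means the series matches the master dated one year later:
an undetected *inserted* increment shows up as $+1$ on the older portion,
a missed increment as $-1$. Flags are advisory: the package never
re-dates a series automatically, since final dating authority stays with
the analyst.

## Chronology, EPS and truncation

Yearly values are the Tukey biweight robust mean ($c = 9$, iterated from
the median, at most 10 reweightings) of the indices available that year;
the arithmetic mean is available as an option. Sample depth is the count
of contributing series per year.

Signal strength uses the expressed population signal,
$\mathrm{EPS} = n\bar r / (n\bar r + 1 - \bar r)$ — the expected squared
correlation between an $n$-series mean chronology and the infinite
population chronology, strictly increasing in both arguments and
conventionally adequate at $\approx 0.85$. The running profile uses
30-yr windows advancing by 1 yr (29-yr overlap). Within a window,
$\bar r$ is the mean pairwise Pearson correlation among series covering
at least $2/3$ of the window — with staggered lifespans, demanding
full-window pairs would leave too few — and $n$ is the mean yearly
sample depth. Windows with fewer than two qualifying series are
undefined. Both the windowed and the whole-period $\bar r$ are reported,
since averaging conventions differ between implementations.

Truncation combines both rules: the retained span starts at the earliest
year from which, through the end of the record, sample depth stays at or
above 10 *and* the year's covering EPS window meets 0.85. A year's EPS
status comes from the most recent fully defined window covering it, so
interior years are judged by the window starting on them and the final
three decades by the last complete window. Earlier years are kept but
flagged provisional (the dashed-line convention of chronology figures).
With no common signal at all, $\bar r \le 0$ makes EPS undefined and the
rule is never satisfied; the retained span is then empty with a warning,
and the validation wrapper falls back to the full span for its null
check — a signal-strength filter cannot be applied to data with no
signal.

## Climate-growth inference

Monthly series are deseasonalized by least-squares removal of a constant
plus sine/cosine pairs at 12- and 6-month periods; gaps are excluded from
the fit and stay gaps. The circulation index is the monthly difference
between a northern and a central dynamic-topography box (positive =
cyclonic regime); because both deseasonalization and differencing are
linear they commute, which the tests verify to $10^{-10}$.

Anomalies are arranged in the 18-column growth-year frame: April–September
of the calendar year before the growth year (months preceding increment
deposition), then October through September of the growth year itself.
Correlations with the chronology are Spearman's rank correlation —
Pearson on mid-ranks with average ranks for ties — with a two-tailed
$t$-approximation p-value ($n-2$ df), replaced below $n = 10$ by the
exact permutation distribution over all $n!$ orderings. Two-tailed is
the conservative reading for tiered reporting at 90%/95%. No
multiple-testing correction is applied across the variable × month grid
(the field convention for exploratory response tables); the expected
false-positive count at the 95% tier is recorded on the table instead.

Seasonal predictors are row means over named column sets, with presets
for June–August, February–March, April–May and the October–September
annual mean. Stepwise regression is forward-only ordinary least squares:
at each step the candidate with the smallest partial-F p-value enters if
below 0.05, otherwise selection stops; perfectly collinear candidates are
skipped with a warning. Screening by rank correlation followed by linear
stepwise modeling mirrors standard practice. Both the multiple $r$ and
its signed version (sign of the first-entered coefficient) are reported,
since a single-predictor model's "r" is conventionally quoted signed.

Prewhitening is AR(1) only — growth and circulation series here carry
first-order persistence: $\hat\phi$ is the lag-1 autocorrelation
(clipped to ±0.99 if degenerate), the residual $x_t - \hat\phi x_{t-1}$
is mean-restored, and the regression is repeated on prewhitened response
and candidates. This deliberately removes real decadal variance along
with the autocorrelation, so it under-estimates true relationships; a
selection that survives it is robust.

## The synthetic-data generator

Defaults describe the study population this toolkit targets: 30 shells,
ages uniform on 35–72 yr, collections staggered over 2015/2016, the first
3 juvenile increments unmeasurable (so a shell of age $A$ collected in
year $c$ is measured from $c - A + 3$ through $c$), signal sensitivity
$\beta = 0.5$, individual noise $\sigma = 0.2$, and a monthly AR(1)
driver ($\phi = 0.6$) with annual/semi-annual harmonics (amplitudes 2 and
0.5) around a mean of 15 — an SST-like series in °C. The driver
innovation SD (0.6) was chosen once so the synthetic series
intercorrelation brackets the ~0.6 typical of well-replicated bivalve
chronologies; it was fixed before the validation thresholds were
evaluated and is not adjusted per test. Each shell draws its age,
collection offset and noise from a counter-derived substream of the
master seed, so enlarging the population never perturbs existing shells,
and identical configurations reproduce bit-identical output.

The generator emulates the *statistical* structure the analysis assumes —
a shared growth-year signal, smooth ontogenetic decline, multiplicative
noise, staggered coverage, insertable dating errors. It does not emulate
mechanistic growth physiology (no von Bertalanffy energetics), spatial
population structure, juvenile growth plasticity, measurement
digitization error, or environmental drivers with trends and regime
shifts. Passing validation therefore shows the pipeline recovers signals
*of the assumed form*; it cannot certify performance against model
violations such as age-dependent signal sensitivity or disturbance
pulses.

## Numerical choices and problem sizes

* Spline checks use 300-yr sinusoids, interior years only.
* The negative-exponential fit starts from a data-driven guess and treats
  parameters at their bounds ($a$ or $b \le 10^{-6}$) as failures,
  triggering the fallback chain.
* Validation of the full pipeline uses 200 replicate seeds of the default
  scenario (and 200 of its $\beta = 0$ null); EPS Monte-Carlo checks use
  6000-yr ensembles; AR(1) checks use $n = 5000$. These sizes put
  Monte-Carlo error well inside the asserted margins while keeping the
  whole validation suite in the minutes range.
* RWL output quantizes widths to the dialect unit (0.01 or 0.001 mm);
  round-trip error is at most half a unit and re-round-tripping is exact.
  Widths that would quantize to zero are refused rather than silently
  written.

## Known limitations

* The spline's closed-form response describes interior behavior;
  endpoints follow the solver's natural boundary conditions and are not
  covered by the attenuation guarantee.
* Running-EPS values at the record's ends inherit the last complete
  window; a rapid signal collapse inside the final three decades is
  detected only through the depth rule.
* The exact Spearman permutation p is computed only below $n = 10$
  (beyond that, $9!$ orderings would be pointless as the
  $t$-approximation is already accurate).
* Stepwise inference p-values are conditional on the selection path, as
  in all classical stepwise software; the prewhitened re-test mitigates
  but does not remove this.
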