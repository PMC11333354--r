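---
title: "From dendrometer and sap-flow traces to soil-moisture thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dendrometer and sap-flow traces to soil-moisture thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(dendrosap)
library(dplyr)
```

## The problem

During a summer drought, a conifer's stem dries out faster overnight than
its roots can refill it.  A point dendrometer records this directly: the
stem radius swells and shrinks diurnally, and once soil water falls below a
critical level the nightly re-swelling no longer reaches the previous
maximum.  The shortfall below the historical maximum radius is the **tree
water deficit** (TWD).  Under the *zero-growth concept*, irreversible radial
growth happens only while the cambium is fully hydrated (TWD = 0), so a
persistent daily-minimum TWD marks both drought stress and growth cessation.

`dendrosap` turns raw monitoring streams — 10-minute stem-radius and
thermal-dissipation (Granier) traces, hourly multi-sensor soil water
content, hourly weather — into two site- and tree-level response parameters:

* **k** — the soil-moisture threshold, as relative extractable water (REW),
  below which the daily-minimum TWD persists; and
* **m** — the slope of the linear decline of relative daily sap flow with
  REW below 0.5, in percent sap flow per percent REW, on days with real
  evaporative demand.

## The processing chain and its models

### Soil water

Each sensor series is cleaned by two reproducible rules (values outside
0–60 % volumetric content, and isolated spikes that jump more than 5
percentage points in one step and return within two samples).  "Outlier and
obvious error" removal is inherently judgement-based; these two rules are
the package's operational stand-in, and both thresholds are arguments of
`clean_vswc()`.  Cleaned sensors are averaged per time stamp
(`site_mean_vswc()`), and the site series is rescaled to REW:

$$\mathrm{REW} = \frac{\mathrm{VSWC} - \mathrm{VSWC}_{\min}}
                      {\mathrm{VSWC}_{\max} - \mathrm{VSWC}_{\min}}$$

with the whole-season extrema serving as proxies for the permanent wilting
point and field capacity (`soil_calibration()`).  REW values falling outside
[0, 1] — possible when analysis and calibration windows differ — are clipped
and counted.  Analysis uses the 20 cm depth by default (`analysis_config()`);
other depths are selected with the `depth` argument.

### Tree water deficit

`twd()` computes the running maximum of the radius trace and its shortfall,
floored at zero.  The running maximum deliberately carries across data gaps:
a gap cannot erase the historical maximum.  Days are calendar days in local
time.  `daily_min_twd()` keeps the per-day minimum (the persistence signal)
and maximum (the normalisation scale).

Because absolute TWD and sap-flow magnitudes vary with tree size, both are
normalised per tree by the mean of the largest 2.5 % of values
(`relative_normalize()`), which maps each series onto a robust 0–~1 scale.
"Largest values" is ambiguous between 10-minute values and daily maxima;
the package averages the largest `ceiling(0.025 N)` of the *daily maxima*
(robust to 10-minute noise), with the raw-value variant available via
`analysis_config(twd_norm_basis = "raw")`.

### Sap flow

Thermal-dissipation probes report the temperature excess of a heated needle
over a reference; flow cools the heated needle.  The zero-flow baseline is
taken as each day's maximum excess, anchored at the time it occurs and
linearly interpolated between days (`build_baseline()`).  The flow index
$K = (\Delta T_{\max} - \Delta T)/\Delta T$ (floored at zero against
baseline noise) maps to flux density through the canonical empirical
calibration $u = 0.0119\,K^{1.231}$ g cm⁻² s⁻¹, and whole-tree daily totals
scale $u$ by the tree's sapwood area with uniform flux assumed over the
conducting area (`whole_tree_daily()`).  The calibration coefficients are
configurable.  `simulate_inverse()` inverts this chain exactly (zero flow at
night makes the daily baseline anchor exact), which gives the round-trip
oracle used in the tests.

### The threshold k

Daily-minimum relative TWD is paired with the site's daily-maximum REW and
fitted with the two-parameter exponential

$$\mathrm{TWD} = a\,e^{b\,\mathrm{REW}},\qquad b < 0 .$$

`fit_twd_exponential()` initialises from a log-linear regression with the
wettest tercile excluded (where `log(twd + 1e-3)` is dominated by the
offset), then refines by Levenberg–Marquardt least squares with up to five
jittered restarts; `r2` is computed on the original scale and the model is
tested against the mean-only model by an F test.

The threshold is the x-intercept of the tangent with fixed slope −3 to the
fitted curve.  The tangent point and intercept exist in closed form:

$$x^* = \frac{\ln\!\big(s/(ab)\big)}{b}, \qquad
  k = x^* - \frac{a\,e^{b x^*}}{s}, \qquad s = -3 .$$

`tangent_threshold()` evaluates this directly (the numeric
tangent-construction route is retained in the test suite as an independent
oracle; the two agree to 10⁻⁶ over a thousand random curves).  A curve that
never attains the requested slope on $x \ge 0$ (i.e. $ab > s$) has no
tangent point and is reported as such rather than as a number.  The slope −3
is a convention; −2, −4 or −5 can be set in `analysis_config()`, and a
shallower tangent always intersects further out, so thresholds are
comparable only at a fixed slope.

A less convention-dependent alternative, `piecewise_threshold()`, fits a
continuous two-segment line with the breakpoint chosen by grid search over
the observed REW values (10th–90th percentile) and takes the x-intercept of
the steep left segment.  A breakpoint is only reported when the segmented
model beats a single line in an F test on its two extra degrees of freedom
(α = 0.05): on noisy data *any* grid breakpoint lowers the SSE slightly, so
a raw SSE comparison could never flag linear data.

### The decline slope m

Relative daily sap flow is regressed on REW (both in percent) over the
closed interval REW ∈ [0, 0.5], using only days whose maximum vapor pressure
deficit exceeds 1 kPa — on humid days sap flow is demand-limited and carries
no information about soil supply.  VPD is computed from temperature and
humidity with the FAO-56 Magnus saturation formula
($e_s = 6.108\,\exp(17.27 T/(T+237.3))$ hPa); barometric pressure is
accepted but unused, since VPD over land at these elevations is insensitive
to it.  Days with more than 25 % of hours missing are excluded from the
daily maxima — a maximum over a sparse day is biased low.  The reported `m`
is the regression slope itself (positive for a decline towards dry soil);
fits on fewer than 10 qualifying days are refused.  Derived statistics:
sap flow at `k` (the line evaluated at the threshold), mean sap flow on the
10 % driest days (strictly below the 10th percentile of REW), and mean sap
flow on days with relative TWD > 0.9.

### Cross-site statistics

`pooled_weighted_mean()` pools per-site means weighted by tree count;
`tukey_hsd_letters()` runs pairwise studentized-range tests (via `aov()` +
`TukeyHSD()`) with a hand-rolled insert-and-absorb compact letter display;
`fit_pca()` decomposes the correlation matrix (all variables standardised)
with unit-norm loadings, orienting each axis so its largest-magnitude
loading is positive — eigenvector signs are otherwise arbitrary.

## The synthetic-data generator

`simulate_site()` produces a complete site dataset — rain, five soil
sensors, hourly weather, and per-tree radius and ΔT traces — from a
mechanistic forward model with known truth, so every pipeline stage can be
tested end to end without field data.

* **Environment.** Rain events are Poisson with exponential depths; the
  event rate drops (default ×0.15) during a configurable mid-summer drought
  spell, emulating a drought year.  Site soil water follows a daily bucket,
  `VSWC[t+1] = VSWC[t] + 0.45·rain − ET`, clipped to the configured
  wilting/field-capacity proxies; draw-down is limited by atmospheric demand
  (`min(1, VPDmax/15)`) and by supply (`REW/0.5`, floored at 0.35 — residual
  evaporation and deep uptake keep drying the profile near the wilting
  point, and without the floor the season never reaches the configured
  minimum and the data-driven REW calibration would be rescaled).  Sensor
  series add constant offsets and AR(1) noise; hourly temperature and
  humidity are constructed so the VPD computed from them has the intended
  diurnal cycle and daily maximum.
* **Trees.** The latent daily stem deficit is a pure exponential in REW,
  $D = A\,e^{b\,\mathrm{REW}}$ (µm).  Given a configured onset `k_true`,
  the steepness `b` is solved so that the tangent-slope(−3) construction
  applied to the latent *relative* curve — anticipating the top-2.5 %
  normalisation, with the driest days near REW 0 and the diurnal amplitude
  riding on top — intersects the x-axis exactly at `k_true`: the generator
  is built as the inverse of the inference it feeds.  The mapping includes
  a fixed onset shift of +0.012 REW, calibrated once on noiseless forward
  runs, which compensates the small downward pull exerted on the fitted
  curve by the running-max offset (TWD is measured relative to the last
  fully hydrated day, not to zero).  Growth proceeds only while the latent
  deficit is below a 10 µm gate (zero-growth gating); the 10-minute radius
  trace adds a VPD-scaled diurnal shrink–swell cycle and dendrometer noise.
  Trees share the latent steepness and onset and differ in deficit
  amplitude (lognormal jitter), which the per-tree normalisation absorbs —
  steeper-than-site curves at a high onset would not be representable on
  the relative scale.
* **Sap flow.** Relative daily sap flow saturates with demand
  (`min(1, VPDmax/12)`) and declines linearly below REW 0.5 at `m_true` %/%
  (floored at 0.02 — the floor must sit below the line's dry-end value or
  it would flatten the fitted slope).  Daily targets are converted to ΔT
  traces by `simulate_inverse()`, so the forward Granier chain recovers
  them by construction.
* **Streams.** Each site uses named substreams (environment, tree *i*), so
  adding a tree never perturbs the environment or earlier trees, and an
  identical configuration reproduces a byte-identical dataset.

The default scenario suite (`default_site_configs()`) spans a dry
continental, an intermediate, a dense wet-soil and an oceanic site, with
true thresholds bracketing 0.217–0.296 REW and decline slopes 1.1–2.0 %/%,
~150-day seasons, 5 trees and 5 sensors each.  `wet_site_config()` is a
no-drought control on which the pipeline must report "no tangent point" and
refuse the decline fit rather than produce numbers.

**What the generator does not emulate:** sensor drift and re-mounting jumps,
frost shrinkage, thermal gradients in the sapwood, radial flux profiles,
stand-level feedbacks, and any carbon-budget coupling.  Passing the
recovery tests therefore shows the *inference machinery* is unbiased under
the stated noise model — not that field data meet these assumptions.

## A worked run

```{r worked}
cfg <- site_config(seed = 1L, noiseless = TRUE)
analysis <- run_site_analysis(simulate_site(cfg))
analysis
glance(analysis) |> select(k, m, r2_twd, r2_sapflow)
c(k_true = cfg$k_true, m_true = cfg$m_true)
```

```{r plots}
ggplot2::autoplot(analysis$site_fit$exp_fit)
ggplot2::autoplot(analysis$site_fit$decline, k = analysis$summary$k)
```

## Numerical choices and edge cases

* Timestamps are timezone-naive throughout (held as UTC internally); days
  are calendar days with no hydrological-day offset.
* The exponential fit refuses degenerate input (fewer than three positive
  deficits or zero variance) instead of returning an arbitrary curve.
* A fitted `k` outside [0, 1] is flagged with a warning, not silently
  clipped.
* The drought statistic ("mean sap flow on the 10 % driest days") ranks
  days by REW and averages the lowest tenth.  A quantile-threshold rule
  breaks down when a long drought pins REW at exactly zero for weeks: with
  heavy ties, "strictly below the 10th percentile" selects nothing.
* The recovery experiments in the acceptance suite use 4 scenarios × 20
  seeds at ~150 days and 5 trees — sizes chosen so the whole suite runs in
  a few minutes on one core while leaving the medians stable.
* Measured on the default suite: noisy recovery has median absolute
  threshold error ≈ 0.03 REW and median relative slope error ≈ 4 %;
  noiseless runs recover the threshold to well under 0.01 REW at machine-
  precision slopes (these are the quantities `scripts/acceptance.R`
  recomputes).

## Known limitations

The tangent construction makes `k` a convention (fixed slope −3) rather
than a physical quantity; the segmented-regression alternative is less
subjective but needs data on both sides of the break.  Ring-width-based
growth ratios compare dendrometer increments (which include bark tissue)
with core ring widths, so they overstate true wood growth by an unknown
margin.  The Granier calibration is the universal literature value; without
per-species calibration, absolute (but not relative) sap flow carries that
systematic uncertainty.
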