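---
title: "Agroclimatic methods: chill, heat, winter extremes and warming scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agroclimatic methods: chill, heat, winter extremes and warming scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`agrochill` characterizes fruit-growing station networks by the agroclimatic
quantities that govern the adaptation of temperate species (peach, apricot,
plum, sweet cherry and similar *Prunus* crops): winter chill accumulation,
early-season heat accumulation, and the weekly probabilities of frost and of
abnormal winter-heat episodes, for the observed climate and under warmed
pseudo-GCM ensembles.  Because dense hourly station archives and downscaled
projection grids are rarely redistributable, the package ships a synthetic
weather generator that reproduces the statistical structure such an analysis
assumes; every stage is exercised end to end against it.

## Accumulation models

All four kernels are hourly.  Seasonal totals sum them over fixed windows:
chill from 1 November to 28 February of the following year (29 February is
excluded), heat from 1 January to 8 April (29 February included when
present).  A season is labeled by the calendar year of its 1 November start.

**Utah chill units.**  A piecewise-constant weight per hour at temperature
$T$ (degrees C): 0 below 1.4, +0.5 on (1.4, 2.4], +1 on (2.4, 9.1], +0.5 on
(9.1, 12.4], 0 on (12.4, 15.9], −0.5 on (15.9, 18], −1 above 18.  Band edges
are closed on the right; warm hours subtract chill, so seasonal totals can
be negative in warm climates.

**Dynamic-model chill portions.**  A two-step kinetic process: a thermally
labile precursor forms toward a temperature-dependent equilibrium
$x_s = (A_0/A_1)\,e^{(E_1-E_0)/T_K}$ at rate $k_1 = A_1 e^{-E_1/T_K}$
($T_K = T + 273.15$ exactly), and once the level reaches 1 a fraction
$\xi(T_K) = s/(1+s)$ with $s = e^{\,\mathrm{slp}\cdot T_x (T_K - T_x)/T_K}$
is banked irreversibly as a chill portion, resetting the pool.  Constants
are the canonical published set ($E_0 = 4153.5$, $E_1 = 12888.8$,
$A_0 = 1.395\times 10^5$, $A_1 = 2.567\times 10^{18}$, slp $= 1.6$,
$T_x = 277$ K), kept in `dynamic_model_constants()`.  Banking is
deterministic (bank $\xi E$ whenever $E \ge 1$), the convention of the
standard dormancy toolkits.  Portions never decrease; near the ~6 C optimum
the model banks roughly one portion per 28 h.  The recursion is implemented
in C++ for speed and is checked against an independently coded literal R
transcription to $10^{-9}$ in the test suite.

**Growing degree hours.**  Richardson: $\max(0, \min(T, 25) - 4.5)$.
Anderson (ASYMCUR): an asymmetric cosine response with cardinal temperatures
base 4, optimum 25, critical 36 C, maximum 21 GDH at the optimum, zero
outside [4, 36]; the stress factor is fixed at 1 because no stress data are
modeled.

## Frost and abnormal-heat events

A frost event is a maximal run of at least 3 consecutive hours strictly
below −1 C; an abnormal winter-heat event at least 3 consecutive hours
strictly above 25 C.  Both thresholds are configurable.  Runs interrupted by
a missing hour are split; a run spanning a week boundary counts once, in the
week of its first hour.

Weeks are 7-day blocks from 1 January (week 1 = days 1-7); the 1-2 day
year-end fragment merges into week 52, which lies outside every analysis
range.  The weekly probability at a station is the number of years in which
that week had at least one event divided by the number of years considered —
multiple events in one week of one year count once.  Frost is tabulated over
weeks 2-10; abnormal heat over weeks 49 (early December, attached to the
following season) through 8.  Display conventionally keeps probabilities
at or above 10 % (`threshold_mask()`).

## Station screening

The regulatory completeness rule behind real network selections is not
public in a reusable form, so the package states its own: a season is
complete iff at least 90 % of its hourly records are present in *each* of
the chill and heat windows, and a station is retained iff it has at least 5
complete seasons.  Missing hours are never imputed.  Both thresholds are
configurable (`screen_station()`, `screen_network()`).

## Hourly idealization of daily projections

Projected climates provide only daily minima and maxima, so hourly
temperatures are reconstructed with the Linvill-style idealized curve:
daytime follows a sine from the minimum at sunrise over a half-period of
(daylength + 4) h, so the maximum falls mid-afternoon; after sunset the
temperature decays logarithmically (hours-since-sunset, clamped below at 1)
from the sunset-point temperature toward the next day's minimum at its
sunrise.  Sunrise and sunset come from the standard declination/hour-angle
geometry, valid for |lat| < 60.  Samples sit on the hour in local solar
time; no daylight-saving shifts are applied.  At block edges the decay
targets the block's own minimum (no tomorrow available).  The curve is exact
against a 1-minute fine-grid evaluation of the same family and preserves
daily extremes to within ~0.3 C at hourly sampling.  Comparing observed
(noisy) hours with idealized (smooth) hours carries an acknowledged bias;
no correction is applied, matching the practice this construction comes
from.

## Synthetic study conditions

`generate_station_network()` emulates a Mediterranean station network:

| archetype | annual mean | seasonal amp | diurnal amp | AR(1) sd, rho | frost/heat episodes per winter |
|---|---|---|---|---|---|
| warm_coastal | 17.6 C | 6.0 C | 3.5 C | 1.5 C, 0.8 | 0.05 / 2.5 |
| intermediate | 15.2 C | 6.0 C | 4.5 C | 1.8 C, 0.8 | 1.2 / 0.6 |
| cold_interior | 12.2 C | 7.2 C | 5.5 C | 2.0 C, 0.8 | 3.5 / 0.05 |

The annual sinusoid troughs on 15 January and the diurnal sinusoid peaks at
15:00 solar time — plausible for Iberia and coherent with the accumulation
windows.  The AR(1) hourly residual is the simplest process giving realistic
persistence of cold and warm spells.  Episodes are injected by depressing
(raising) a random 4-8 h pre-dawn (afternoon) block below −1 C (above 25 C)
by a sampled 0.5-3 C margin, with Poisson counts per winter, which makes
event probabilities controllable in tests.  Station coordinates are uniform
in the bounding box (the real spatial pattern of any particular network is
not modeled); the default archetype mix (12.5 / 45 / 42.5 %) mirrors the
proportions of low/medium/high-chill stations reported for the Spanish
stone-fruit network.  Per-station coverage is drawn as
$\max(5,\, 21 - \mathrm{Geom}(0.3))$ seasons — range 5-21, median 20 —
and records are generated per dormancy season (1 Oct - 30 Apr), which
contains both accumulation windows and both event-analysis ranges.  The
archetype parameters were calibrated once so that long-run mean portions
land mid-class (about 43, 73 and 85 portions) and decline monotonically
under uniform warming; they are part of the shipped configuration, not a
per-analysis dial.

What the generator does *not* emulate: elevation and coastal-distance
effects, spatially correlated weather between stations, precipitation or
radiation, trends within the historical period, and the real network's
station placement.  Tests passing on this synthetic world therefore
validate the *computational* pipeline and the qualitative climate-gradient
behaviour, not any site-specific conclusion about real orchards.

## Warming scenarios and the ensemble

Four scenarios (horizons 2035 = 2025-2045 and 2055 = 2045-2065, each under
RCP4.5 and RCP8.5) with default mean offsets +1.2, +1.5, +1.9 and +2.9 C,
representative of downscaled Iberian projections.  Each of the 11
pseudo-GCMs applies a fixed offset `mean_offset + N(0, 0.3)` to the daily
extremes extracted from a station's most recent 5 seasons; grid points are
station coordinates jittered by 0.2-3.9 km, emulating nearest-point matching
on a ~5 km grid (`match_stations_to_grid()` reports min/mean/max great-circle
distances on a 6371 km sphere).  Within a GCM, metrics are averaged over
season-years first (per-GCM climatology); the ensemble value is the
unweighted arithmetic mean across GCMs (median available via
`statistic = "median"`).  Weekly event probabilities are computed per GCM
and then ensemble-averaged.  `chill_delta()` reports chill lost (current
minus future portions) and heat gained (future minus current Anderson GDH).

## Spatial analysis

Stations are classed by current mean portions: low < 60, medium in the
closed interval [60, 80], high > 80 (boundaries configurable; the closed
reading of "between 60 and 80" keeps the three classes a partition).
Surfaces use inverse-distance weighting, $\hat v = \sum d_i^{-p} v_i /
\sum d_i^{-p}$ with default power 2 over all stations (no k-nearest
truncation), on a 0.05 degree (~5 km) grid, exact at station locations and
masked beyond 50 km from the nearest station.  Class distribution summaries
use type-7 quartiles and Tukey 1.5 x IQR whiskers with outliers reported by
station id.

## Numerical and degenerate-input choices

* Kelvin conversion is +273.15 exactly; Utah band edges are closed-right;
  Anderson is zero at and beyond the critical temperature.
* The night-decay clamp (hours-since-sunset >= 1) keeps the first post-sunset
  sample at the sunset temperature instead of diverging.
* Empty series: zero-length input yields zero portions; an all-missing
  window yields zero totals, zero hours and an incomplete flag, not an
  error; an empty station is simply not retained.
* IDW: coincident stations are averaged with a warning; a cell within 1e-6
  km of a station takes the station value exactly; an empty station set is
  an error.
* Partial seasons (window completeness below 90 %) are excluded from
  station climatologies, consistent with the screening rule.
* Determinism: every stochastic step is a pure function of the spec/config
  seed; regenerating with the same seed is bitwise identical, and two
  pipeline runs with the same config produce byte-identical outputs.

## Problem sizes

The test suite exercises single seasons and small networks (1-16 stations)
for unit checks, and one shared 60-station network spanning the three
archetypes (2000-2020, median 20 seasons per station) for the end-to-end
checks: model-agreement statistics, chill-loss/heat-gain association,
scenario ordering and class recovery, with two scenario runs of 11
pseudo-GCMs over the 5 most recent seasons per station.
`scripts/acceptance.R` recomputes the same quantities from scratch at an
arbitrary seed.

## Known limitations

* Offsets shift daily extremes uniformly; pseudo-GCMs do not alter diurnal
  range, variance or the annual cycle shape, so between-GCM disagreement is
  narrower than in real ensembles.
* The idealized-curve bias between observed and projected paths is not
  corrected, so current-vs-future deltas inherit it, as they do in the
  practice this package mirrors.
* No bias correction, quantile mapping or GCM skill weighting; no kriging,
  elevation covariates or cartography (surfaces export as CSV/GeoJSON).
* Cultivar- or stage-specific frost damage thresholds are out of scope; the
  event definitions characterize exposure, not damage.
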