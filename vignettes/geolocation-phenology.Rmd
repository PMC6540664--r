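---
title: "From raw light to migration phenology: the models behind flytrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw light to migration phenology: the models behind flytrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flytrack)
```

flytrack estimates where a small bird was, day by day, from nothing but the
light recorded by an archival geolocator on its back, and then turns those
daily locations into the quantities migration ecologists actually compare:
when spring migration began, when the bird reached its breeding site, how
far and how fast it travelled, and how long it sat on stopovers. This
vignette explains each model in the chain, the tunable parameters and their
defaults, what the bundled simulator does and does not emulate, and the
numerical decisions that shape edge-case behaviour.

## The threshold method

A light-level geolocator samples ambient light every few minutes. The only
robustly usable feature of that series is the pair of times at which light
crosses a fixed threshold each day — sunrise (upward) and sunset (downward)
crossings, the *twilight events*. Given a twilight pair, solar geometry
yields a position:

* **Longitude** comes from the twilight midpoint: the midpoint estimates
  apparent solar noon, and after applying the equation of time
  $\mathrm{EoT}(t)$, longitude is
  $\lambda = (720 - \mathrm{EoT} - t_{\mathrm{mid}})/4$ degrees (4 minutes
  per degree).
* **Latitude** comes from day length: with solar declination $\delta$ and a
  calibrated zenith angle $z$, the half day length fixes the hour angle
  $H$ in $\cos z = \sin\phi\sin\delta + \cos\phi\cos\delta\cos H$, which is
  solved for $\phi$.

Solar declination and the equation of time use the NOAA low-precision
closed form (a Fourier series in the fractional year; `solarPosition()`).
Its errors (≤0.3° declination, ≤0.5 min EoT) are negligible against the
0.5–2° error floor of light-level geolocation itself. Forward prediction
(`predictTwilights()`) evaluates the solar terms at local apparent noon,
and the inversion (`thresholdLocation()`) evaluates them at the observed
twilight midpoint — the same instant — so the forward/inverse round trip
closes to well under 0.1° away from the equinoxes.

Near an equinox day length is ~12 h at every latitude, so latitude is
unidentifiable from a twilight pair; `thresholdLocation()` flags a fix
`latitude_unreliable` when day length is within 8 min of 12 h (below
typical twilight noise) and always returns the longitude.

## Twilight detection

`findTwilights()` classifies samples as day or night against the threshold
(0.5 light units by convention for BAS-style loggers), merges dark or
light spells shorter than `min_dark_minutes` (default 120) so that daytime
shading spikes and nocturnal glints do not spawn spurious events, and
interpolates each crossing linearly between the two adjacent samples.
Linear interpolation matches the threshold semantics, and the sampling
interval — not the interpolation — dominates the timing error.

## Calibration

While the bird is still at its capture site its position is known, so the
observed crossings calibrate two things (`calibrate()`):

1. the **zenith angle** $z$ of the sun at threshold crossing, and
2. the distribution of **twilight delays**: shading can only make observed
   sunrise later and observed sunset earlier than the geometric crossing,
   so delays are one-sided, $d \ge 0$, and modelled log-normally,
   $d \sim \mathrm{LogNormal}(\mu, \sigma)$ in minutes.

The two are coupled: the naive zenith estimator (median solar zenith at
the observed crossings) is biased towards the horizon by the median delay
itself — about 1° for a 5-minute median delay. flytrack therefore fits
$(z, \mu, \sigma)$ jointly by profile maximum likelihood over a zenith
grid (0.02° steps), treating any non-positive delay as impossible; the
naive median-crossing zenith seeds the lower end of the grid. In recovery
experiments this estimator finds the true zenith within ±0.4°.

Two numerical guards: delays are floored at 0.01 min before taking logs,
and when the median delay is below half a minute the data are effectively
noise-free — the residuals are crossing-quantisation, not shading — so
$\sigma$ is clamped to a configured floor (0.01) with a warning.

**A known identifiability limit.** Along the $(z, \mu, \sigma)$ ridge the
likelihood is nearly flat: a slightly larger zenith shifts every delay up
and compresses the log-spread. At a typical calibration size (60
twilights) the ML estimate of $\sigma$ scatters by roughly ±30% across
realisations (the generating draws' own sample $\sigma$ already scatters
by ±9%), while $z$ and $\mu$ recover within ±0.5° and ±20%. We evaluated
order-statistic anchoring, a zenith-free difference-ratio estimator and
parametric-bootstrap bias correction; none reliably tightens $\sigma$
further, because the uncertainty is variance, not bias. Downstream
inference is insensitive: the fitted triple is self-consistent along the
ridge, and the sampler uses it as a unit.

## The location posterior

For each twilight day the model combines (`sampleTrackPosterior()`):

* the **twilight likelihood**: log-normal log-density of the day's sunrise
  and sunset delays at the candidate position (−∞ if a predicted twilight
  does not exist there, or a delay is non-positive);
* a **behavioural speed prior**: the great-circle speed between
  consecutive daily positions, divided by a ceiling (80 km/h), follows a
  beta distribution;
* an optional **land mask** (polygons; even-odd rule), off-mask positions
  having zero posterior mass. The mask applies to every day, since
  stationarity is unknown at sampling time.

A Metropolis sampler with Gaussian random-walk proposals (SD 0.5°,
latitude reflected at the poles, longitude wrapped) explores the joint
posterior. Days are updated in two alternating blocks — odd and even
indices — so each block's conditionals factorise given the other block and
the whole sweep vectorises; this targets the same posterior as one-at-a-
time updates. The run protocol is three runs of three chains with 5,000
iterations each: the first two runs are burn-in, each run is re-initialised
at the previous run's median daily locations, and only the final run is
retained, keeping every second iteration. Initial locations are threshold
fixes computed from twilights shifted by the median calibrated delay
(raw threshold fixes sit at delay 0, outside the error support), with
flagged latitudes interpolated from neighbouring days.

**Speed prior default.** The prior must encode that most days are
stationary while migratory hops of several hundred km/day remain
plausible. flytrack uses Beta(0.7, 8) on speed/80 km h⁻¹ — monotone
decreasing, mean ≈ 154 km/day, matching the 81–223 km/day rates observed
in this system. An interior-mode alternative (e.g. Beta(2.2, 2), mode ≈
45 km/h sustained) actively rewards movement; in ground-truthed
simulations it produced near-equinox latitude random walks of tens of
degrees and roughly 60% wider longitude intervals, so it was rejected.

**Polar-grazing degeneracy.** With a calibrated zenith beyond 90°, the
twilight-to-twilight "day length" is non-monotonic in latitude: near the
pole whose autumn/spring declination matches $z - 90°$, the sun grazes the
calibrated zenith all day and almost any twilight pair is approximately
consistent. Chains that drift poleward during equinox-flat days can lodge
in this spurious mode. A land mask removes it; without one, the sampler's
latitude support (`lat_range`, default ±80°) excludes the degenerate caps.
Equinox-window latitudes remain, as in all threshold geolocation, poorly
identified — only the speed prior constrains them.

Posterior summaries (`summarizePosterior()`) are componentwise medians
with central 95% credible intervals from linear-interpolation quantiles.

## Stationary periods

`segmentStationary()` delimits the daily posterior into stationary periods
and movement days with a greedy forward pass over the running posterior
mean: a new segment opens when the incoming day's median departs from the
open segment's running mean by more than `z_break` × the segment's mean
daily CrI half-width on either axis. This reconstructs the "natural
breaks" idea — change points in the running posterior mean, scaled by the
location uncertainty itself — without claiming to replicate any specific
unpublished implementation. `z_break` is the module's central free
parameter; its default (2.0) is deliberately conservative, and the test
suite carries a sensitivity check confirming that the number of periods is
monotonically non-increasing in `z_break`. Segments of at least `min_days`
(default 2 — stopovers can be short) become stationary periods, whose
location is the median (and 2.5–97.5% quantiles) of all retained samples
pooled over the segment's days. Within ±15 days of an equinox an optional
flag restricts the break test to longitude; it is off by default.

## Phenology rules

Winter and spring are delimited purely by stationary-period durations
(`delimitWinter()`), because these birds shift among multiple nonbreeding
sites across longitudes:

* **winter start** — beginning of the first stationary period of ≥30 days
  after the deployment residency (the schedule's first stationary period)
  has ended;
* **spring initiation** — end of the first ≥30-day period not followed by
  another ≥30-day period (equivalently, the end of the last long period);
* **winter sites** — the ≥30-day periods between those bounds;
* **arrival** (`detectArrival()`) — the first post-initiation day whose
  longitude 95% CrI contains the breeding-site longitude; at the two
  austral sites this is floored at that year's census first-observation
  date (2010-10-10, 2011-09-29, 2014-10-05, 2015-10-12), because the
  migration route crosses the breeding longitude and the pure longitude
  rule can fire while the bird is still travelling. At sites without a
  census floor the same early-capture bias exists and is inherited by any
  longitude-CrI arrival rule; flytrack's concentrated speed prior keeps it
  to a day or two in simulation, but it is a structural limit of the
  method, not of the implementation.

Spring metrics (`springMetrics()`) then follow: distance is the
great-circle distance (haversine, R = 6371 km) from the last winter
period's median to the breeding site; durations are inclusive day counts
(both endpoints counted — the convention forced by the reference
per-individual table, e.g. 23 Sep → 10 Oct printed as 18 days); rate is
distance/duration; stopovers are the stationary periods strictly between
initiation and arrival. A missing arrival leaves duration and rate
missing but keeps the distance. `qcRateOutlier()` flags, within each
site, any rate more than double the next-fastest — such rates are
artefacts of arrival uncertainty, not flight performance.

## Group statistics

`groupSummary()` reports means and sample SDs (n−1), dropping missing
values per variable and summarising dates on day-of-year (Jan 1 = 1).
`fitLM()` is ordinary least squares with treatment coding and DF as the
site reference level; `backwardEliminate()` removes, one at a time, the
removable term (marginality respected: interactions before their mains)
whose likelihood-ratio χ² test against the current model has the largest
p > α (default 0.05). `pearsonTest()` is the product-moment correlation
with the t test on n−2 df. The sex comparison uses Welch's two-sample
t test — a deliberate choice, since the original comparison's statistic is
unspecified; Welch avoids the equal-variance assumption at these small,
unbalanced sample sizes. All p values are two-sided and uncorrected.

## The simulator

`simulateAnnualTrack()` builds a ground-truthed year: breeding residency
at one of the four configured sites, a fall transit, winter split over
1–5 stationary sites near the wintering centre (default 2.5°N, 65°W,
jittered), and a spring migration with 0–5 stopovers placed along the
route, all dates configurable with defaults emulating the observed
movement structure (spring distances ~2,600–5,100 km in 16–57 days).
`simulateLight()` renders light as a logistic function of solar altitude
— scaled so the threshold crossing happens exactly at the true zenith —
clipped at the sensor maximum, with per-day log-normal twilight delays
(sunrise shifted late, sunset early, via a time warp split at local
noon) and optional Poisson shading events. The defaults
(LogNormal(log 5, 0.6) delays, 5-min sampling, zenith 96°) represent a
moderately shaded passerine logger.

What the simulator does *not* emulate: weather and cloud systems
(delays are independent across days, real shading is autocorrelated),
sensor saturation curves and temperature drift, longitude-dependent
habitat shading, and coastline geometry. Passing recovery tests therefore
demonstrate correctness of the estimation chain under the stated error
model, not performance on any particular field dataset.

## Problem sizes and runtime choices

The test suite and the acceptance script run recovery at sizes chosen to
finish in minutes while keeping the statistics meaningful: 30-day
stationary calibrations (60 twilights), 20–30-day stationary posterior
runs at 1,000 iterations, an 87-day stopover scenario at 1,000 iterations
× 2 chains × 2 runs, and one full 371-day tropical year at 2,000
iterations × 2 chains × 2 runs. The full protocol (3 × 3 × 5,000, thin 2)
remains the package default for real deployments.

## Known limitations

* Latitude is unidentifiable within roughly ±2 weeks of the equinoxes;
  flytrack flags it and relies on longitude plus the speed prior there.
* The calibration σ is weakly identified at typical calibration sizes
  (see above).
* The longitude-CrI arrival rule is biased early when the final approach
  is longitudinally unresolvable; census flooring is the remedy where
  census data exist.
* The scheduler's `z_break` is a reconstruction of an informal criterion;
  boundary placement within ±2 days is what simulations support.
* The movement model factorises speed between consecutive daily medians
  (forward-neighbour pairs); within-day movement between twilights is not
  modelled.
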