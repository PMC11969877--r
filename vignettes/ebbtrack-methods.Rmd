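---
title: "Methods: tidal and circadian selectivity analysis for river telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tidal and circadian selectivity analysis for river telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Catadromous river animals — here, adult Chinese mitten crabs on their
once-in-a-lifetime downstream spawning migration — cross three hydrological
regimes on their way to brackish water: unidirectional non-tidal rivers, a
micro-tidal transition, and a meso/macro-tidal estuary. Two timing
strategies are of interest: *nocturnal movement* (predator avoidance in
shallow clear water) and *selective tidal stream transport* (STST: moving
only on the ebb, whose seaward current subsidises transport). Fixed acoustic
receivers observe neither strategy directly; they yield detection times at
known positions. The package turns those detections into phase-annotated
arrival/departure events and tests them against a continuous-migration null.

## The null model and its assumptions

For each event type (arrival = first detection of a tag at a receiver,
departure = last), the null hypothesis is that migration is continuous in
time, so events fall into a phase in proportion to the phase's share of the
cycle. The test is Pearson's chi-squared goodness of fit with *weighted*
expected proportions:

* **Circadian** (day / twilight / night, with twilight = dawn ∪ dusk): the
  phase shares change through the season, so each event contributes the
  phase-duration fractions of *its own UTC date at its own receiver
  position*; the expected proportion is the mean over events. This is
  algebraically identical to weighting each date by its number of
  occurrences, but order-free. Tests are run separately per tidal class
  because light regime and tidal forcing are confounded along the river.
* **Tidal** (ebb / flood): phase shares change along the river (the ebb
  lengthens upstream), so each event contributes its receiver's mean-ebb /
  mean-cycle share, i.e. receiver-occurrence weighting. Events pool across
  the tidal zone; arrivals and departures are always tested separately and
  no multiple-testing correction is applied by default (a flag exists).

Assumptions worth stating: events are treated as independent draws from the
phase distribution (see *Fixture design* below for when that premise fails);
phases with zero expected duration in a stratum (astronomical night in
midsummer at 51° N) are dropped with df reduced, because the chi-squared
statistic requires strictly positive expecteds; single-detection visits
count as both an arrival and a departure, since the two tallies are tested
separately.

## Tidal phase from water levels

Tidal phase is defined purely by the water level: ebb runs from a high-water
turning point to the next low water, flood the reverse, with half-open
intervals so an instant exactly at high water belongs to the starting ebb.
Levels are first inverse-distance interpolated from the two chainage-closest
gauges to the receiver position (weights 1/d; a coincident gauge wins
exactly; a zone with a single usable gauge — the transition zone — gets no
tidal annotation at all, and its events are marked `unavailable` rather than
guessed). Segmentation then:

1. smooths the 10-min series with a centred moving average (default 7
   samples = 70 min) to suppress gauge noise;
2. takes alternating sign changes of the first difference as candidate
   turning points, enforcing alternation (the more extreme of two same-type
   neighbours wins) and a minimum half-cycle separation (default 3 h,
   guarding against wind-setup double extrema);
3. **debiases** each interior turning point: a symmetric running mean drags
   an extremum toward its flatter limb. With adjacent half-cycle durations
   *P* (before) and *N* (after) and limb curvature scaling as 1/duration²,
   the smoothed extremum sits ≈ *h*(N − P)/(N + P) past the true one
   (*h* = half the window). The sub-sample location is found by spline
   upsampling, the shift subtracted, and the time re-rounded to the 10-min
   grid.

Numerical behaviour: on noise-free asymmetric tides (ebb fractions 0.50,
0.573, 0.677 of a 12.4-h cycle) recovered mean ebb/flood durations are
within ±10 min of the analytic values; under 2-cm Gaussian gauge noise the
means stay within about one 10-min sample. Under much heavier noise the
estimator re-acquires a bias toward the flatter limb (noise flattens the
distinction between near-extreme samples); this is a known limitation.

## Solar phases

Day/twilight/night follow the standard conventions: day above −0.833° solar
altitude (sunrise/sunset with refraction and semidiameter), astronomical
twilight down to −18°, night below. Altitude uses the truncated-Meeus
ephemeris (NOAA-calculator grade, ~0.01° over 1900–2100); daily durations
come from threshold-crossing times (1-min scan, root refinement to < 0.5 s),
so the three durations partition 24 h exactly. At 51° N the sun never
reaches −18° near the June solstice; night is then 0 h by convention and
twilight absorbs the dark period, rather than raising an error. Durations
are computed per UTC day (all timestamps in the package are UTC), and each
event's position is its receiver's coordinates. An independently coded
equation-of-time oracle agrees with the implementation to < 0.05° in
altitude and < 2 min in crossing times across the October–August study
window; near-grazing −18° crossings are intrinsically ill-conditioned (the
crossing-time derivative with respect to altitude error diverges as the
nightly minimum approaches the threshold), so existence disagreements are
tolerated only when the day's altitude extreme sits within 0.05° of the
threshold.

## Mixed models

Acceleration: `log(accel) ~ circadian × tidal + sex` in the tidal zone,
`log(accel) ~ circadian + sex` elsewhere (no tidal factor where no
annotation exists); random intercepts for receiver ID nested in tag ID;
AR1 residual correlation within each tag × receiver measurement series
(`nlme::corAR1` on measurement order). Migration speed:
`log(speed) ~ sex × tidal class` with crossed random intercepts for tag and
destination receiver (`lme4`). Both responses are log-transformed for
variance homogeneity; fixed terms are pruned by stepwise backward selection
on ML AIC, respecting marginality (interactions drop before their main
effects), and the selected structure is refit with REML. Omnibus tests are
marginal Wald chi-squared per retained term (exact reproduction of
denominator degrees of freedom from any particular field dataset is a
non-goal); estimated marginal means average model predictions over an
equally weighted grid of the other retained factors and are back-transformed
(geometric means) with 95% CI; pairwise contrasts use the t distribution
with residual df, Tukey-adjusted (via the studentized range) for the
3-level tidal class and unadjusted within other factors. If the nested AR1
fit fails to converge the model falls back to independent residuals, then to
a tag-level intercept, each fallback logged and recorded in the manifest.

## What the simulator emulates — and what it does not

The generator's defaults *are* the stated study system: a 166-km axis (tidal
0–125 km, transition 125–136, non-tidal beyond); a 12.4-h piecewise-
sinusoidal tide whose ebb fraction rises linearly from 0.508 at the mouth to
0.677 at the upstream tidal limit (ebb 6.3 h → 8.4 h) with amplitude
2.5 → 1.0 m and 2-cm gauge noise; zone behaviour nocturnal/nocturnal/STST at
base speeds 4.65 / 4.71 / 1.29 km day⁻¹ with lognormal per-step jitter
(sdlog 0.3, mean 1); movement ceasing at a spawning chainage of 60 km
(mid-mesohaline); detection range 500 m (field range < 300–1005 m), ping
interval 90–150 s, per-ping detection probability 0.5; accelerometer levels
0.25 m s⁻² moving / 0.11 m s⁻² resting with multiplicative lognormal noise
(sdlog 0.35 — the two-level-with-noise form is a simulator choice, the
source study quantifies no resting/moving acceleration model); depth from a
chainage profile (1 m headwaters → ~12 m estuary) plus the tidal level
offset. Positions for solar geometry interpolate between anchors at
~51.35° N, 4.0° E (mouth) and ~51.10° N, 4.75° E (headwaters). Behavioural
gates are evaluated against the simulator's own analytic phases, never the
pipeline's annotations, so recovery tests are non-circular.

Not emulated: 2-D channel geometry and hydrodynamics (detection range acts
along-channel), discharge and salinity, predation/mortality, tag loss,
receiver outages, and range variability with environmental noise. A green
test therefore establishes that the *analysis* recovers what the *stated
behavioural world* put in — not that the field system lacks these
complications.

## Fixture design for the statistical acceptance tests

Three fixture decisions deserve their rationale:

* **Null calibration needs heterogeneity.** Identical steady walkers passing
  evenly spaced receivers sample the tidal cycle systematically —
  within-animal phase counts become nearly deterministic and the chi-squared
  test is radically conservative; perfectly shared movement patterns across
  animals instead create cluster over-dispersion. Real networks and real
  animals are neither: the calibration world uses irregular receiver
  spacing, release times spread across a tidal cycle, and per-crab lognormal
  speed multipliers (sdlog 0.3; field speed CVs are larger). Under that
  world the 5%-level tidal test rejects at 7.6% over 500 replicates —
  within the accepted [3%, 8%] band — and the power world (pure ebb gating)
  rejects always.
* **Model recovery uses ground-truth phase labels.** The acceleration-model
  recovery replicates label each sensor observation with the gate state of
  the trajectory step that generated it. Pipeline annotations carry ≤1-sample
  boundary error, which attenuates the ebb/flood ratio a few percent — enough
  to sink CI coverage at n ≈ 2000 while telling us nothing about the model
  machinery; annotation accuracy is gated separately by the segmentation
  oracle.
* **Speed-model recovery generates speed records directly** from the model's
  generative form at the three zone means, because receiver-to-receiver
  speeds have a separate, known geometric bias (the clock runs only between
  detection-range edges, inflating speeds by spacing/(spacing − 2·range)),
  tested in its own unit test.

## Other numerical choices and limitations

* Timestamps are rounded to the nearest 10 min before any tidal lookup
  (matching the gauge resolution); exact five-minute midpoints round up.
* Duplicate detection triples are dropped keeping the first; release-day
  filtering removes the release UTC calendar day and events are recomputed
  from the surviving detections.
* Default event extraction collapses each (tag, receiver) pair to one visit
  (the convention behind the published event counts); a `split_gap` option
  exists for sensitivity analysis, and revisit pairs with zero chainage
  distance are skipped in speed computation. Upstream displacements are kept
  as flagged records but excluded from the speed model.
* Segment zone for a speed record is the zone of the midpoint chainage (the
  boundary-spanning case is otherwise undefined).
* Outputs are byte-deterministic given (dataset, config): stable CSV
  formatting, no wall-clock values in the manifest, all randomness seeded.
* Limitations: the chi-squared framework ignores within-animal dependence
  (see above); no circular statistics (Rayleigh/Watson) or periodogram
  methods; AR1 is fit on measurement order, not elapsed time, so irregular
  ping gaps are treated as equidistant — the same convention as the original
  analysis.
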