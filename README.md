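# ebbtrack

Tidal and circadian analysis of acoustic-telemetry detections for
downstream-migrating river animals — built around the movement ecology of
adult Chinese mitten crabs (*Eriocheir sinensis*) on their catadromous
spawning migration, but applicable to any tagged animal moving along a river
axis through non-tidal, micro-tidal and meso/macro-tidal water.

## Who this is for

Movement ecologists with (i) a detection table from a fixed acoustic receiver
network, (ii) receiver positions expressed as chainage (km upstream from the
estuarine mouth), (iii) tide-gauge water-level series, and (iv) tag metadata —
who want to ask: *do animals time their movement to the ebb tide (selective
tidal stream transport, STST) or to darkness, and how do movement rates and
depth change along the tidal gradient?*

## The statistics at the core

**Continuous-migration null model.** Arrival (first detection) and departure
(last detection) of each animal at each receiver proxy migratory activity.
Under continuous migration, the number of events in phase *k* is proportional
to the relative duration of that phase, so with observed counts
*O₁…O_K* and weighted expected proportions *p₁…p_K* the test statistic is
Pearson's goodness-of-fit

&nbsp;&nbsp;&nbsp;&nbsp;χ² = Σₖ (Oₖ − n pₖ)² / (n pₖ),&nbsp;&nbsp; df = K − 1.

Because phase durations vary over the season (day/twilight/night) and along
the river (ebb/flood), the expected proportions are weighted means: each
event contributes its own date's daily phase-duration fractions (circadian;
durations from solar geometry at the receiver position, with twilight =
dawn ∪ dusk between −0.833° and −18° solar altitude) or its own receiver's
mean ebb/flood cycle shares (tidal; from ebb/flood segmentation of
water levels inverse-distance-interpolated to the receiver chainage).

**Kinematics.** Migration speed = chainage distance between consecutive
receivers / (arrival at next − departure at previous), in km day⁻¹; per-zone
depth summaries from pressure-sensor tags.

**Mixed models.** Accelerometer activity: `log(accel) ~ circadian × tidal +
sex` (tidal zone) or `log(accel) ~ circadian + sex` (elsewhere) with random
intercepts for receiver ID nested in tag ID and AR1 residual correlation
within each tag × receiver series (`nlme::lme`, `corAR1`); migration speed:
`log(speed) ~ sex × tidal class` with crossed random intercepts for tag and
receiver (`lme4::lmer`). Fixed effects are pruned by backward AIC selection;
group means are reported back-transformed (geometric means) with 95% CI and
pairwise contrasts (Tukey-adjusted for the 3-level tidal class).

**Simulator.** A 1-D river (default 166 km: tidal 0–125 km, transition
125–136 km, non-tidal beyond) with piecewise-sinusoidal asymmetric tides
(12.4-h period; ebb fraction rising 0.508 → 0.677 upstream, i.e. ebb
6.3 h → 8.4 h), behaviourally gated crabs (nocturnal in non-tidal water,
ebb-selective in tidal water; movement stops at the spawning chainage) and a
ping/range/probability detection process — with ground-truth trajectories
and gate states for every downstream validation.

## Worked example

```r
library(ebbtrack)
dir <- file.path(tempdir(), "demo")
make_fixture(dir, seed = 42, profile = "small")     # synthetic dataset, 10 crabs
ds  <- read_dataset(dir, analysis_config(seed = 42))
res <- run_pipeline(ds, out_dir = file.path(tempdir(), "demo-results"))
cat(readLines(file.path(tempdir(), "demo-results", "summary.txt")), sep = "\n")
```

prints (abridged):

```
== selectivity tests ==
circadian arrival   non_tidal  n=  9  chi2=   9.751 df=2 p=0.00763 *
tidal     departure tidal      n=  5  chi2=   3.348 df=1 p=0.0673
...
== migration speed (km/day, downstream records) ==
tidal      n=   1  mean=  0.91 sd=    NA range=0.91-0.91
transition n=   3  mean=  2.77 sd=  0.02 range=2.75-2.79
non_tidal  n=   5  mean=  2.77 sd=  0.03 range=2.72-2.81

== acceleration model, tidal zone ==
  retained: tidal + sex
  flood: 0.11 m/s^2 [0.10-0.12]
  ebb: 0.23 m/s^2 [0.21-0.24]

== speed model ==
  tidal - non_tidal: ratio=0.33 p(Tukey)=2.22e-07
  transition - non_tidal: ratio=1.01 p(Tukey)=0.861
```

Reading it: the simulated crabs are nocturnal in the non-tidal river (the
circadian arrival test rejects continuous migration there), ebb-active in the
tidal zone (acceleration geometric means 0.23 vs 0.11 m s⁻²), and migrate
about three times slower in tidal water — the fingerprint of selective tidal
stream transport. The 14-day demo fixture has too few tidal events (n = 5)
for the tidal goodness-of-fit test itself to reach significance; the
acceptance suite runs it at the study's real event counts (n ≈ 130–150)
where it is calibrated under the null and near-certain to reject under STST.

A command-line interface wraps the same steps:

```sh
Rscript -e 'ebbtrack::ebbtrack_cli()' simulate --out demo --seed 42 --profile small
Rscript -e 'ebbtrack::ebbtrack_cli()' run --data demo --out demo-results
Rscript -e 'ebbtrack::ebbtrack_cli()' selftest
```

## Layout

- `R/` — core data (`read_dataset`), tides (`segment_phases`, `phase_at`,
  `cycle_stats`, `interpolate_level`), solar (`circadian_phase`,
  `phase_durations`), events (`extract_visits`, `exclude_release_day`,
  `annotate_events`), selectivity (`expected_*_props`, `gof_test`,
  `run_selectivity`, `rose_bins`), kinematics (`migration_speeds`,
  `depth_summary`, `link_sensor_phases`), inference
  (`fit_acceleration_models`, `fit_speed_model`), simulator (`sim_config`,
  `simulate_*`, `make_fixture`), pipeline (`run_pipeline`).
- `vignettes/ebbtrack-methods.Rmd` — model assumptions, parameter defaults,
  what the simulator does and does not emulate, numerical choices.
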