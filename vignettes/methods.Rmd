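---
title: "Inferring honey bee foraging from waggle dances: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring honey bee foraging from waggle dances: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
dance-decoding model, the error propagation, the resampling estimators,
and the choices we made where the method leaves room for judgement.

## The decoding model

A waggle run encodes a polar vector from the hive. The run's angle from
vertical on the comb, measured clockwise-positive, equals the bearing of
the advertised resource relative to the sun's azimuth at the time of the
dance; its duration maps to distance through a linear calibration

$$\text{duration (s)} = a + b \cdot \text{distance (m)},$$

so decoding a dance is: average the four measured runs, add the solar
azimuth to the mean angle, and invert the calibration line.

* **Angle averaging is circular** (mean resultant direction). For the
  tight intra-dance spreads real dancers show (a few degrees to ~15°)
  the circular mean is numerically indistinguishable from the
  arithmetic mean — the bias is third order in the spread, under 0.15°
  at ±15° — but it remains correct when a dance points near ±180°,
  where the arithmetic mean can be off by 180°. Durations are averaged
  arithmetically.
* **Solar azimuth** is computed from the NOAA solar-calculator
  equations (a Meeus-derived algorithm). We verified it against an
  independent implementation of Michalsky's (1988) algorithm: maximum
  disagreement over two hundred random daytime instants at the hive
  site was ~0.012°, far below the degree-scale imprecision of the
  dances themselves. Timestamps are local civil time with an explicit
  UTC offset; an offset error of one hour rotates every bearing by
  roughly 15°, which is why the offset is a required input rather than
  something inferred.
* **All bearings are relative to true north.** The solar azimuth is
  defined on true north and the comb reference is gravity, so no
  magnetic declination correction is involved anywhere.
* The **plumb-line offset** (camera/hive tilt, typically under a few
  degrees) is added to each measured angle before averaging.
* **Four runs, two left and two right turns** is the protocol contract.
  A dance with a different run count is a structural error; an
  unbalanced turn count only warns, since legitimate data entry can
  deviate.

### Calibration constants

The calibration parameters are configuration, not estimates made here.
The shipped defaults — intercept 0.30 s, slope 0.00135 s/m, residual
duration SD 0.15 s, angular SD 15°, all user-overridable via a YAML file
(`read_calibration()`) — are round representative values of the
published universal-calibration lineage. Any study should substitute the
constants it actually uses; every numeric result downstream depends on
them. Durations below the intercept invert to negative distances and are
floored at `min_distance_m` (default 0) with a warning.

## Probability clouds

Dances are honestly noisy in both components, so a decoded vector is
mapped not as a point but as a cloud of `n_draws` (default 1000)
simulated locations:

* duration* = mean duration + ε, ε ~ Normal(0, `duration_sd_s`), then
  inverted through the calibration (negative distances floored at the
  minimum, with a count reported, so the draw count the resamplers rely
  on is preserved);
* bearing* = bearing + η, η ~ von Mises with circular SD
  `angle_sd_deg` (concentration found by inverting the Bessel-ratio
  relation; sampling by Best–Fisher rejection).

Noise enters *duration* rather than distance because the calibration is
defined duration-on-distance. Geometry is done in a local
azimuthal-equidistant plane centred on the hive (`east = d sin θ`,
`north = d cos θ`); at the ≤10 km scale of bee foraging the planar error
is below a metre, and geographic coordinates are recovered by geodesic
destination-point computation when needed.

Reproducibility: a single pipeline seed deterministically derives a
substream per dance keyed on the dance identifier, so a dance's cloud
does not change when other dances are added or removed.

## Landscape, recruitment, and the resampling CI

Crop fields arrive as labelled polygons (KML or GeoJSON), are validated
(simple polygons only; overlaps warn and resolve by file order) and
queried in the hive plane. Boundary points count as inside. Land cover
within a disc (default 2 km, where the large majority of recruitment
falls) is computed by clipping each polygon against a 720-gon disc
(Sutherland–Hodgman; the disc-polygon area error is below one part in
10^4) — "other" is the complement, so covers sum to 100%.

**Percent recruitment** follows the pick-one-prediction scheme: per
repetition, draw one location per dance uniformly from its cloud, label
it, and record the percentage of dances in the crop class; over
`n_reps = 10,000` repetitions the median is the point estimate and the
2.5th/97.5th percentiles the CI (percentiles by the conventional
linear-interpolation rule; the mean is reported alongside the median
since both conventions appear in practice). Strata are defined per
crop's own full-bloom window (the period when >75% of its fields
flower), boundary dates inclusive, so the same dance can be "during" for
one crop and "pre" for another. Simulated draws landing beyond a
region-of-interest radius can either be labelled "other" (default) or
dropped — a choice the user makes explicitly because it changes the
denominator.

**What this CI is and is not.** The resampling interval propagates the
dance-communication uncertainty encoded in the clouds. It does *not*
include the sampling variability of the observed dance set: with few
dances in a reference stratum, the realized composition can deviate from
the generating process while the interval stays narrow. Our null
simulations show exactly this: the estimator faithfully recovers the
*realized* season, and its interval covers the generative truth only
when communication noise dominates realization noise. Users comparing
small strata should treat these CIs as uncertainty in *where the
observed dances point*, not as full inferential intervals about colony
behaviour.

**Mapping** uses a 25 m grid anchored at the hive with half-open cells;
each dance's weight is split equally over its cloud draws, so total
weight is conserved exactly and cell values are percentages of overall
recruitment.

## Distance-corrected attractiveness

Whether a crop is *attractive* (used beyond its availability) is
confounded by distance: nearer fields receive more recruitment for pure
economics. The attractiveness model is a multinomial logistic regression
of the labelled outcome (reference "other") on month (dummy-coded,
reference April or the earliest month present), distance in km (linear,
taken from the sampled draw so outcome and covariate are consistent) and
a year indicator. To propagate cloud uncertainty the model is refit
`n_models` times (default 1000), each run relabelling every dance from a
fresh cloud draw; odds ratios are the exponentiated medians of the
per-run coefficients, with percentile CIs.

Design choices here:

* **Year enters as a fixed indicator**, not a random effect: with two
  levels a variance component is essentially unidentified, and the fixed
  indicator reproduces the same adjustment. `year_effect = "stratified"`
  fits seasons separately instead.
* Runs in which an outcome category never occurs cannot estimate that
  category's contrasts and are **dropped with a reported count**; runs
  showing separation (|log-odds| > 10) are refit with a tiny ridge
  penalty (`decay = 1e-3`) and counted.
* The reference month's odds ratio is 1 by construction and is not
  reported as a row.

The same realization-noise caveat applies: the percentile CI reflects
label (communication) uncertainty around the observed season.
Misclassification of cloud draws across field boundaries also attenuates
odds ratios toward 1 relative to the truth-level preference — visibly so
when fields are small or far (bearing blur grows linearly with
distance). Parameter-recovery simulations in the test suite therefore
use few, large, near fields for the focal crop, the regime in which a
planted preference is identifiable at moderate sample size.

## Seasonal distance statistics

Communicated distance proxies forage availability. Summaries are exact
order statistics (even-n midpoint median; interpolated 95th percentile).
The month comparison is a Kruskal–Wallis rank test (seven filming months
give df = 6) followed by pairwise Dunn z-tests with tie correction and
Holm adjustment, rendered as a compact letter display via
insert-and-absorb — months sharing a letter do not differ at α = 0.05.
The omnibus test is deliberately rank-based: distance distributions are
right-skewed with occasional kilometre-scale excursions, and medians are
the quantity of interest. Dunn's test is the standard post hoc companion
to Kruskal–Wallis; both choices are configurable conventions rather than
uniquely determined by the method. The LOESS curve in the seasonal plot
(`plot_distance_season()`, span 0.1) is a visual aid only and takes no
part in inference.

## Data validation (QC)

Before analysis, rows with missing measurements are removed (dropping
the affected dance), and each dance is scored by its intra-dance spread:
sample SD of the four durations and circular SD of the four corrected
angles. The ten highest-SD dances per component form a review queue; a
human either corrects a recognisable entry error (the dance is re-scored
next round) or accepts the dance as a genuinely noisy dancer. Rounds
repeat until every queued dance is noisy-accepted. The package models
this as a flag-transition workflow (`qc_review_cycle()`) with the
judgement injected as a callback; ranks break ties by dance id so the
queue is deterministic.

## The synthetic-data generator

The generator is the package's testbed: it produces landscapes, foraging
truths and run-level tables with the statistical structure every stage
assumes, so the whole pipeline can be validated by parameter recovery.

* **Landscape**: non-overlapping axis-aligned rectangular fields placed
  in configurable distance bands until each crop's land cover inside
  the 2 km disc hits its target (defaults 6–10% per crop, the
  magnitude of row-crop cover around a mixed-crop research farm).
  Rectangles are sufficient for all geometric logic; real KML traces
  remain ingestible.
* **Foraging truth**: category-then-point sampling. A dance's category
  (crop or "other") is drawn with probability proportional to land
  cover × a per-crop, per-month attractiveness weight — the same
  parameterisation the inference model estimates, which makes recovery
  targets closed-form. Within a crop, a field is chosen with weight
  area × exp(−distance/700 m) (nearer fields of equal quality are
  preferred, basic foraging economics) and the point is uniform in the
  field. "Other" points take a uniform bearing and a gamma-distributed
  distance (shape 2, scale 260 m) scaled by a monthly
  forage-availability multiplier (shortest in July when the surrounding
  crops bloom, longer in the spring and early-summer dearth); together
  these defaults yield a pooled median communicated distance of about
  0.7 km, mid-summer row-crop recruitment near half of dances, and a
  significant month effect — the seasonal structure the pipeline is
  meant to detect. A `uniform` alternative distributes non-crop
  foraging uniformly over the disc, the correct null for calibration
  checks.
* **Dance records**: per dance, the timestamp is uniform in the
  09:30–12:30 filming window; four runs get durations
  `a + b·d + Normal(0, 0.06 s)` quantized to whole frames at 30 fps
  (rounding half-up) and angles
  `true bearing − solar azimuth + Normal(0, 10°) − plumb offset`, with
  two left and two right turns. With all noise at zero, decoding
  recovers truths exactly up to frame quantization (≤ 1/60 s per run),
  the pipeline's round-trip identity.

**What the generator does not emulate**: dance-rate feedback
(profitable sites elicit more dances), recruit behaviour, weather gaps,
crop rotation within a season, curved field boundaries, and bee-level
biases in the calibration. Passing recovery tests therefore demonstrates
the *estimators* are correct under the stated error model, not that real
landscapes will be as clean.

## Numerical and policy details

* Angles wrap to (−180°, 180°] (dance frame) and [0°, 360°) (bearings);
  the circular mean maps −180° to +180°.
* von Mises concentration: κ solves A₁(κ) = exp(−σ²/2) by
  root-finding on the exponentially scaled Bessel ratio; for σ < 0.57°
  the asymptote κ = 1/σ² is used directly (the two branches agree to
  5% at the switch).
* Point-in-polygon: even-odd rule with boundary points inside
  (`sp::point.in.polygon`), checked in the test suite against an
  independent brute-force ray-casting oracle on tens of thousands of
  random points over random landscapes.
* Resampling percentiles: type-7 (linear interpolation), R's default.
* Seeds: one pipeline seed; every stochastic stage derives an
  independent substream (dances by identifier hash, stages by fixed
  offsets), all below 2³¹.
* Degenerate inputs fail loudly and early: single-month attractiveness
  designs, empty cloud lists, zero-rep configurations, self-intersecting
  polygons, missing calendar entries.

## Problem sizes used by the shipped checks

The test suite validates at deliberately moderate sizes chosen to
exercise every code path with tight Monte-Carlo bounds: round-trip and
oracle checks at 10⁴–2×10⁵ points, null calibration at 500 dances × 400
draws × 2000 reps, parameter recovery at 1000 dances × 400 draws × 200
repeated fits, seasonal recovery at 800 dances. The acceptance script
runs the full two-season default study (~3400 dances, 1000-draw clouds,
10,000-rep recruitment, 300 repeated fits). These sizes are the
package's own validation choices; all scale linearly if users want more.

## Known limitations

* The resampling CIs quantify communication uncertainty only (discussed
  above) — small-stratum comparisons are optimistic.
* Odds ratios are attenuated by draw misclassification near field
  boundaries; the effect grows with distance and shrinking field size.
* The calibration is treated as known; its parameter uncertainty is not
  propagated (only its residual noise is).
* Fields are static within a year; mid-season land-use change is out of
  scope.
* The multinomial model assumes independence across dances; repeated
  dances by one forager (partially mitigated upstream by the 6-minute
  video skip protocol) would understate uncertainty.
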