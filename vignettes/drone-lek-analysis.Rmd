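---
title: "Analysing harmonic-radar drone tracks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing harmonic-radar drone tracks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beelek)
```

`beelek` analyses timestamped positional fixes of individually tracked
flying insects — honeybee drones in the motivating application — recorded
by harmonic radar: one fix per ~3 s antenna rotation, within a ~800 m
radius, with ~2 m positional accuracy and frequent missed sweeps. This
vignette explains the models and algorithms behind each stage, the
parameters that matter, and the design decisions taken where more than
one reasonable choice existed. The companion simulator generates tracks
with known ground truth, so every claim below is backed by a test the
package actually runs.

## Data model and coordinate frames

A **flight segment** is an ordered series of fixes unambiguously
attributable to one flight by one individual; it need not be complete,
because bees leave radar coverage by flying too high or low, landing, or
entering radar shadow. Radar output is polar (range, azimuth); azimuth
follows the navigation convention, degrees clockwise from true north, so
`x = r sin(az)`, `y = r cos(az)` in a planar east–north frame in metres
anchored at the radar. At ranges of a few hundred metres a planar frame
is well within the 2 m measurement accuracy; geographic (WGS84) export
is available through a similarity transform calibrated from two surveyed
reference points, with the calibration residual reported so miskeyed
references are caught.

Segments lasting under 30 s, or in which the bee never moved 15 m from
its start, are too brief to characterise flight behaviour. These
thresholds are applied inclusively (`>= 30 s`, `>= 15 m` keeps a
segment). `filter_substantial()` partitions rather than discards:
non-substantial segments still carry occupancy evidence and feed the
heat maps.

## Straight versus convoluted flight

Drone flights alternate between straight commuting legs and tightly
looping, *convoluted* flight. The classifier uses only the directional
statistics of the track, making it scale free:

1. Every consecutive fix pair defines a transition with a bearing
   `atan2(dx, dy)`. Zero-displacement transitions have no bearing and
   never enter window statistics.
2. A 21 s window (seven radar rotations at nominal sampling) is centred
   on every fix time. The **resultant vector length**
   `R = |mean unit bearing vector|` of the transitions falling in the
   window measures directional persistence: 1 when aligned, 0 when
   balanced.
3. A fix covered by *any* window with `R > 0.7` is a straight candidate;
   all others are convoluted candidates. A window needs at least two
   defined bearings to certify anything.
4. Transitions with a gap over 12 s *and* a displacement over 40 m sever
   convoluted runs, so flight either side of a long dropout cannot merge
   into one convoluted section.
5. Maximal convoluted runs of at least 7 consecutive fixes become
   convoluted sections; shorter runs are relabelled straight. The
   remaining fixes form straight sections.

Window anchoring deserves a note: the definition above evaluates windows
centred at every fix and lets a qualifying window certify every fix
incident to a transition inside it. A continuous slide or a half-open
interval would be equally defensible; anchoring at fixes is symmetric,
reproduces the seven-rotation span at nominal sampling, and is exposed
through `classifier_params()` so the sensitivity can be checked (the
suite re-runs the classifier at `window_s` 15/21/27 and `r_threshold`
0.6/0.7/0.8 on simulated tracks; per-fix labels agree with the default
setting to between roughly 89% and 100% across that sweep). A fix whose only transitions are zero-displacement is treated
as a convoluted candidate — hovering is not straight flight. When a
whole segment is shorter than one window the classifier cannot certify
anything and labels the segment straight with a warning.

## Congregation discovery

Convoluted fixes are pooled across flights, excluding sections whose
centre of mass lies within 50 m of a hive (strictly greater than 50 m
keeps a section): looping flight at the hive entrance is hive behaviour,
not congregation behaviour. By default only hives active at the time of
the flight are considered, falling back to all hives when no dates are
recorded; a strict all-hives mode is available.

The pooled fixes are clustered by single-linkage agglomerative
clustering cut at 8 m: two fixes share a cluster exactly when a chain of
steps of at most 8 m connects them — the connected components of the
8 m adjacency graph, which is what the test oracle computes by
brute-force search. Complete and average linkage are available behind
the same interface, but single linkage is the only criterion for which
a plain distance cutoff has that graph interpretation. Because every
fix must land in some cluster, most clusters are scraps of single
flights; only clusters supported by at least 10 distinct flight
segments are retained as candidate congregation areas. Areas are
labelled `A`, `B`, … by decreasing segment support. The centre of an
area is the mean of its member fixes — robust to the inclusion or
exclusion of a few perimeter points — while the convex hull is kept for
illustration only.

## Swarm cohesion dynamics

Within convoluted sections assigned to a location (centre of mass within
50 m of a congregation or active hive; nearest centre wins, with exact
ties resolved toward the congregation), per-fix kinematics are computed
by finite differences: velocity is displacement over the transition
interval; acceleration is the difference of consecutive velocities over
a time interval, positioned at the fix the two transitions share. The
source analysis specifies the numerator but not which interval divides
it; the trailing interval is the default and the mean of the two
intervals is available (`accel_dt = "mean"`). For evenly sampled data
the two coincide.

The cohesion signature is the regression of acceleration on position:
an ordinary least-squares fit pooled over all sections at one location,
per axis. A negative slope with an x-intercept at the swarm centre means
drones accelerate back toward the centre the further they stray — an
effective elastic potential well. `fit_well()` reports the slope,
intercept, x-intercept (`-b0/b1`, with a delta-method standard error),
and the slope p-value; no multiple-testing correction is applied, and
5 m binned profiles (`binned_profile()`) support the visual check of
linearity. Position and velocity distributions at congregations should
have Gaussian cores: `kurtosis()` (Pearson convention, Gaussian = 3)
and `gaussian_core_points()` (standard normal-probability pairs)
quantify this; hive-side flight is heavier tailed.

A caveat established with the simulator and worth knowing when
interpreting fits on radar-rate data: finite-difference acceleration
over 3 s intervals attenuates the recovered slope when the velocity
correlation time is comparable to the sampling interval (measured
attenuation ~10–40% depending on the well). The parameter-recovery
tests therefore sample the simulated continuous path at 0.2 s, where
the bias is under 2%; with field data at 3 s resolution, slopes are
conservative (biased toward zero) and x-intercepts remain essentially
unbiased, so the *location* of the well is trustworthy even where its
stiffness is underestimated.

Visits are counted per flight and area: a visit is either a convoluted
section whose centre of mass lies within 50 m of the area centre, or a
dwell of at least 21 s inside that 50 m disc, bridging signal-loss
intervals whose flanking fixes are both inside (a bee that climbed out
of radar coverage above the congregation has not left it).

## Occupancy heat maps

Between two consecutive fixes the bee's position is interpolated by a
Brownian bridge observed with error: the interval is split into 5
timeslices per second, and at fraction `alpha` through the interval the
position is bivariate normal around the linear interpolation with
per-axis variance `alpha (1 - alpha) T sigma_mobility^2 +
sigma_location^2`. Timeslices sit at interval midpoints. The mobility
scale is not identified by the data themselves; the default makes the
bridge standard deviation at the midpoint of a 3 s interval equal the
2 m positional error, and it is configurable. Per pixel, the density is
integrated by exact normal-CDF differences by default; the faster
density-times-area approximation is available (`method = "center"`) but
aliases visibly when the bridge standard deviation drops below the 5 m
pixel size, violating mass conservation by several percent, which is
why it is not the default. Each timeslice contributes unit mass on a
covering grid, a property the tests assert to 0.1%.

Per segment, timeslice rasters are summed and the grid normalised so
the hottest pixel equals 1: a single long track can then never dominate
the aggregate — hotspots require multiple segments. Heat maps consume
*all* segments, including non-substantial ones. Aggregation sums the
normalised grids and derives per-pixel opacity from percentiles of the
summed values: transparent below the 1st percentile, opaque above the
5th, linear between. Percentiles are computed over occupied (nonzero)
pixels; computing them over the vast never-visited background would
push both thresholds to zero and saturate the ramp.

## The simulator and what passing tests mean

`simulate_dataset()` generates the study conditions end to end: three
hives, four congregation areas inside the 800 m radius, drones making
flights that optionally open with a hovering bout at the hive, then
commute at 4.8 m/s (correlated random walk steered at the target,
heading noise 0.1 rad per 0.1 s step) to one to three areas with a
potential-well swarm bout at each (exponential dwell, mean 134 s,
truncated at 21 s so bouts are detectable), and return. Swarming is an
Ornstein–Uhlenbeck velocity process with a linear restoring force,
integrated by Euler–Maruyama at `dt = 0.1` s (30 substeps per radar
rotation); the default well (`k = 0.1` 1/s², `gamma = 0.5` 1/s,
`sigma = 4` m/s^1.5) gives a position sd of ~12.6 m per axis — a swarm
core a few tens of metres across — and mean speeds near 5 m/s,
matching the reported contrast with ~4.8 m/s commuting. Hive hovering
is a mixture of a tight slow well (3 m, 1.5 m/s) and wider loops (12 m,
2.5 m/s), switched every 20 s: a deliberately simple stand-in whose
pooled position distribution is heavy tailed (kurtosis > 3) and slow,
creating the hive-versus-congregation contrast the dynamics stage must
detect, without claiming biological realism. The radar model samples
every 3 s, drops sweeps with probability 0.05, adds 2 m Gaussian error
per axis, and discards fixes beyond 800 m.

What the simulator does *not* emulate: altitude (the radar is 2-D),
radar shadow from terrain and vegetation (dropouts are independent
rather than spatially structured), wind, inter-individual interaction
within swarms, identity-assignment ambiguity when several transponders
fly at once, and orientation-flight ontogeny. Passing recovery tests
therefore show the pipeline is correct under its stated model, not that
field data meet that model.

## Problem sizes and numerical tolerances

The test-suite simulations use 30 drones with 2 flights each (roughly
11,000 fixes), 100 random clustering instances of up to 200 points
against the brute-force oracle, well-parameter recovery at
`k ∈ {0.01, 0.05, 0.1}` with at least 5,000 kinematics samples per fit
(slope and x-intercept checked within 2 standard errors; stationary
variances within 10%), and Monte-Carlo bridge validation at 10^5 draws
per timeslice (3-sigma binomial tolerance per pixel). Cluster
assignments must match the adjacency-graph oracle exactly; mass
conservation is asserted to 0.1%; kurtosis oracles to 10^-12. The full
suite runs in well under a minute on one core.

## Known limitations

- Single-linkage clustering is O(n²) in fixes through the distance
  matrix; datasets beyond ~50,000 convoluted fixes would need a spatial
  index, which the field datasets this targets do not approach.
- The exact geographic triangulation used to produce GPS tracks from
  raw radar polar coordinates is site-specific; the similarity
  transform calibrated from two reference points reproduces it only up
  to an affine approximation, adequate at ≤800 m range.
- Regression standard errors treat kinematics samples as independent;
  at radar-rate sampling successive samples are nearly uncorrelated,
  but at the 0.2 s sampling used in recovery tests they are not, and
  the reported standard errors there are mildly optimistic.
- The dwell-visit rule bridges arbitrarily long signal losses when both
  flanking fixes are inside the disc; with very sparse tracks this can
  overcount dwell time. The 21 s threshold makes this conservative at
  nominal 3 s sampling.
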