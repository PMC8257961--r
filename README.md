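# beelek

Analysis of harmonic-radar tracks of flying insects, built for the study
of honeybee drone congregation areas (DCAs) — the aerial leks where male
honeybees gather to await virgin queens. Harmonic radar returns one
(range, azimuth) fix per ~3 s antenna rotation for a single tagged
insect within ~800 m, with ~2 m accuracy and frequent missed sweeps.
From such tracks, `beelek`:

- converts polar fixes to a local planar frame and filters *substantial
  flight segments* (≥ 30 s, ≥ 15 m from the start);
- classifies flight into **straight** and **convoluted** sections using
  a moving 21 s window of transition bearings: a fix is straight when
  some window covering it has resultant vector length
  `R = |Σ(sin θᵢ, cos θᵢ)| / n > 0.7`; convoluted runs need ≥ 7
  consecutive fixes, and gaps > 12 s spanning > 40 m sever them;
- discovers candidate congregation areas by single-linkage clustering
  (8 m cutoff) of convoluted fixes more than 50 m from any active hive,
  keeping clusters supported by ≥ 10 distinct flight segments;
- quantifies swarm cohesion: per-axis OLS of acceleration `a` on
  position `x` relative to a centre. A slope `−k < 0` with x-intercept
  at the centre is the elastic-potential-well signature
  (`E[a|x] = −k(x − c)`); 5 m binned profiles, Pearson kurtosis
  (Gaussian = 3) and normal-probability points diagnose the Gaussian
  core; per-flight visits to multiple areas are counted (convoluted
  section CoM within 50 m, or a ≥ 21 s dwell with gap bridging);
- renders landscape occupancy heat maps from a timesliced Brownian
  bridge: 5 slices/s, per-axis variance
  `α(1−α)T σ²_mobility + σ²_location`, 5 m pixels, per-segment
  max-normalisation, percentile-based opacity;
- simulates the whole observation process (commutes at 4.8 m/s,
  Ornstein–Uhlenbeck potential-well swarming, hive hovering, radar
  sampling artefacts) with per-fix ground truth, so every stage is
  testable without field data.

## Worked example

```r
library(beelek)

sim  <- simulate_dataset(sim_config(seed = 1))      # 30 drones, 2 flights each
fs   <- filter_substantial(sim$segments)
secs <- classify_all(fs$kept)
st   <- sections_table(secs)
str(st$aggregates)
#> List of 5
#>  $ n_convoluted_sections        : int 114
#>  $ n_flights_with_convoluted    : int 56
#>  $ n_flights_multi_convoluted   : int 32
#>  $ mean_convoluted_duration_s   : num 137
#>  $ mean_fraction_time_convoluted: num 0.382

areas <- find_congregations(fs$kept, secs, sim$site)
congregations_table(areas)
#>   area_id  center_x  center_y n_segments n_fixes
#> 1       A  139.9326  419.8649         27    1401
#> 2       B  299.8241 -199.8043         25    1140
#> 3       C -259.4981  319.9678         25    1393
#> 4       D  449.9110  120.3238         20     853
```

The four discovered centres sit within a metre of the four planted
congregation areas (`sim$area_centers`), each supported by 20–27 of the
60 flights. The mean convoluted-section duration (~137 s) reflects the
simulated swarm dwell (exponential, mean 134 s). Fitting the potential
well at a finely sampled simulated bout recovers the planted dynamics:

```r
set.seed(42)
path <- simulate_swarm_bout(center = c(10, -5), k = 0.05, gamma = 0.5,
                            sigma = 2, duration_s = 4000, dt = 0.1)
kin <- kinematics(path[seq(1, nrow(path), 2), c("t", "x", "y")], c(0, 0))
fit_well(kin, "x")[, c("slope", "slope_se", "x_intercept", "n")]
#>         slope    slope_se x_intercept     n
#> 1 -0.05565664 0.003152662    9.914506 19999
```

The slope estimate −0.056 ± 0.003 recovers the planted stiffness
k = 0.05 and the x-intercept the planted centre (x = 10 m): drones
straying from the swarm centre accelerate back toward it in proportion
to their distance. Note that differencing at the 3 s radar rate instead
attenuates the slope (documented in the methods vignette); x-intercepts
stay unbiased.

A command-line wrapper covering the same pipeline is installed at
`inst/scripts/beelek`:

```sh
Rscript inst/scripts/beelek simulate --seed 7 --out synth/
Rscript inst/scripts/beelek cluster synth/tracks.csv --site synth/site.yml \
    --out congregations.csv
```

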