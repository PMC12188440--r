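# troopline

Detection and analysis of collective travel progressions from
multi-individual GPS tracking.

Group-living animals — the motivating system is a group of chacma baboons
(*Papio ursinus*) carrying 1 Hz GPS collars — often travel in elongated
"line" formations called progressions. Whether an individual walks at the
front, middle or rear of a progression has been linked to predation risk,
feeding competition, leadership, and to the pull of social bonds.
`troopline` turns that question into a reproducible pipeline: it detects
progression events from simultaneous trajectories, measures each
individual's spatial order inside the moving group, and fits the network
and mixed-model statistics that discriminate the competing explanations.
A seeded synthetic trajectory generator with planted ground truth makes
every stage testable without any field data.

## The quantities at the core

For $N$ tracked individuals with velocities $\mathbf{v}_i(t)$, the package
computes per second:

* **polarization** $P(t) = \frac{1}{N}\left\lVert \sum_{i=1}^{N}
  \mathbf{v}_i/\lVert\mathbf{v}_i\rVert \right\rVert \in [0,1]$ — 1 when
  all headings agree;
* **mean individual speed**, **group centroid**, and the **travel
  direction** (centroid displacement over a 10 s window);
* **elongation** — the ratio of the group's extent along the travel
  direction to its extent perpendicular to it;
* **cohesion** — whether at least 10 tracked individuals have a
  conspecific within 50 m.

A **progression** is a maximal run of seconds in which the smoothed
(5-min running average) polarization *and* smoothed mean speed lie at or
above their pooled 90th percentiles, the group is cohesive, the run's mean
elongation exceeds 1, and the run lasts at least 15 s.

Within each progression, individuals are projected into the moving group
frame (origin at the centroid, x-axis along travel): the signed
front–back coordinate is the **spatial position**, its absolute value the
**spatial interiority** (small = central). Downstream statistics include
repeatability (ICC) of position, mean pairwise-distance networks inside
and outside progressions with eigenvector centrality, nearest-neighbour
Markov-chain consistency, and a five-model `glmmTMB` battery.

## Worked example

Simulate two days of 13 individuals under the default study conditions
and run the full pipeline:

```r
library(troopline)

ds  <- generate(sim_config(seed = 1))     # trajectories + ground truth
rep <- run_pipeline(ds$trajectories, ds$attributes)
rep
#> <progression_report> 3 events over 2 day(s), 0.85 h total
#>   thresholds: polarization >= 0.503, speed >= 0.731 m/s
#>   ICC of spatial position: 0.618

event_overlap_jaccard(ds$events, rep$events)
#> [1] 0.9526834
```

Three planted progressions are recovered with a seconds-level overlap of
0.95. The detected events carry the formation geometry (mean length
86 m vs width 37 m, elongation 2.4), and the model battery reports the
planted social structure:

```r
battery_summary(rep$battery)[c(8, 14, 16), c("model", "term", "estimate", "p")]
#>   model       term      estimate        p
#> 1 interiority dominance   -26.0     0.023   # dominants central
#> 2 association rest_dist     1.25    6.3e-21 # progression distances track
#>                                            # everyday associations
#> 3 variability dominance    -5.89    0.013   # dominants hold steadier slots
```

The negative interiority coefficient says higher-ranked individuals sit
closer to the centroid along the travel axis; the positive association
slope says pairs that keep close during ordinary foraging also travel
close in line — spatial order as a by-product of social bonds rather
than a directly selected trait. With `sim_config(structure = "null")` the
generator plants no structure and these effects vanish, which is exactly
what the test suite checks.

Field data enter the same way: a per-fix CSV (id, timestamp, lat/lon or
x/y) through `read_trajectories()`, an attribute CSV (id, sex, dominance
in [0, 1]) through `read_attributes()`, then `run_pipeline()`. A thin
command-line front-end is included at `inst/cli/troopline.R`
(`simulate` and `run-all` commands).

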